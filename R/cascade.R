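#' Fit the whole-exome endometrial-cancer subtype classifier
#'
#' Trains the one tunable component of the hierarchical subtype cascade:
#' the Gaussian naive Bayes model of copy-number cluster-4 membership.
#' Gene selection (the most frequently altered genes) runs on the full
#' training cohort, the feature matrix is built, and the model fitted.
#' The POLE rule and the MSI gate carry no trained parameters; their
#' thresholds are stored alongside so a fitted object fully determines the
#' cascade.
#'
#' The cascade applied by [predict.ec_classifier()] is, in strict order:
#' POLE (SNV burden > `snv_min`, C>A fraction > `ca_min`, C>G fraction <
#' `cg_max`), then MSI (MSI-high status), then CN-high (naive Bayes
#' posterior of cluster-4 membership at or above `threshold`), residual
#' CN-low.
#'
#' @param cn a `cn_cohort` of training copy-number profiles
#'   (see [read_seg()]).
#' @param cluster4 binary labels aligned with `names(cn$ploidy)`:
#'   `TRUE`/1 when the sample belongs to copy-number cluster 4.
#' @param genes gene model data frame (see [read_gene_bed()]).
#' @param pole a [pole_params()] object.
#' @param spec a [cn_feature_spec()] object.
#' @param threshold posterior cutoff for the CN-high call (default 0.5).
#' @return object of class `ec_classifier`.
#' @seealso [predict.ec_classifier()], [cross_validate()]
#' @export
ec_classifier <- function(cn, cluster4, genes, pole = pole_params(),
                          spec = cn_feature_spec(), threshold = 0.5) {
  if (length(cluster4) != length(cn$ploidy)) {
    stop_("cluster4 labels do not match the number of CN profiles")
  }
  y <- factor(ifelse(as.logical(cluster4), "cluster4", "other"),
              levels = c("other", "cluster4"))
  feats <- build_cn_features(cn, genes, spec)
  nb <- fit_gnb(feats$features, y)
  gene_table <- genes[match(feats$selected_genes, genes$gene_id), ,
                      drop = FALSE]
  rownames(gene_table) <- NULL
  structure(
    list(nb = nb, selected_genes = feats$selected_genes,
         gene_table = gene_table, spec = spec,
         pole = pole, threshold = threshold,
         n_train = length(y), n_positive = sum(y == "cluster4")),
    class = "ec_classifier"
  )
}

#' @export
print.ec_classifier <- function(x, ...) {
  cat("Endometrial-cancer molecular subtype classifier\n")
  cat(sprintf(
    "  POLE rule: >%d SNV, C>A rate > %.2f, C>G rate < %.2f\n",
    x$pole$snv_min, x$pole$ca_min, x$pole$cg_max
  ))
  cat("  MSI gate: MSI-high status (score cutoff",
      x$pole$msi_high_threshold, ")\n")
  cat(sprintf(
    "  CN-high: naive Bayes cluster-4 posterior >= %.2f (%d features, %d genes; trained on %d samples, %d positive)\n",
    x$threshold, x$nb$n_features, length(x$selected_genes),
    x$n_train, x$n_positive
  ))
  invisible(x)
}

#' @export
summary.ec_classifier <- function(object, ...) {
  print(object)
  cat("\nNaive Bayes class means of the last two features:\n")
  p <- object$nb$n_features
  print(round(object$nb$mean[, (p - 1):p], 3))
  invisible(object)
}

#' Classify a cohort into the four molecular subtypes
#'
#' Applies the hierarchical cascade sample by sample with strict precedence
#' POLE > MSI > CN-high > CN-low. The sample universes of the three inputs
#' must coincide; a mismatch is an error listing the offending ids. The
#' CN-high posterior is only computed for samples that reach the
#' copy-number stage unless `full_evidence = TRUE`.
#'
#' @param object a fitted [ec_classifier()].
#' @param variants a `somatic_variants` cohort table.
#' @param clinical a `clinical_table`.
#' @param cn a `cn_cohort`.
#' @param full_evidence compute the naive Bayes posterior for every sample
#'   (audit mode); default `FALSE` leaves it `NA` for samples resolved at
#'   the POLE or MSI stage.
#' @param ... unused.
#' @return a `subtype_calls` data frame: `sample`, `subtype`, `snv_count`,
#'   `ca_rate`, `cg_rate`, `msi_high`, `cn_high_posterior`.
#' @export
predict.ec_classifier <- function(object, variants, clinical, cn,
                                  full_evidence = FALSE, ...) {
  sv <- sort(unique(variants$sample))
  sc <- sort(clinical$sample)
  sn <- sort(names(cn$ploidy))
  universe <- sort(unique(c(sv, sc, sn)))
  missing <- lapply(
    list(variants = sv, clinical = sc, `copy-number` = sn),
    function(s) setdiff(universe, s)
  )
  missing <- missing[lengths(missing) > 0]
  if (length(missing)) {
    stop_("sample universes differ; missing from ",
          paste(sprintf("%s: %s", names(missing),
                        sapply(missing, paste, collapse = ",")),
                collapse = "; "))
  }
  spec_tab <- mutation_spectrum(variants, object$pole)
  spec_tab <- spec_tab[match(universe, spec_tab$sample), , drop = FALSE]
  clinical <- clinical[match(universe, clinical$sample), , drop = FALSE]

  pole_flag <- spec_tab$pole
  msi_flag <- rep(NA, length(universe))
  need_msi <- !pole_flag
  if (any(need_msi)) {
    msi_flag[need_msi] <- is_msi_high(clinical[need_msi, , drop = FALSE],
                                      object$pole)
  }
  if (full_evidence && any(pole_flag)) {
    msi_flag[pole_flag] <- tryCatch(
      is_msi_high(clinical[pole_flag, , drop = FALSE], object$pole),
      error = function(e) NA
    )
  }

  posterior <- rep(NA_real_, length(universe))
  need_cn <- if (full_evidence) rep(TRUE, length(universe)) else {
    !pole_flag & !msi_flag %in% TRUE
  }
  if (any(need_cn)) {
    sub <- subset_cn(cn, names(cn$ploidy) %in% universe[need_cn])
    feats <- build_cn_features(sub, genes = object$gene_table,
                               spec = object$spec,
                               selected_genes = object$selected_genes)
    post <- predict(object$nb, feats$features)[, "cluster4"]
    posterior[match(rownames(feats$features), universe)] <- post
  }

  subtype <- ifelse(
    pole_flag, "POLE",
    ifelse(msi_flag %in% TRUE, "MSI",
           ifelse(posterior >= object$threshold, "CN-high", "CN-low"))
  )
  out <- data.frame(
    sample = universe,
    subtype = factor(subtype, levels = SUBTYPES),
    snv_count = spec_tab$n_snv,
    ca_rate = spec_tab$ca_rate,
    cg_rate = spec_tab$cg_rate,
    msi_high = msi_flag,
    cn_high_posterior = posterior,
    stringsAsFactors = FALSE
  )
  if (!full_evidence) {
    out$cn_high_posterior[out$subtype %in% c("POLE", "MSI")] <- NA_real_
  }
  rownames(out) <- NULL
  class(out) <- c("subtype_calls", "data.frame")
  out
}

#' @export
print.subtype_calls <- function(x, ...) {
  cat("Molecular subtype calls for", nrow(x), "samples:\n")
  print(table(x$subtype))
  invisible(x)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Save / load a fitted classifier as versioned JSON
#'
#' The model file stores the naive Bayes parameters, the selected gene
#' list, the feature specification, the POLE-rule thresholds and the
#' CN-high decision threshold as one JSON document with a schema version.
#'
#' @param object a fitted `ec_classifier`.
#' @param path file path for the model JSON.
#' @return `read_ec_model()` returns the restored `ec_classifier`.
#' @export
write_ec_model <- function(object, path) {
  doc <- list(
    schema = "ecsubtype-model", version = MODEL_SCHEMA_VERSION,
    pole = unclass(object$pole),
    spec = unclass(object$spec),
    threshold = object$threshold,
    selected_genes = object$selected_genes,
    gene_table = object$gene_table,
    n_train = object$n_train, n_positive = object$n_positive,
    nb = list(
      levels = object$nb$levels, prior = object$nb$prior,
      mean = object$nb$mean, var = object$nb$var,
      var_floor = object$nb$var_floor,
      feature_names = object$nb$feature_names
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ec_model
#' @export
read_ec_model <- function(path) {
  if (!file.exists(path)) stop_("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (!identical(doc$schema, "ecsubtype-model")) {
    stop_("not an ecsubtype model file: ", path)
  }
  nb <- doc$nb
  mean_m <- as.matrix(nb$mean)
  var_m <- as.matrix(nb$var)
  rownames(mean_m) <- rownames(var_m) <- nb$levels
  colnames(mean_m) <- colnames(var_m) <- nb$feature_names
  structure(
    list(
      nb = structure(
        list(levels = nb$levels, prior = nb$prior, mean = mean_m,
             var = var_m, var_floor = nb$var_floor,
             n_features = ncol(mean_m), feature_names = nb$feature_names),
        class = "gnb"
      ),
      selected_genes = as.character(doc$selected_genes),
      gene_table = as.data.frame(doc$gene_table),
      spec = do.call(cn_feature_spec, doc$spec),
      pole = do.call(pole_params, doc$pole),
      threshold = doc$threshold,
      n_train = doc$n_train, n_positive = doc$n_positive
    ),
    class = "ec_classifier"
  )
}
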