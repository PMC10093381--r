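#' POLE rule parameters
#'
#' Thresholds of the ultramutated-POLE decision rule and the MSI-high score
#' cutoff. A tumor is called POLE when it carries strictly more than
#' `snv_min` somatic SNVs, a C>A fraction strictly above `ca_min`, and a
#' C>G fraction strictly below `cg_max` (all three inequalities strict).
#'
#' @param snv_min minimum SNV burden (exclusive); default 500.
#' @param ca_min minimum C>A fraction (exclusive); default 0.2.
#' @param cg_max maximum C>G fraction (exclusive); default 0.03.
#' @param msi_high_threshold cutoff applied (with `>=`) when MSI status is
#'   a numeric score; default 0.5.
#' @return object of class `pole_params`.
#' @export
pole_params <- function(snv_min = 500, ca_min = 0.2, cg_max = 0.03,
                        msi_high_threshold = 0.5) {
  stopifnot(snv_min >= 0, ca_min >= 0, ca_min <= 1, cg_max >= 0, cg_max <= 1)
  structure(
    list(snv_min = snv_min, ca_min = ca_min, cg_max = cg_max,
         msi_high_threshold = msi_high_threshold),
    class = "pole_params"
  )
}

#' Collapse a substitution to its pyrimidine-centric class
#'
#' Maps each of the 12 ordered base substitutions to one of the six classes
#' C>A, C>G, C>T, T>A, T>C, T>G by reverse-complementing purine-reference
#' changes (e.g. G>T becomes C>A), so both strands of the same somatic event
#' fall in one class.
#'
#' @param ref,alt single-base character vectors (A/C/G/T), `ref != alt`.
#' @return character vector of collapsed classes.
#' @export
#' @examples
#' collapse_substitution(c("C", "G", "A"), c("A", "T", "G"))
collapse_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  base <- c("A", "C", "G", "T")
  if (any(!ref %in% base) || any(!alt %in% base)) {
    stop_("collapse_substitution: alleles must be single bases in A/C/G/T")
  }
  if (any(ref == alt)) stop_("collapse_substitution: ref == alt")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp[ref], ref)
  a <- ifelse(pur, comp[alt], alt)
  paste0(r, ">", a)
}

#' Per-sample substitution spectrum and POLE-rule evidence
#'
#' Counts somatic SNVs per sample into the six pyrimidine-collapsed classes
#' and derives the C>A and C>G fractions used by the POLE rule. Indels and
#' other non-SNV records are ignored. Samples with zero SNVs get both rates
#' 0 (and can never satisfy the POLE rule).
#'
#' @param variants a `somatic_variants` data frame (see
#'   [read_variant_table()]).
#' @param params a [pole_params()] object used for the `pole` flag.
#' @return data frame of class `mutation_spectrum` with one row per sample:
#'   `n_snv`, the six class counts, `ca_rate`, `cg_rate`, `pole`.
#' @export
mutation_spectrum <- function(variants, params = pole_params()) {
  snv <- variants[variants$variant_class == "SNV", , drop = FALSE]
  samples <- sort(unique(variants$sample))
  cls <- if (nrow(snv)) collapse_substitution(snv$ref, snv$alt) else character()
  tab <- table(
    factor(snv$sample, levels = samples),
    factor(cls, levels = SPECTRUM_CLASSES)
  )
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(samples, SPECTRUM_CLASSES))
  n_snv <- rowSums(counts)
  ca <- ifelse(n_snv > 0, counts[, "C>A"] / n_snv, 0)
  cg <- ifelse(n_snv > 0, counts[, "C>G"] / n_snv, 0)
  out <- data.frame(
    sample = samples, n_snv = as.integer(n_snv),
    counts, ca_rate = as.numeric(ca), cg_rate = as.numeric(cg),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out$pole <- is_pole(out, params)
  rownames(out) <- NULL
  class(out) <- c("mutation_spectrum", "data.frame")
  out
}

#' Apply the ultramutated-POLE rule
#'
#' @param spectrum a `mutation_spectrum` data frame (or any data frame with
#'   `n_snv`, `ca_rate`, `cg_rate` columns).
#' @param params a [pole_params()] object.
#' @return logical vector, `TRUE` where the POLE rule holds.
#' @export
is_pole <- function(spectrum, params = pole_params()) {
  spectrum$n_snv > params$snv_min &
    spectrum$ca_rate > params$ca_min &
    spectrum$cg_rate < params$cg_max
}

#' MSI-high gate
#'
#' Categorical status `MSI-high` passes the gate; `MSS` does not; a numeric
#' score passes when `score >= msi_high_threshold`. Unknown status is an
#' error naming the offending sample(s) — the cascade cannot place a
#' non-POLE tumor without an MSI call.
#'
#' @param clinical a `clinical_table` data frame (see [read_clinical()]).
#' @param params a [pole_params()] object (supplies the score threshold).
#' @return logical vector aligned with `clinical` rows.
#' @export
is_msi_high <- function(clinical, params = pole_params()) {
  out <- rep(NA, nrow(clinical))
  score <- clinical$msi_score %||% rep(NA_real_, nrow(clinical))
  has_score <- !is.na(score)
  out[has_score] <- score[has_score] >= params$msi_high_threshold
  out[!has_score & clinical$msi_status == "MSI-high"] <- TRUE
  out[!has_score & clinical$msi_status == "MSS"] <- FALSE
  if (anyNA(out)) {
    stop_("unknown MSI status for sample(s): ",
          paste(clinical$sample[is.na(out)], collapse = ", "))
  }
  out
}
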