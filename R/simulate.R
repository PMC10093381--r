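#' Default per-subtype simulation parameters
#'
#' One parameter block per molecular subtype, emulating the qualitative
#' structure the cascade relies on: a log-normal somatic SNV burden with a
#' subtype-specific substitution spectrum (ultramutated, C>A-skewed POLE;
#' hypermutated but C>T-dominated MSI; quiet CN-low/CN-high), an MSI-high
#' probability, a copy-number profile (segment count, per-segment
#' alteration probability, ploidy), and exponential survival hazards
#' ordered POLE < CN-low < MSI < CN-high so 36-month survival falls near
#' 1.00 / 0.87 / 0.81 / 0.60.
#'
#' The defaults make POLE samples satisfy the POLE rule with probability
#' > 0.99 (median burden 3000 SNV, C>A weight 0.30, C>G weight 0.01) and
#' give CN-high profiles well over five times the altered-genome fraction
#' of CN-low.
#'
#' @return named list of per-subtype parameter lists, class `sim_params`.
#' @export
subtype_sim_params <- function() {
  generic_spectrum <- c(`C>A` = 0.08, `C>G` = 0.05, `C>T` = 0.45,
                        `T>A` = 0.06, `T>C` = 0.30, `T>G` = 0.06)
  pole_spectrum <- c(`C>A` = 0.30, `C>G` = 0.01, `C>T` = 0.40,
                     `T>A` = 0.04, `T>C` = 0.20, `T>G` = 0.05)
  p <- list(
    POLE = list(
      snv_meanlog = log(3000), snv_sdlog = 0.4, spectrum = pole_spectrum,
      msi_high_prob = 0.30, n_segments = 26, alt_prob = 0.05,
      ploidy_mean = 2.0, ploidy_sd = 0.05,
      event_hazard = 0, censor_hazard = 0.012
    ),
    MSI = list(
      snv_meanlog = log(900), snv_sdlog = 0.5, spectrum = generic_spectrum,
      msi_high_prob = 1.00, n_segments = 26, alt_prob = 0.05,
      ploidy_mean = 2.0, ploidy_sd = 0.05,
      event_hazard = -log(0.81) / 36, censor_hazard = 0.012
    ),
    `CN-low` = list(
      snv_meanlog = log(60), snv_sdlog = 0.5, spectrum = generic_spectrum,
      msi_high_prob = 0.00, n_segments = 30, alt_prob = 0.05,
      ploidy_mean = 2.0, ploidy_sd = 0.05,
      event_hazard = -log(0.87) / 36, censor_hazard = 0.012
    ),
    `CN-high` = list(
      snv_meanlog = log(80), snv_sdlog = 0.5, spectrum = generic_spectrum,
      msi_high_prob = 0.00, n_segments = 60, alt_prob = 0.50,
      ploidy_mean = 3.1, ploidy_sd = 0.25,
      event_hazard = -log(0.60) / 36, censor_hazard = 0.012
    )
  )
  for (s in names(p)) {
    stopifnot(abs(sum(p[[s]]$spectrum) - 1) < 1e-12)
  }
  structure(p, class = "sim_params")
}

DEFAULT_PROPORTIONS <- c(POLE = 0.07, MSI = 0.28, `CN-low` = 0.39,
                         `CN-high` = 0.26)

#' Simulate a random gene model
#'
#' Places `n_genes` genes uniformly across the 1-22,X chromosome universe
#' (probability proportional to chromosome length) with log-normal gene
#' lengths around 50 kb.
#'
#' @param n_genes number of genes (default 300).
#' @param seed RNG seed.
#' @return gene model data frame (`gene_id`, `chromosome`, `start`, `end`).
#' @export
simulate_gene_model <- function(n_genes = 300, seed = 1) {
  with_seed(seed, {
    chrom <- sample(CHROMOSOMES, n_genes, replace = TRUE,
                    prob = CHROM_MB / sum(CHROM_MB))
    len <- pmax(1000, round(stats::rlnorm(n_genes, log(5e4), 0.8)))
    start <- sapply(chrom, function(c) {
      sample.int(CHROM_MB[[c]] * 1e6 - 2e6, 1)
    })
    df <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chromosome = chrom, start = as.integer(start),
      end = as.integer(start + len - 1),
      stringsAsFactors = FALSE
    )
    df[order(match(df$chromosome, CHROMOSOMES), df$start), ]
  })
}

#' Simulate a synthetic endometrial-cancer cohort
#'
#' Draws subtype labels from a multinomial with the given proportions and
#' generates, per sample, somatic variant calls (SNVs with the subtype's
#' substitution spectrum plus ~3% indels), a tiling copy-number segment
#' profile with ploidy, MSI status, and exponential survival follow-up.
#' One master seed fans out into independent substreams for labels,
#' variants, copy number and survival, so the stages are individually
#' reproducible.
#'
#' @param n cohort size (default 232).
#' @param proportions subtype proportions (default 7/28/39/26% for
#'   POLE/MSI/CN-low/CN-high).
#' @param params per-subtype parameters from [subtype_sim_params()].
#' @param seed master seed (default 1).
#' @param genes optional gene model to attach (shared between cohorts);
#'   default simulates one with `n_genes` genes.
#' @param n_genes gene model size when `genes` is `NULL`.
#' @return list of class `ec_cohort_sim` with `variants`
#'   (`somatic_variants`), `cn` (`cn_cohort`), `clinical`
#'   (`clinical_table`, including `tcga_subtype` truth and `cn_cluster`),
#'   `labels` (data frame sample/subtype) and `genes`.
#' @export
simulate_cohort <- function(n = 232, proportions = DEFAULT_PROPORTIONS,
                            params = subtype_sim_params(), seed = 1,
                            genes = NULL, n_genes = 300) {
  if (abs(sum(proportions) - 1) > 1e-8) stop_("proportions must sum to 1")
  if (n < 4) stop_("need n >= 4")
  seeds <- substream_seeds(seed, 5)
  labels <- with_seed(seeds[1], {
    sample(names(proportions), n, replace = TRUE, prob = proportions)
  })
  ids <- sprintf("S%04d", seq_len(n))
  if (is.null(genes)) genes <- simulate_gene_model(n_genes, seeds[5])

  variants <- simulate_variants(ids, labels, params, seeds[2])
  cn <- simulate_cn(ids, labels, params, seeds[3])
  clinical <- simulate_clinical(ids, labels, params, seeds[4])

  structure(
    list(variants = variants, cn = cn, clinical = clinical,
         labels = data.frame(sample = ids, subtype = labels,
                             stringsAsFactors = FALSE),
         genes = genes, seed = seed),
    class = "ec_cohort_sim"
  )
}

simulate_variants <- function(ids, labels, params, seed) {
  with_seed(seed, {
    counts <- vapply(labels, function(l) {
      max(0L, as.integer(round(stats::rlnorm(1, params[[l]]$snv_meanlog,
                                             params[[l]]$snv_sdlog))))
    }, integer(1))
    total <- sum(counts)
    sample_col <- rep(ids, counts)
    cls <- unlist(lapply(seq_along(ids), function(i) {
      sample(SPECTRUM_CLASSES, counts[i], replace = TRUE,
             prob = params[[labels[i]]]$spectrum)
    }), use.names = FALSE)
    # emit each event on a random strand so collapsing is exercised
    flip <- stats::runif(total) < 0.5
    ref <- ifelse(flip, chartr("CT", "GA", substr(cls, 1, 1)),
                  substr(cls, 1, 1))
    alt <- ifelse(flip, chartr("ACGT", "TGCA", substr(cls, 3, 3)),
                  substr(cls, 3, 3))
    chrom <- sample(CHROMOSOMES, total, replace = TRUE,
                    prob = CHROM_MB / sum(CHROM_MB))
    pos <- floor(stats::runif(total) * (CHROM_MB[chrom] * 1e6 - 1)) + 1
    df <- data.frame(
      sample = sample_col, chromosome = chrom, position = as.integer(pos),
      ref = ref, alt = alt, stringsAsFactors = FALSE
    )
    # ~3% short indels on top of the SNVs
    n_ind <- round(0.03 * total)
    if (n_ind > 0) {
      ins <- stats::runif(n_ind) < 0.5
      ind <- data.frame(
        sample = sample(ids, n_ind, replace = TRUE,
                        prob = pmax(counts, 1) / sum(pmax(counts, 1))),
        chromosome = sample(CHROMOSOMES, n_ind, replace = TRUE,
                            prob = CHROM_MB / sum(CHROM_MB)),
        position = as.integer(sample.int(5e7, n_ind)),
        ref = ifelse(ins, "C", "CA"),
        alt = ifelse(ins, "CAT", "C"),
        stringsAsFactors = FALSE
      )
      df <- rbind(df, ind)
    }
    df$variant_class <- variant_class(df$ref, df$alt)
    new_somatic_variants(df)
  })
}

simulate_cn <- function(ids, labels, params, seed) {
  with_seed(seed, {
    ploidy <- vapply(labels, function(l) {
      max(1, stats::rnorm(1, params[[l]]$ploidy_mean, params[[l]]$ploidy_sd))
    }, numeric(1))
    names(ploidy) <- ids
    seg_list <- lapply(seq_along(ids), function(i) {
      p <- params[[labels[i]]]
      extra <- max(0, (p$n_segments - length(CHROMOSOMES)) /
                     length(CHROMOSOMES))
      per_chrom <- 1 + stats::rpois(length(CHROMOSOMES), extra)
      chrom <- rep(CHROMOSOMES, per_chrom)
      segs <- do.call(rbind, lapply(seq_along(CHROMOSOMES), function(ci) {
        k <- per_chrom[ci]
        L <- CHROM_MB[[ci]] * 1e6
        cuts <- if (k > 1) sort(sample.int(L - 1, k - 1)) else integer(0)
        data.frame(
          chromosome = CHROMOSOMES[ci],
          start = as.integer(c(1, cuts + 1)),
          end = as.integer(c(cuts, L)),
          stringsAsFactors = FALSE
        )
      }))
      m <- nrow(segs)
      alt <- stats::runif(m) < p$alt_prob
      gain <- alt & stats::runif(m) < 0.5
      loss <- alt & !gain
      pl <- ploidy[[i]]
      cnv <- pl + stats::runif(m, -0.3, 0.3)           # neutral wobble
      cnv[gain] <- pl + stats::runif(sum(gain), 0.7, 2.5)
      cnv[loss] <- pmax(0.2, pl - stats::runif(sum(loss), 0.7, 1.8))
      segs$copy_number <- round(cnv, 3)
      segs$sample <- ids[i]
      segs
    })
    seg <- do.call(rbind, seg_list)
    new_cn_cohort(seg[, c("sample", "chromosome", "start", "end",
                          "copy_number")], ploidy)
  })
}

simulate_clinical <- function(ids, labels, params, seed) {
  with_seed(seed, {
    msi <- vapply(labels, function(l) {
      stats::runif(1) < params[[l]]$msi_high_prob
    }, logical(1))
    surv <- simulate_survival_times(labels, params)
    out <- data.frame(
      sample = ids,
      msi_status = ifelse(msi, "MSI-high", "MSS"),
      msi_score = NA_real_,
      followup_months = surv$time,
      event = surv$event,
      tcga_subtype = labels,
      cn_cluster = ifelse(labels == "CN-high", 4L,
                          sample(1:3, length(ids), replace = TRUE)),
      stringsAsFactors = FALSE
    )
    class(out) <- c("clinical_table", "data.frame")
    out
  })
}

# exponential event and censoring times; follow-up is their minimum
simulate_survival_times <- function(labels, params) {
  n <- length(labels)
  ev_h <- vapply(labels, function(l) params[[l]]$event_hazard, numeric(1))
  ce_h <- vapply(labels, function(l) params[[l]]$censor_hazard, numeric(1))
  t_event <- ifelse(ev_h > 0, stats::rexp(n, pmax(ev_h, 1e-12)), Inf)
  t_cens <- ifelse(ce_h > 0, stats::rexp(n, pmax(ce_h, 1e-12)), Inf)
  time <- pmin(t_event, t_cens)
  if (any(!is.finite(time))) {
    stop_("event and censoring hazards are both zero for some subtype")
  }
  list(time = round(time, 3), event = as.integer(t_event <= t_cens))
}

#' Simulate subtype-dependent survival follow-up
#'
#' Standalone access to the survival stage of the generator: exponential
#' event and censoring times per subtype with follow-up
#' `min(event, censoring)`.
#'
#' @param labels character vector of subtype labels.
#' @param params per-subtype parameters from [subtype_sim_params()].
#' @param seed RNG seed.
#' @return data frame with `followup_months` and `event`.
#' @export
simulate_survival <- function(labels, params = subtype_sim_params(),
                              seed = 1) {
  surv <- with_seed(seed, simulate_survival_times(labels, params))
  data.frame(followup_months = surv$time, event = surv$event)
}

#' @export
print.ec_cohort_sim <- function(x, ...) {
  cat("Synthetic EC cohort:", nrow(x$labels), "samples (seed", x$seed, ")\n")
  print(table(factor(x$labels$subtype, levels = SUBTYPES)))
  cat(nrow(x$variants), "variant calls,", nrow(x$cn$segments),
      "CN segments,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Write a simulated cohort to standard on-disk formats
#'
#' Writes per-sample VCFs (`variants/<sample>.vcf`), a SEG-style segment
#' table with ploidy column (`segments.seg`), the clinical table
#' (`clinical.tsv`), the true labels (`truth.tsv`) and the gene model
#' (`genes.bed`, converted back to 0-based half-open). The files load
#' through the package readers unchanged.
#'
#' @param cohort an `ec_cohort_sim` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "variants"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in cohort$labels$sample) {
    v <- cohort$variants[cohort$variants$sample == id, , drop = FALSE]
    write_minimal_vcf(v, file.path(dir, "variants", paste0(id, ".vcf")), id)
  }
  seg <- cohort$cn$segments
  seg$ploidy <- cohort$cn$ploidy[seg$sample]
  utils::write.table(seg, file.path(dir, "segments.seg"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clin <- cohort$clinical
  utils::write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$labels, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(
    chrom = cohort$genes$chromosome,
    start = cohort$genes$start - 1L,  # back to BED 0-based
    end = cohort$genes$end,
    name = cohort$genes$gene_id
  )
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

write_minimal_vcf <- function(variants, path, sample_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ecsubtype-simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  ), con)
  if (nrow(variants)) {
    v <- variants[order(match(variants$chromosome, CHROMOSOMES),
                        variants$position), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1",
                       v$chromosome, v$position, v$ref, v$alt), con)
  }
  invisible(path)
}
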