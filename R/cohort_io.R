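#' Classify a variant by its alleles
#'
#' Assigns one of `SNV`, `insertion`, `deletion` or `other` from the REF/ALT
#' allele pair. A variant is an SNV iff both alleles are single bases in
#' A/C/G/T and differ; longer ALT than REF is an insertion, shorter a
#' deletion; anything else (MNVs, symbolic alleles) is `other`.
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return character vector of variant classes.
#' @export
#' @examples
#' variant_class(c("C", "CT", "C", "AT"), c("A", "C", "CAA", "GC"))
variant_class <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  base <- c("A", "C", "G", "T")
  out <- rep("other", length(ref))
  snv <- ref %in% base & alt %in% base & ref != alt
  simple <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  out[simple & nchar(alt) > nchar(ref)] <- "insertion"
  out[simple & nchar(alt) < nchar(ref)] <- "deletion"
  out[snv] <- "SNV"
  out
}

new_somatic_variants <- function(df) {
  df <- df[order(df$sample, df$chromosome, df$position, df$ref, df$alt), ,
           drop = FALSE]
  key <- paste(df$sample, df$chromosome, df$position, df$ref, df$alt)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("somatic_variants", "data.frame")
  df
}

#' Read somatic small-variant calls
#'
#' Reads per-sample somatic variant calls from a VCF (v4.x) file or from a
#' minimal MAF-like tab-separated table. Coordinates are kept 1-based.
#' Multi-allelic VCF records are split into one record per ALT allele, a
#' leading `chr` prefix is stripped from chromosome names, records failing
#' the FILTER column (anything other than `PASS` or `.`) are dropped, and
#' duplicate (sample, chromosome, position, ref, alt) entries are collapsed.
#'
#' The TSV dialect needs columns `sample`, `chromosome`, `position`, `ref`,
#' `alt` (MAF-style synonyms such as `Tumor_Sample_Barcode`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2` are accepted)
#' and may carry a `filter` column.
#'
#' @param path path to the variant file.
#' @param dialect `"vcf"` or `"tsv"`; default guessed from the extension.
#' @param sample_id sample identifier for VCF input; defaults to the first
#'   genotype column name, or the file base name for site-only VCFs.
#' @return a `somatic_variants` data frame with columns `sample`,
#'   `chromosome`, `position`, `ref`, `alt`, `variant_class`.
#' @export
read_variant_table <- function(path, dialect = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop_("variant file not found: ", path)
  dialect <- dialect %||%
    (if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv")
  if (!dialect %in% c("vcf", "tsv")) stop_("unknown variant dialect: ", dialect)
  if (dialect == "vcf") {
    read_variants_vcf(path, sample_id)
  } else {
    read_variants_tsv(path)
  }
}

read_variants_vcf <- function(path, sample_id = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_("malformed VCF ", path, ": ", conditionMessage(e))
  )
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    gt_samples <- setdiff(colnames(v@gt), "FORMAT")
    sample_id <- if (length(gt_samples)) {
      gt_samples[1]
    } else {
      tools::file_path_sans_ext(basename(path), compression = TRUE)
    }
  }
  if (nrow(fix) == 0) {
    return(new_somatic_variants(data.frame(
      sample = character(), chromosome = character(), position = integer(),
      ref = character(), alt = character(), variant_class = character(),
      stringsAsFactors = FALSE
    )))
  }
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  fix <- fix[keep, , drop = FALSE]
  # split multi-allelic records: one row per ALT allele
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos) || any(pos < 1)) {
    stop_("non-positive or non-integer POS in ", path, " (line ",
          which(is.na(pos) | pos < 1)[1], " of body)")
  }
  df <- data.frame(
    sample = sample_id,
    chromosome = normalize_chrom(rep(fix$CHROM, n)),
    position = rep(pos, n),
    ref = toupper(rep(fix$REF, n)),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE
  )
  df$variant_class <- variant_class(df$ref, df$alt)
  new_somatic_variants(df)
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- data.frame(
    sample = as.character(
      match_column(df, c("sample", "sample_id", "Tumor_Sample_Barcode"),
                   "sample", path)
    ),
    chromosome = normalize_chrom(
      match_column(df, c("chromosome", "chrom", "chr"), "chromosome", path)
    ),
    position = match_column(df, c("position", "pos", "Start_Position"),
                            "position", path),
    ref = toupper(as.character(
      match_column(df, c("ref", "ref_allele", "Reference_Allele"), "ref", path)
    )),
    alt = toupper(as.character(
      match_column(df, c("alt", "alt_allele", "Tumor_Seq_Allele2"), "alt", path)
    )),
    stringsAsFactors = FALSE
  )
  if (!is.numeric(out$position)) {
    stop_("non-numeric position column in ", path)
  }
  bad <- which(is.na(out$position) | out$position < 1 | is.na(out$sample) |
               out$sample == "")
  if (length(bad)) {
    stop_("malformed variant record in ", path, " at data line ", bad[1])
  }
  out$position <- as.integer(out$position)
  filt <- match_column(df, c("filter", "FILTER"), "filter", path,
                       required = FALSE)
  if (!is.null(filt)) out <- out[is.na(filt) | filt %in% c("PASS", "."), ]
  out$variant_class <- variant_class(out$ref, out$alt)
  new_somatic_variants(out)
}

#' Read a directory or file of variant calls into one cohort table
#'
#' A directory is read as one VCF per sample; a single file is dispatched
#' on its extension via [read_variant_table()].
#'
#' @param path a file or a directory containing `*.vcf` files.
#' @inheritParams read_variant_table
#' @return a `somatic_variants` data frame covering all samples.
#' @export
read_variants <- function(path, dialect = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
    if (!length(files)) stop_("no VCF files found under ", path)
    parts <- lapply(files, read_variant_table, dialect = "vcf")
    new_somatic_variants(do.call(rbind, parts))
  } else {
    read_variant_table(path, dialect = dialect)
  }
}

#' Read per-sample copy-number segment profiles (SEG-style TSV)
#'
#' Expects tab-separated columns `sample` (or `ID`), `chromosome` (`chrom`),
#' `start` (`loc.start`), `end` (`loc.end`) and `copy_number` (`seg.mean`),
#' 1-based inclusive coordinates, plus an optional per-sample `ploidy`
#' column (default 2 when absent). Segments must not overlap within a
#' chromosome of a sample.
#'
#' @param path path to the segment table.
#' @param log2 when `TRUE` the value column holds log2 ratios and is
#'   converted to absolute copy number as `ploidy * 2^value`.
#' @return a `cn_cohort`: list with `segments` (data frame) and `ploidy`
#'   (named numeric vector per sample).
#' @export
read_seg <- function(path, log2 = FALSE) {
  if (!file.exists(path)) stop_("segment file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  seg <- data.frame(
    sample = as.character(match_column(df, c("sample", "sample_id", "ID"),
                                       "sample", path)),
    chromosome = normalize_chrom(
      match_column(df, c("chromosome", "chrom", "chr"), "chromosome", path)
    ),
    start = as.numeric(match_column(df, c("start", "loc.start"), "start", path)),
    end = as.numeric(match_column(df, c("end", "loc.end"), "end", path)),
    copy_number = as.numeric(
      match_column(df, c("copy_number", "seg.mean", "value"), "copy_number",
                   path)
    ),
    stringsAsFactors = FALSE
  )
  ploidy_col <- match_column(df, "ploidy", "ploidy", path, required = FALSE)
  pl <- if (is.null(ploidy_col)) {
    stats::setNames(rep(2, length(unique(seg$sample))), unique(seg$sample))
  } else {
    p <- tapply(as.numeric(ploidy_col), seg$sample, function(x) x[1])
    stats::setNames(as.numeric(p), names(p))
  }
  if (log2) seg$copy_number <- pl[seg$sample] * 2^seg$copy_number
  new_cn_cohort(seg, pl)
}

new_cn_cohort <- function(segments, ploidy) {
  if (any(is.na(segments$start)) || any(is.na(segments$end))) {
    stop_("non-numeric segment coordinates")
  }
  bad <- which(segments$start > segments$end)
  if (length(bad)) {
    stop_("segment start > end for sample ", segments$sample[bad[1]],
          " at ", segments$chromosome[bad[1]], ":", segments$start[bad[1]])
  }
  if (any(is.na(segments$copy_number) | segments$copy_number < 0)) {
    stop_("negative or missing copy number in segment table")
  }
  if (any(is.na(ploidy) | ploidy <= 0)) stop_("ploidy must be positive")
  segments <- segments[order(segments$sample, segments$chromosome,
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  # overlap check within each sample x chromosome (segments now sorted)
  grp <- paste(segments$sample, segments$chromosome)
  same <- grp[-1] == grp[-length(grp)]
  if (nrow(segments) > 1) {
    ov <- which(same & segments$start[-1] <= segments$end[-nrow(segments)])
    if (length(ov)) {
      stop_("overlapping segments for sample ", segments$sample[ov[1] + 1],
            " on chromosome ", segments$chromosome[ov[1] + 1])
    }
  }
  missing_pl <- setdiff(unique(segments$sample), names(ploidy))
  if (length(missing_pl)) {
    ploidy <- c(ploidy, stats::setNames(rep(2, length(missing_pl)), missing_pl))
  }
  ploidy <- ploidy[order(names(ploidy))]
  structure(list(segments = segments, ploidy = ploidy), class = "cn_cohort")
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat("Copy-number cohort:", length(x$ploidy), "samples,",
      nrow(x$segments), "segments\n")
  cat("Mean ploidy:", round(mean(x$ploidy), 2), "\n")
  invisible(x)
}

MSI_HIGH_LABELS <- c("msi-high", "msi-h", "msi high", "msi_high", "high")
MSS_LABELS <- c("mss", "msi-low", "msi-l", "msi low", "msi_low",
                "stable", "mss/msi-low", "low")

#' Read the clinical/MSI table
#'
#' Tab-separated with header; columns `sample`, `msi_status` (categorical
#' labels or a numeric score in `[0, 1]`), `followup_months`, `event`
#' (1 = progression/death observed, 0 = censored) and optionally
#' `tcga_subtype` (one of POLE, MSI, CN-low, CN-high) and `cn_cluster`
#' (1-4). MSI labels are normalised to `MSI-high` / `MSS` / `unknown`;
#' numeric scores are kept in `msi_score` and thresholded later by the
#' classifier.
#'
#' @param path path to the clinical table.
#' @return data frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_("clinical file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- data.frame(
    sample = as.character(match_column(df, c("sample", "sample_id"),
                                       "sample", path)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample)) {
    stop_("duplicate sample_id in ", path, ": ",
          out$sample[anyDuplicated(out$sample)])
  }
  msi_raw <- match_column(df, c("msi_status", "msi", "msi_score"),
                          "msi_status", path, required = FALSE)
  if (is.null(msi_raw)) {
    out$msi_status <- "unknown"
    out$msi_score <- NA_real_
  } else if (is.numeric(msi_raw)) {
    if (any(msi_raw < 0 | msi_raw > 1, na.rm = TRUE)) {
      stop_("numeric msi score outside [0, 1] in ", path)
    }
    out$msi_score <- msi_raw
    out$msi_status <- ifelse(is.na(msi_raw), "unknown", "score")
  } else {
    low <- tolower(trimws(as.character(msi_raw)))
    out$msi_status <- ifelse(
      low %in% MSI_HIGH_LABELS, "MSI-high",
      ifelse(low %in% MSS_LABELS, "MSS", "unknown")
    )
    out$msi_score <- suppressWarnings(as.numeric(msi_raw))
    out$msi_status[!is.na(out$msi_score)] <- "score"
  }
  fu <- match_column(df, c("followup_months", "followup", "time"),
                     "followup_months", path, required = FALSE)
  if (!is.null(fu)) {
    fu <- as.numeric(fu)
    if (any(fu < 0, na.rm = TRUE)) {
      stop_("negative followup_months in ", path, " for sample ",
            out$sample[which(fu < 0)[1]])
    }
    out$followup_months <- fu
    ev <- match_column(df, c("event", "status"), "event", path,
                       required = FALSE)
    out$event <- if (is.null(ev)) NA_integer_ else as.integer(as.logical(
      ifelse(ev %in% c("0", "1", 0, 1, TRUE, FALSE), as.integer(ev), NA)
    ))
  }
  st <- match_column(df, c("tcga_subtype", "subtype"), "tcga_subtype", path,
                     required = FALSE)
  if (!is.null(st)) {
    st <- as.character(st)
    st[is.na(st) | st == ""] <- NA
    bad <- stats::na.omit(setdiff(unique(st), SUBTYPES))
    if (length(bad)) stop_("unknown subtype label(s) in ", path, ": ",
                           paste(bad, collapse = ", "))
    out$tcga_subtype <- st
  }
  cl <- match_column(df, "cn_cluster", "cn_cluster", path, required = FALSE)
  if (!is.null(cl)) {
    cl <- as.integer(cl)
    if (any(!cl %in% c(NA, 1:4))) stop_("cn_cluster must be 1-4 in ", path)
    out$cn_cluster <- cl
  }
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Read a gene model from BED
#'
#' BED intervals (0-based, half-open) are converted on read to the package's
#' internal 1-based inclusive convention; column 4 supplies gene ids.
#'
#' @param path path to a BED file (>= 4 columns, no header).
#' @return data frame with `gene_id`, `chromosome`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop_("gene model file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (nrow(df) == 0 || ncol(df) < 4) {
    stop_("gene model BED needs >= 4 columns (chrom, start, end, name): ",
          path)
  }
  out <- data.frame(
    gene_id = as.character(df[[4]]),
    chromosome = normalize_chrom(df[[1]]),
    start = as.integer(df[[2]]) + 1L,  # BED 0-based start -> 1-based
    end = as.integer(df[[3]]),         # half-open end == inclusive end
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop_("empty or negative gene interval in ", path)
  if (anyDuplicated(out$gene_id)) stop_("duplicate gene_id in ", path)
  out
}

#' Write / read subtype calls
#'
#' `write_calls()` writes one tab-separated row per sample with the assigned
#' subtype and its evidence trail (`snv_count`, `ca_rate`, `cg_rate`,
#' `msi_high`, `cn_high_posterior`); numeric evidence is written at 6
#' decimals and round-trips losslessly through `read_calls()`.
#'
#' @param calls a `subtype_calls` data frame from [predict.ec_classifier()].
#' @param path output path.
#' @return `write_calls()` returns `path` invisibly.
#' @export
write_calls <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0) stop_("no subtype calls to write")
  out <- calls
  for (col in c("ca_rate", "cg_rate", "cn_high_posterior")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], digits = 6, format = "f"))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_("cannot write calls to ", path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop_("calls file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$subtype <- factor(df$subtype, levels = SUBTYPES)
  if (anyNA(df$subtype)) stop_("unknown subtype label in ", path)
  for (col in c("ca_rate", "cg_rate", "cn_high_posterior")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$msi_high <- as.logical(df$msi_high)
  class(df) <- c("subtype_calls", "data.frame")
  df
}
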