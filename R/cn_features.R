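#' Copy-number feature specification
#'
#' Parameters of the segment-to-feature engineering behind the CN-cluster-4
#' model. A segment is a gain when its absolute copy number is at least
#' `gain_margin` above the sample ploidy and a loss when at least
#' `loss_margin` below it; per-gene gain/loss counts are built for the
#' `top_k_genes` most frequently altered genes of the training set; the
#' altered-length feature divides total altered bases by
#' `genome_mb * 1e6`.
#'
#' @param gain_margin,loss_margin copy-number margins around ploidy
#'   (default 0.5 each).
#' @param top_k_genes number of most-altered genes to keep (default 25).
#' @param genome_mb genome size in megabases (default 3100).
#' @return object of class `cn_feature_spec`.
#' @export
cn_feature_spec <- function(gain_margin = 0.5, loss_margin = 0.5,
                            top_k_genes = 25, genome_mb = 3100) {
  stopifnot(gain_margin > 0, loss_margin > 0, top_k_genes >= 1, genome_mb > 0)
  structure(
    list(gain_margin = gain_margin, loss_margin = loss_margin,
         top_k_genes = as.integer(top_k_genes), genome_mb = genome_mb),
    class = "cn_feature_spec"
  )
}

#' Call a segment gain / loss / neutral relative to ploidy
#'
#' @param copy_number numeric vector of absolute segment copy numbers.
#' @param ploidy sample ploidy (scalar or vector recycled per segment).
#' @param spec a [cn_feature_spec()].
#' @return character vector in `{gain, loss, neutral}`.
#' @export
call_gain_loss <- function(copy_number, ploidy, spec = cn_feature_spec()) {
  ifelse(copy_number >= ploidy + spec$gain_margin, "gain",
         ifelse(copy_number <= ploidy - spec$loss_margin, "loss", "neutral"))
}

# segments data frame augmented with per-segment calls for one cohort
segment_calls <- function(cn, spec) {
  seg <- cn$segments
  seg$call <- call_gain_loss(seg$copy_number, cn$ploidy[seg$sample], spec)
  seg
}

count_by <- function(seg, key_levels, key) {
  g <- table(factor(key[seg$call == "gain"], levels = key_levels))
  l <- table(factor(key[seg$call == "loss"], levels = key_levels))
  cbind(gain = as.integer(g), loss = as.integer(l))
}

#' Per-sample gain/loss segment counts
#'
#' @param cn a `cn_cohort` (see [read_seg()]).
#' @param spec a [cn_feature_spec()].
#' @return data frame with `sample`, `n_gain`, `n_loss`.
#' @export
sample_counts <- function(cn, spec = cn_feature_spec()) {
  seg <- segment_calls(cn, spec)
  samples <- names(cn$ploidy)
  m <- count_by(seg, samples, seg$sample)
  data.frame(sample = samples, n_gain = m[, "gain"], n_loss = m[, "loss"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-chromosome gain/loss segment counts for one cohort
#'
#' The chromosome universe is fixed to 1-22 and X so that feature ordering
#' is stable; chromosomes absent from a profile report zero counts and an
#' unknown chromosome name is an error.
#'
#' @inheritParams sample_counts
#' @return 3-dimensional array `[sample, chromosome, gain/loss]`.
#' @export
chromosome_counts <- function(cn, spec = cn_feature_spec()) {
  seg <- segment_calls(cn, spec)
  bad <- setdiff(unique(seg$chromosome), CHROMOSOMES)
  if (length(bad)) {
    stop_("chromosome(s) outside the 1-22,X universe: ",
          paste(bad, collapse = ", "))
  }
  samples <- names(cn$ploidy)
  out <- array(
    0L, dim = c(length(samples), length(CHROMOSOMES), 2),
    dimnames = list(samples, CHROMOSOMES, c("gain", "loss"))
  )
  for (what in c("gain", "loss")) {
    s <- seg[seg$call == what, , drop = FALSE]
    t <- table(factor(s$sample, levels = samples),
               factor(s$chromosome, levels = CHROMOSOMES))
    out[, , what] <- as.integer(t)
  }
  out
}

# per-sample x per-gene matrices of gain/loss overlap counts (>=1 bp,
# 1-based inclusive on both sides); the workhorse behind gene features
# and top-gene selection.
gene_overlap_counts <- function(cn, genes, spec) {
  if (is.null(genes) || nrow(genes) == 0) stop_("empty gene model")
  seg <- segment_calls(cn, spec)
  seg <- seg[seg$call != "neutral", , drop = FALSE]
  samples <- names(cn$ploidy)
  out <- list(
    gain = matrix(0L, length(samples), nrow(genes),
                  dimnames = list(samples, genes$gene_id)),
    loss = matrix(0L, length(samples), nrow(genes),
                  dimnames = list(samples, genes$gene_id))
  )
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    s <- seg[seg$chromosome == chr, , drop = FALSE]
    if (nrow(s) == 0) next
    # overlap iff seg.start <= gene.end and seg.end >= gene.start
    ov <- outer(s$start, g$end, `<=`) & outer(s$end, g$start, `>=`)
    for (what in c("gain", "loss")) {
      rows <- s$call == what
      if (!any(rows)) next
      hits <- ov[rows, , drop = FALSE]
      cnt <- rowsum(hits + 0L, group = s$sample[rows])
      out[[what]][rownames(cnt), g$gene_id] <-
        out[[what]][rownames(cnt), g$gene_id] + cnt
    }
  }
  out
}

#' Select the most frequently copy-number-altered genes
#'
#' Ranks genes by the fraction of (training) samples in which the gene
#' overlaps at least one gain or loss segment, breaks ties by genomic order
#' (chromosome, start, gene_id), drops never-altered genes, and returns at
#' most `spec$top_k_genes` gene ids. Must be run on training samples only;
#' [build_cn_features()] accepts the result for held-out data.
#'
#' @param cn a `cn_cohort` of training profiles.
#' @param genes gene model data frame (see [read_gene_bed()]).
#' @param spec a [cn_feature_spec()].
#' @return character vector of selected gene ids (frequency order).
#' @export
select_top_genes <- function(cn, genes, spec = cn_feature_spec()) {
  oc <- gene_overlap_counts(cn, genes, spec)
  altered <- (oc$gain + oc$loss) > 0
  freq <- colMeans(altered)
  chr_idx <- match(genes$chromosome, CHROMOSOMES)
  ord <- order(-freq, chr_idx, genes$start, genes$gene_id)
  keep <- ord[freq[ord] > 0]
  genes$gene_id[utils::head(keep, spec$top_k_genes)]
}

#' Build the copy-number feature matrix
#'
#' Assembles, per sample and in a fixed reproducible order, the feature
#' vector of the CN-cluster-4 model: gain and loss segment counts per
#' sample, per chromosome (1-22, X), and per selected gene, followed by
#' ploidy and the altered-genome length per megabase.
#'
#' @param cn a `cn_cohort`.
#' @param genes gene model data frame.
#' @param spec a [cn_feature_spec()].
#' @param selected_genes gene ids from [select_top_genes()]; when `NULL`
#'   (training mode) selection is run on `cn` itself. Pass the training
#'   list explicitly for held-out samples — the function never re-selects
#'   when a list is supplied.
#' @return object of class `cn_features`: list with `features` (numeric
#'   matrix, samples x features) and `selected_genes`.
#' @export
build_cn_features <- function(cn, genes, spec = cn_feature_spec(),
                              selected_genes = NULL) {
  if (is.null(selected_genes)) {
    selected_genes <- select_top_genes(cn, genes, spec)
  }
  samples <- names(cn$ploidy)
  sc <- sample_counts(cn, spec)
  cc <- chromosome_counts(cn, spec)
  oc <- gene_overlap_counts(cn, genes, spec)
  chr_block <- matrix(0L, length(samples), 2 * length(CHROMOSOMES))
  chr_block[, seq(1, ncol(chr_block), 2)] <- cc[, , "gain"]
  chr_block[, seq(2, ncol(chr_block), 2)] <- cc[, , "loss"]
  colnames(chr_block) <- as.vector(rbind(paste0("chr", CHROMOSOMES, "_gain"),
                                         paste0("chr", CHROMOSOMES, "_loss")))
  gene_block <- matrix(0L, length(samples), 2 * length(selected_genes))
  if (length(selected_genes)) {
    gene_block[, seq(1, ncol(gene_block), 2)] <-
      oc$gain[, selected_genes, drop = FALSE]
    gene_block[, seq(2, ncol(gene_block), 2)] <-
      oc$loss[, selected_genes, drop = FALSE]
    colnames(gene_block) <- as.vector(rbind(paste0(selected_genes, "_gain"),
                                            paste0(selected_genes, "_loss")))
  }
  feats <- cbind(
    n_gain = sc$n_gain, n_loss = sc$n_loss,
    chr_block, gene_block,
    ploidy = as.numeric(cn$ploidy[samples]),
    altered_per_mb = altered_length_per_mb(cn, spec)
  )
  rownames(feats) <- samples
  structure(list(features = feats, selected_genes = selected_genes,
                 spec = spec),
            class = "cn_features")
}

#' Altered genome length per megabase
#'
#' Sum of the lengths (`end - start + 1`) of all gain/loss segments of a
#' sample, divided by `genome_mb * 1e6`: the fraction of the genome with a
#' copy-number alteration.
#'
#' @inheritParams sample_counts
#' @return named numeric vector per sample.
#' @export
altered_length_per_mb <- function(cn, spec = cn_feature_spec()) {
  seg <- segment_calls(cn, spec)
  alt <- seg[seg$call != "neutral", , drop = FALSE]
  len <- tapply(alt$end - alt$start + 1,
                factor(alt$sample, levels = names(cn$ploidy)), sum)
  out <- ifelse(is.na(len), 0, len) / (spec$genome_mb * 1e6)
  stats::setNames(as.numeric(out), names(cn$ploidy))
}

#' @export
print.cn_features <- function(x, ...) {
  cat("CN feature matrix:", nrow(x$features), "samples x",
      ncol(x$features), "features\n")
  cat("Selected genes (", length(x$selected_genes), "): ",
      paste(utils::head(x$selected_genes, 8), collapse = ", "),
      if (length(x$selected_genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
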