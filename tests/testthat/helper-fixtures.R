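# Fixture builders shared across test files; everything is generated in
# code so no binary or large data lives in the repository.

write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    lines
  ), path)
  path
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small in-memory cn_cohort: seg_df needs sample/chromosome/start/end/
# copy_number; ploidy defaults to 2 for every sample
make_cn <- function(seg_df, ploidy = NULL) {
  p <- write_tsv(if (is.null(ploidy)) seg_df else
    cbind(seg_df, ploidy = ploidy[seg_df$sample]))
  read_seg(p)
}

seg_row <- function(sample, chromosome, start, end, copy_number) {
  data.frame(sample = sample, chromosome = chromosome, start = start,
             end = end, copy_number = copy_number,
             stringsAsFactors = FALSE)
}

tiny_gene_model <- function() {
  data.frame(
    gene_id = c("GA", "GB", "GC"),
    chromosome = c("1", "1", "2"),
    start = c(100L, 5000L, 100L),
    end = c(1000L, 6000L, 2000L),
    stringsAsFactors = FALSE
  )
}

# Table-style reference confusion matrix of the published 232-sample
# cohort comparison (rows = multi-platform reference, cols = WES cascade)
published_concordance <- function() {
  m <- matrix(
    c(17, 0, 0, 0,
      0, 58, 6, 1,
      0, 0, 80, 10,
      0, 0, 9, 51),
    nrow = 4, byrow = TRUE,
    dimnames = list(reference = c("POLE", "MSI", "CN-low", "CN-high"),
                    predicted = c("POLE", "MSI", "CN-low", "CN-high"))
  )
  class(m) <- c("confusion_matrix", class(m))
  m
}
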