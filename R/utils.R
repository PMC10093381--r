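# Internal helpers shared across modules.

# Chromosome universe for endometrial cancer cohorts: autosomes + X, no Y.
CHROMOSOMES <- c(as.character(1:22), "X")

# Approximate chromosome lengths in megabases (GRCh38 scale); used only by
# the synthetic cohort generator to place segments, genes and variants.
CHROM_MB <- c(
  248, 242, 198, 190, 182, 171, 159, 145, 138, 134,
  135, 133, 114, 107, 102, 90, 83, 80, 59, 64, 47, 51, 156
)
names(CHROM_MB) <- CHROMOSOMES

SUBTYPES <- c("POLE", "MSI", "CN-low", "CN-high")

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[x == "23"] <- "X"
  x
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Derive independent substream seeds (< 2^31) from one master seed.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half away from zero at `digits` decimals (base round() is half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_ <- function(...) stop(..., call. = FALSE)

# Column lookup tolerant to a few common header synonyms.
match_column <- function(df, aliases, what, path, required = TRUE) {
  hit <- which(tolower(names(df)) %in% tolower(aliases))
  if (length(hit) == 0) {
    if (!required) return(NULL)
    stop_(sprintf(
      "column '%s' not found in %s (accepted names: %s)",
      what, path, paste(aliases, collapse = ", ")
    ))
  }
  df[[hit[1]]]
}
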