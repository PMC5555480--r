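# Shared toy universe (small: 1 chromosome, 8 tRNAs, 4 families).
toy <- function(seed = 7L, ...) {
  make_toy_reference(fixture_spec(seed = seed, ...))
}

chrom_lengths <- function(genome) vapply(genome, nchar, integer(1))

# Independent reverse-complement oracle (no Biostrings).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# Brute-force per-base overlap oracle for window matching.
oracle_match <- function(pred_start, pred_end, tsd_start, tsd_end, window) {
  if (identical(window, "exact")) {
    return(pred_start == tsd_start && pred_end == tsd_end)
  }
  lo <- max(tsd_start - window, 0)
  hi <- tsd_end + window
  if (hi <= lo) return(FALSE)
  target <- lo:(hi - 1)
  pred <- pred_start:(pred_end - 1)
  any(pred %in% target)
}

# Uniform random predictions over a genome, one per sample id given.
random_predictions <- function(n, chrom_lens, families, method = "rand",
                              len = 5L) {
  ci <- sample.int(length(chrom_lens), n, replace = TRUE,
                   prob = chrom_lens / sum(chrom_lens))
  start <- as.integer(floor(runif(n) * (chrom_lens[ci] - len)))
  standard_predictions(data.frame(
    chrom = names(chrom_lens)[ci], start = start, end = start + len,
    family = sample(families, n, replace = TRUE),
    category = "nonreference",
    sample_id = sprintf("s%05d", seq_len(n)),
    method = method, evidence = "sr", strand = ".",
    stringsAsFactors = FALSE
  ))
}
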