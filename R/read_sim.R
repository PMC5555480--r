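#' Paired-end library parameters
#'
#' Defaults mirror the yeast resequencing design the benchmark
#' emulates: 101-base reads, 300-bp insert with 42-bp standard
#' deviation, 100-fold coverage, 1% per-base substitution error.
#'
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size mean and
#'   standard deviation in bp.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param coverage Target fold coverage (> 0).
#' @param seed Integer RNG seed.
#' @return List of validated parameters (class `library_params`).
#' @export
library_params <- function(read_len = 101L, insert_mean = 300L,
                           insert_sd = 42L, error_rate = 0.01,
                           coverage = 100, seed = 1L) {
  stopifnot(read_len >= 1L, insert_mean > 0, insert_sd >= 0,
            error_rate >= 0, error_rate < 1, coverage > 0)
  structure(
    list(read_len = as.integer(read_len),
         insert_mean = insert_mean, insert_sd = insert_sd,
         error_rate = error_rate, coverage = coverage,
         seed = as.integer(seed)),
    class = "library_params"
  )
}

#' Number of read pairs needed for a target mean depth
#'
#' `ceiling(genome_len * coverage / (2 * read_len))`, so realized mean
#' depth lies in `[coverage, coverage + 2 * read_len / genome_len)`.
#'
#' @param genome_len Total genome length in bp.
#' @param params [library_params()].
#' @return Integer pair count.
#' @export
compute_pair_count <- function(genome_len, params = library_params()) {
  if (genome_len < 2 * params$read_len) {
    stop("genome shorter than one read-pair footprint")
  }
  as.integer(ceiling(genome_len * params$coverage / (2 * params$read_len)))
}

# Substitute bases in-place with probability `rate` per base; each
# substituted base becomes one of the three other nucleotides uniformly
# (N always substitutes into A/C/G/T). Returns the mutated sequences.
apply_substitutions <- function(seqs, read_len, rate) {
  if (rate <= 0 || !length(seqs)) {
    return(seqs)
  }
  k <- stats::rbinom(length(seqs), read_len, rate)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(read_len, k[i])
    for (p in pos) {
      alt <- setdiff(bases, chars[p])
      chars[p] <- alt[sample.int(length(alt), 1L)]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a genome
#'
#' A wgsim-style simulator sufficient for this benchmark: fragments are
#' placed uniformly (chromosomes chosen length-weighted), fragment
#' length is drawn `Normal(insert_mean, insert_sd)`, rounded, and
#' truncated to `[2 * read_len, chrom_len]`; each fragment is assigned
#' a strand with probability 1/2. Read 1 is the 5' `read_len` bases of
#' the fragment and read 2 the reverse complement of its 3' `read_len`
#' bases (roles swap on minus-strand fragments, so read 2 is always
#' oriented opposite read 1). Each base substitutes independently with
#' probability `error_rate`; quality is the constant symbol `I`.
#' Chromosomes shorter than one pair footprint are skipped with a
#' warning. Output is deterministic given the seed in `params`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param params [library_params()]; `params$seed` seeds the RNG.
#' @param n_pairs Number of pairs; defaults to
#'   [compute_pair_count()] on the total genome length.
#' @return List of class `read_sim` with `read1`, `read2` (character
#'   vectors), `names` (pair names), `placements` (data.frame `pair`,
#'   `chrom`, `frag_start`, `frag_end`, `strand`; 0-based half-open)
#'   and `params`.
#' @export
simulate_read_pairs <- function(genome, params = library_params(),
                                n_pairs = NULL) {
  L <- params$read_len
  lens <- vapply(genome, nchar, integer(1))
  usable <- lens >= 2L * L
  if (any(!usable)) {
    warning("skipping chromosome(s) shorter than one pair footprint: ",
            paste(names(genome)[!usable], collapse = ", "))
  }
  genome <- genome[usable]
  lens <- lens[usable]
  if (!length(genome)) {
    stop("no usable chromosomes")
  }
  if (is.null(n_pairs)) {
    n_pairs <- compute_pair_count(sum(lens), params)
  }
  set.seed(params$seed)
  ci <- sample.int(length(genome), n_pairs, replace = TRUE,
                   prob = lens / sum(lens))
  clen <- lens[ci]
  frag <- as.integer(round(stats::rnorm(n_pairs, params$insert_mean,
                                        params$insert_sd)))
  frag <- pmin(pmax(frag, 2L * L), clen)
  start <- as.integer(floor(stats::runif(n_pairs) * (clen - frag + 1)))
  strand <- ifelse(stats::runif(n_pairs) < 0.5, "+", "-")
  left <- right <- character(n_pairs)
  for (j in seq_along(genome)) {
    idx <- which(ci == j)
    if (!length(idx)) next
    s <- genome[[j]]
    left[idx] <- substring(s, start[idx] + 1L, start[idx] + L)
    right[idx] <- substring(s, start[idx] + frag[idx] - L + 1L,
                            start[idx] + frag[idx])
  }
  right_rc <- dna_revcomp(right)
  plus <- strand == "+"
  read1 <- ifelse(plus, left, right_rc)
  read2 <- ifelse(plus, right_rc, left)
  read1 <- apply_substitutions(read1, L, params$error_rate)
  read2 <- apply_substitutions(read2, L, params$error_rate)
  placements <- data.frame(
    pair = seq_len(n_pairs),
    chrom = names(genome)[ci],
    frag_start = start,
    frag_end = start + frag,
    strand = strand,
    stringsAsFactors = FALSE
  )
  nm <- sprintf("%s_%d_%d_%s_%d", placements$chrom, start, start + frag,
                strand, seq_len(n_pairs))
  structure(
    list(read1 = read1, read2 = read2, names = nm,
         placements = placements, params = params),
    class = "read_sim"
  )
}

#' Write a simulated library to FASTQ files and a placement log
#'
#' Emits `<prefix>_1.fastq` and `<prefix>_2.fastq` with constant
#' quality `I`, and `<prefix>_placements.tsv` recording the true origin
#' of every pair.
#'
#' @param sim Result of [simulate_read_pairs()].
#' @param prefix Output path prefix.
#' @return Character vector of the three paths written, invisibly.
#' @export
write_read_pairs <- function(sim, prefix) {
  qual <- strrep("I", sim$params$read_len)
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  fq <- function(reads, mate, path) {
    lines <- as.vector(rbind(paste0("@", sim$names, "/", mate),
                             reads, "+", qual))
    writeLines(lines, path)
  }
  fq(sim$read1, 1L, p1)
  fq(sim$read2, 2L, p2)
  p3 <- paste0(prefix, "_placements.tsv")
  utils::write.table(sim$placements, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}

# Reconstruct the error-free reads a placement implies.
true_reads_from_placements <- function(placements, genome, read_len) {
  L <- read_len
  left <- right <- character(nrow(placements))
  for (ch in unique(placements$chrom)) {
    idx <- which(placements$chrom == ch)
    s <- genome[[ch]]
    a <- placements$frag_start[idx]
    b <- placements$frag_end[idx]
    left[idx] <- substring(s, a + 1L, a + L)
    right[idx] <- substring(s, b - L + 1L, b)
  }
  right_rc <- dna_revcomp(right)
  plus <- placements$strand == "+"
  list(read1 = ifelse(plus, left, right_rc),
       read2 = ifelse(plus, right_rc, left))
}

#' Empirical substitution rate of a simulated library
#'
#' Reconstructs the error-free reads from the placement log and the
#' source genome, and counts mismatching bases in the emitted reads.
#'
#' @param sim Result of [simulate_read_pairs()].
#' @param genome The genome the library was simulated from.
#' @return List with `mismatches`, `total` (bases) and `rate`.
#' @export
empirical_error_rate <- function(sim, genome) {
  truth <- true_reads_from_placements(sim$placements, genome,
                                      sim$params$read_len)
  count_mm <- function(obs, exp) {
    sum(vapply(seq_along(obs), function(i) {
      sum(charToRaw(obs[i]) != charToRaw(exp[i]))
    }, integer(1)))
  }
  mm <- count_mm(sim$read1, truth$read1) + count_mm(sim$read2, truth$read2)
  total <- 2L * length(sim$read1) * sim$params$read_len
  list(mismatches = mm, total = total, rate = mm / total)
}
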