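#' Specification for a synthetic test universe
#'
#' Defines a fully synthetic miniature of the benchmark's input world:
#' a random genome with annotated tRNA genes (mixed strands), a
#' canonical TE library, TE copies embedded in the reference, and the
#' instance-to-family hierarchy. tRNA loci are spaced so that insertion
#' and evaluation windows never overlap, which keeps truth bookkeeping
#' exact. With `similar_family_pair`, the first two families share an
#' identical terminal repeat but differ internally, emulating family
#' pairs (such as yeast Ty1/Ty2) that share a nearly identical LTR —
#' the hard case for family assignment.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_trna Number of tRNA genes (strands alternate).
#' @param n_families Number of canonical TE families, named `Ty1..`;
#'   `Ty3` (when present) gets the proximal offset rule.
#' @param te_len Canonical TE length in bp.
#' @param n_reference_copies Number of TE copies embedded in the
#'   reference genome.
#' @param similar_family_pair Give families 1 and 2 a shared terminal
#'   repeat?
#' @param feature_gap Minimum clearance around each feature in bp.
#' @param seed RNG seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chroms = 1L, chrom_len = 100000L, n_trna = 8L,
                         n_families = 4L, te_len = 400L,
                         n_reference_copies = 4L,
                         similar_family_pair = TRUE,
                         feature_gap = 1600L, seed = 1L) {
  stopifnot(n_chroms >= 1L, chrom_len >= 1000L, n_trna >= 1L,
            n_families >= 1L, te_len >= 50L, n_reference_copies >= 0L,
            feature_gap >= 300L)
  structure(
    list(n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
         n_trna = as.integer(n_trna), n_families = as.integer(n_families),
         te_len = as.integer(te_len),
         n_reference_copies = as.integer(n_reference_copies),
         similar_family_pair = isTRUE(similar_family_pair),
         feature_gap = as.integer(feature_gap), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference universe
#'
#' Deterministic for a fixed seed. Features are laid out sequentially
#' with `feature_gap` clearance, tRNAs first (72 bp, alternating
#' strands), then reference TE copies (canonical family sequences,
#' alternating strands), distributed round-robin over chromosomes.
#'
#' @param spec A [fixture_spec()].
#' @return List with `genome` (named character vector), `trna`
#'   (annotation data.frame), `te_library` (named character vector of
#'   canonical sequences), `reference_tes` (annotation data.frame of
#'   embedded copies) and `hierarchy` (named character vector,
#'   instance -> family).
#' @export
make_toy_reference <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  fam_names <- paste0("Ty", seq_len(spec$n_families))
  te_library <- character(spec$n_families)
  if (spec$similar_family_pair && spec$n_families >= 2L) {
    ltr <- random_dna(80L)
    internal_len <- spec$te_len - 160L
    stopifnot(internal_len >= 10L)
    te_library[1L] <- paste0(ltr, random_dna(internal_len), ltr)
    te_library[2L] <- paste0(ltr, random_dna(internal_len), ltr)
    if (spec$n_families > 2L) {
      te_library[3:spec$n_families] <-
        vapply(3:spec$n_families, function(i) random_dna(spec$te_len), "")
    }
  } else {
    te_library <- vapply(seq_len(spec$n_families),
                         function(i) random_dna(spec$te_len), "")
  }
  names(te_library) <- fam_names

  chrom_names <- paste0("chr", utils::as.roman(seq_len(spec$n_chroms)))
  genome <- stats::setNames(
    vapply(seq_len(spec$n_chroms), function(i) random_dna(spec$chrom_len), ""),
    chrom_names
  )

  trna_len <- 72L
  gap <- spec$feature_gap
  cursor <- stats::setNames(rep(gap, spec$n_chroms), chrom_names)
  place <- function(chrom, width) {
    a <- cursor[[chrom]]
    b <- a + width
    if (b + gap > spec$chrom_len) {
      stop("infeasible packing: chromosome ", chrom, " too short for the ",
           "requested features")
    }
    cursor[[chrom]] <<- b + gap
    c(a, b)
  }
  trna <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), name = character(0), stringsAsFactors = FALSE
  )
  for (i in seq_len(spec$n_trna)) {
    chrom <- chrom_names[((i - 1L) %% spec$n_chroms) + 1L]
    ab <- place(chrom, trna_len)
    trna[i, ] <- list(chrom, as.integer(ab[1L]), as.integer(ab[2L]),
                      if (i %% 2L == 1L) "+" else "-",
                      sprintf("trna%02d", i))
  }
  reference_tes <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), name = character(0), stringsAsFactors = FALSE
  )
  hierarchy <- character(0)
  if (spec$n_reference_copies > 0L) {
    for (i in seq_len(spec$n_reference_copies)) {
      chrom <- chrom_names[((i - 1L) %% spec$n_chroms) + 1L]
      fam <- fam_names[((i - 1L) %% spec$n_families) + 1L]
      ab <- place(chrom, nchar(te_library[[fam]]))
      strand <- if (i %% 2L == 1L) "+" else "-"
      inst <- sprintf("%s-%d", fam, i)
      reference_tes[i, ] <- list(chrom, as.integer(ab[1L]),
                                 as.integer(ab[2L]), strand, inst)
      seq <- if (strand == "-") dna_revcomp(te_library[[fam]]) else
        te_library[[fam]]
      substr(genome[[chrom]], ab[1L] + 1L, ab[2L]) <- seq
      hierarchy[inst] <- fam
    }
  }
  trna$type <- rep("tRNA_gene", nrow(trna))
  reference_tes$type <- rep("transposable_element", nrow(reference_tes))
  list(genome = genome, trna = trna, te_library = te_library,
       reference_tes = reference_tes, hierarchy = hierarchy)
}

#' Write a toy reference universe to disk
#'
#' Emits `genome.fasta`, `te_library.fasta`, `trna.gff`,
#' `reference_tes.gff` and `hierarchy.tsv` under `dir`.
#'
#' @param fixture Result of [make_toy_reference()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_toy_reference <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    te_library = file.path(dir, "te_library.fasta"),
    trna = file.path(dir, "trna.gff"),
    reference_tes = file.path(dir, "reference_tes.gff"),
    hierarchy = file.path(dir, "hierarchy.tsv")
  )
  write_fasta(fixture$genome, paths[["genome"]])
  write_fasta(fixture$te_library, paths[["te_library"]])
  write_gff_features(fixture$trna, paths[["trna"]])
  write_gff_features(fixture$reference_tes, paths[["reference_tes"]])
  write_hierarchy(fixture$hierarchy, paths[["hierarchy"]])
  invisible(paths)
}

#' Behavioural profile of a mock TE caller
#'
#' Mock callers operate on the truth manifest and emulate behaviours
#' real callers exhibit: imperfect detection, Gaussian positional
#' jitter, a constant directional shift, systematic under- or
#' over-calling of the TSD length, uniform false positives, and family
#' confusion. They exist to exercise the evaluation machinery with
#' known parameters that must be recoverable from its outputs.
#'
#' @param method Method name stamped on every prediction.
#' @param p_detect Detection probability per truth insertion; either a
#'   scalar or a named vector by family.
#' @param pos_error_sd SD in bp of Gaussian positional jitter (0 for
#'   exact).
#' @param shift Constant directional shift in bp (positive = 3').
#' @param tsd_bias Bp added to the predicted TSD length (negative =
#'   under-call; length floors at 1).
#' @param fp_rate Poisson mean of false predictions per sample.
#' @param family_confusion Row-stochastic matrix (true family x called
#'   family), or `NULL` for no confusion.
#' @param evidence `"sr"` or `"rp"`.
#' @return List of class `mock_caller_profile`.
#' @export
mock_caller_profile <- function(method = "mock", p_detect = 1,
                                pos_error_sd = 0, shift = 0L,
                                tsd_bias = 0L, fp_rate = 0,
                                family_confusion = NULL,
                                evidence = c("sr", "rp")) {
  evidence <- match.arg(evidence)
  stopifnot(all(p_detect >= 0), all(p_detect <= 1), pos_error_sd >= 0,
            fp_rate >= 0)
  if (!is.null(family_confusion)) {
    stopifnot(is.matrix(family_confusion),
              all(abs(rowSums(family_confusion) - 1) < 1e-8))
  }
  structure(
    list(method = method, p_detect = p_detect,
         pos_error_sd = pos_error_sd, shift = as.integer(shift),
         tsd_bias = as.integer(tsd_bias), fp_rate = fp_rate,
         family_confusion = family_confusion, evidence = evidence),
    class = "mock_caller_profile"
  )
}

#' Generate mock-caller predictions from a truth manifest
#'
#' Per truth insertion, with probability `p_detect` a prediction is
#' emitted at the TSD shifted by the positional jitter plus the
#' directional shift, with length `tsd_len + tsd_bias` (floored at 1)
#' and a family drawn from the confusion row; per sample,
#' `Poisson(fp_rate)` false predictions are added at uniform random
#' loci. Deterministic for a fixed seed.
#'
#' @param truths Truth manifest from [generate_sample_set()].
#' @param profile A [mock_caller_profile()].
#' @param chrom_lens Named integer vector of chromosome lengths (for
#'   false-positive placement).
#' @param seed RNG seed.
#' @return Standardized prediction table.
#' @export
make_mock_predictions <- function(truths, profile, chrom_lens,
                                  seed = 1L) {
  set.seed(seed)
  fams <- sort(unique(truths$family))
  p_det <- profile$p_detect
  if (is.null(names(p_det))) {
    p_det <- stats::setNames(rep_len(p_det, length(fams)), fams)
  }
  rows <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, , drop = FALSE]
    if (stats::runif(1) < p_det[[tr$family]]) {
      jitter <- if (profile$pos_error_sd > 0) {
        as.integer(round(stats::rnorm(1, 0, profile$pos_error_sd)))
      } else 0L
      start <- max(0L, tr$start + jitter + profile$shift)
      len <- max(1L, (tr$end - tr$start) + profile$tsd_bias)
      fam <- tr$family
      if (!is.null(profile$family_confusion)) {
        row <- profile$family_confusion[tr$family, ]
        fam <- sample(colnames(profile$family_confusion), 1L, prob = row)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tr$chrom, start = start, end = start + len,
        family = fam, category = "nonreference", sample_id = tr$sample_id,
        method = profile$method, evidence = profile$evidence,
        strand = ".", stringsAsFactors = FALSE
      )
    }
    n_fp <- stats::rpois(1, profile$fp_rate)
    if (n_fp > 0L) {
      ci <- sample.int(length(chrom_lens), n_fp, replace = TRUE,
                       prob = chrom_lens / sum(chrom_lens))
      len <- max(1L, (tr$end - tr$start) + profile$tsd_bias)
      start <- as.integer(floor(stats::runif(n_fp) *
                                  (chrom_lens[ci] - len)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(chrom_lens)[ci], start = start, end = start + len,
        family = sample(fams, n_fp, replace = TRUE),
        category = "nonreference", sample_id = tr$sample_id,
        method = profile$method, evidence = profile$evidence,
        strand = ".", stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(standard_predictions())
  }
  standard_predictions(do.call(rbind, rows))
}
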