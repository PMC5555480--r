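#' Mean prediction coverage around a set of anchors
#'
#' Computes a metaplot: per-position mean prediction coverage in a
#' window around each anchor, in anchor orientation. Two anchor uses
#' are supported by the same mechanism:
#'
#' * TSD mode: anchors are the truth TSDs of a single-insertion strand
#'   batch (one per sample, `sample_id` set, `strand` = the batch's TE
#'   genome strand). Only the anchor's own sample's predictions
#'   contribute, and minus-strand batches are flipped left-right so
#'   both batches are comparable on one axis.
#' * tRNA mode: anchors are tRNA transcription starts (1-bp intervals,
#'   `strand` = tRNA orientation, no `sample_id`); all predictions
#'   contribute and minus-strand anchors are flipped.
#'
#' In `indicator` mode a position covered by at least one prediction of
#' a sample contributes 1 for that sample, so single-insertion profiles
#' are bounded by 1 (1 = perfect prediction in every sample); in
#' `multiplicity` mode every covering prediction contributes and values
#' may exceed 1. Window positions beyond a chromosome edge contribute
#' nothing and the denominator is unchanged.
#'
#' @param predictions Standardized prediction table (pre-filter
#'   recurrent false positives with [recurrent_site_filter()] if
#'   desired).
#' @param anchors data.frame with `chrom`, `start`, `end`, `strand`,
#'   and optionally `sample_id`; all anchors must share one width.
#' @param flank_up,flank_down Flank sizes (bp) upstream/downstream of
#'   the anchor in anchor orientation; a symmetric `flank` may be given
#'   instead.
#' @param mode `"indicator"` or `"multiplicity"`.
#' @param denominator `"samples"` (TSD mode; divides by
#'   `n_samples`) or `"anchors"`.
#' @param n_samples Number of samples for the `samples` denominator;
#'   defaults to the number of anchors.
#' @return data.frame with `offset` (bp relative to the anchor start,
#'   oriented; 0 = first anchor base) and `value`.
#' @export
anchored_profile <- function(predictions, anchors, flank = NULL,
                             flank_up = flank, flank_down = flank,
                             mode = c("indicator", "multiplicity"),
                             denominator = c("samples", "anchors"),
                             n_samples = NULL) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  predictions <- standard_predictions(predictions)
  stopifnot(nrow(anchors) > 0L, !is.null(flank_up), !is.null(flank_down))
  widths <- anchors$end - anchors$start
  stopifnot(length(unique(widths)) == 1L)
  alen <- widths[1L]
  vlen <- flank_up + alen + flank_down
  per_sample <- "sample_id" %in% names(anchors)
  total <- numeric(vlen)
  for (i in seq_len(nrow(anchors))) {
    an <- anchors[i, , drop = FALSE]
    minus <- identical(an$strand, "-")
    # genome-coordinate window; upstream flank sits right of the anchor
    # on the minus strand
    win_lo <- if (minus) an$start - flank_down else an$start - flank_up
    win_hi <- if (minus) an$end + flank_up else an$end + flank_down
    ps <- predictions
    if (per_sample) {
      ps <- ps[ps$sample_id == an$sample_id, , drop = FALSE]
    }
    ps <- ps[ps$chrom == an$chrom & ps$start < win_hi & ps$end > win_lo, ,
             drop = FALSE]
    if (!nrow(ps)) next
    acc <- numeric(vlen)
    for (s in unique(ps$sample_id)) {
      pss <- ps[ps$sample_id == s, , drop = FALSE]
      v <- numeric(vlen)
      for (r in seq_len(nrow(pss))) {
        lo <- max(pss$start[r], win_lo) - win_lo
        hi <- min(pss$end[r], win_hi) - win_lo
        v[(lo + 1L):hi] <- v[(lo + 1L):hi] + 1
      }
      if (mode == "indicator") v <- pmin(v, 1)
      acc <- acc + v
    }
    if (minus) acc <- rev(acc)
    total <- total + acc
  }
  denom <- if (denominator == "anchors") {
    nrow(anchors)
  } else if (!is.null(n_samples)) {
    n_samples
  } else {
    nrow(anchors)
  }
  data.frame(offset = seq_len(vlen) - flank_up - 1L, value = total / denom)
}

#' Predicted TSD length distribution per family
#'
#' For split-read-class predictions the interval length is the
#' predicted TSD length. With `unique_sites_only`, predictions
#' identical on `(chrom, start, end, family)` across samples count
#' once; calls at nearly the same location but with different lengths
#' are distinct sites and count separately.
#'
#' @param predictions Standardized prediction table (split-read class).
#' @param unique_sites_only Collapse identical sites across samples?
#' @return data.frame with `family`, `length`, `count`.
#' @export
tsd_length_histogram <- function(predictions, unique_sites_only = TRUE) {
  predictions <- standard_predictions(predictions)
  if (unique_sites_only) {
    key <- paste(predictions$chrom, predictions$start, predictions$end,
                 predictions$family, sep = "\r")
    predictions <- predictions[!duplicated(key), , drop = FALSE]
  }
  len <- predictions$end - predictions$start
  tab <- table(predictions$family, len)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("family", "length", "count")
  df$length <- as.integer(df$length)
  df$count <- as.integer(df$count)
  df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(df$family, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' tRNA-region windows in genome coordinates
#'
#' The region spans `upstream` bp upstream and `downstream` bp
#' downstream of the tRNA transcription start, in tRNA orientation:
#' `[tss - upstream, tss + downstream)` for a plus-strand tRNA and the
#' mirror image for a minus-strand one. Each window has length
#' `upstream + downstream`.
#'
#' @param trna_genes tRNA annotation data.frame.
#' @param upstream,downstream Extent in bp (defaults 1000 and 500).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `name`.
#' @export
trna_region_windows <- function(trna_genes, upstream = 1000L,
                                downstream = 500L) {
  stopifnot(upstream >= 0L, downstream >= 0L,
            all(trna_genes$strand %in% c("+", "-")))
  tss <- trna_tss(trna_genes)
  plus <- trna_genes$strand == "+"
  data.frame(
    chrom = trna_genes$chrom,
    start = as.integer(ifelse(plus, tss - upstream, tss - downstream + 1L)),
    end = as.integer(ifelse(plus, tss + downstream, tss + upstream + 1L)),
    strand = trna_genes$strand,
    name = trna_genes$name,
    stringsAsFactors = FALSE
  )
}

#' Per-family counts of predictions in tRNA regions
#'
#' A prediction is in a tRNA region when any part of it overlaps a
#' window from [trna_region_windows()]; membership counts once per
#' prediction even when it overlaps several regions, but insertions
#' present in more than one sample are counted independently.
#'
#' @param predictions Standardized nonreference prediction table.
#' @param trna_genes tRNA annotation.
#' @param upstream,downstream Window extent in bp.
#' @return data.frame with `family`, `in_region`, `total`, `percent`.
#' @export
trna_region_table <- function(predictions, trna_genes, upstream = 1000L,
                              downstream = 500L) {
  predictions <- standard_predictions(predictions)
  win <- trna_region_windows(trna_genes, upstream, downstream)
  in_region <- logical(nrow(predictions))
  for (i in seq_len(nrow(win))) {
    in_region <- in_region |
      (predictions$chrom == win$chrom[i] &
         predictions$start < win$end[i] &
         predictions$end > win$start[i])
  }
  fams <- sort(unique(predictions$family))
  df <- data.frame(
    family = fams,
    in_region = vapply(fams, function(f) {
      sum(in_region[predictions$family == f])
    }, integer(1)),
    total = vapply(fams, function(f) {
      sum(predictions$family == f)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  df$percent <- ifelse(df$total > 0L, 100 * df$in_region / df$total, NA_real_)
  rownames(df) <- NULL
  df
}

#' Expected proportion of uniformly random insertions in anchor windows
#'
#' `n_anchors * window_len / genome_len`, assuming non-overlapping
#' windows. Values above 1 are clamped with a warning. The value is
#' returned as a fraction of 1.
#'
#' @param n_anchors Number of anchor windows (e.g. tRNA genes).
#' @param window_len Window length in bp.
#' @param genome_len Genome length in bp.
#' @return Expected fraction in `[0, 1]`.
#' @export
expected_random_proportion <- function(n_anchors, window_len, genome_len) {
  stopifnot(n_anchors > 0, window_len > 0, genome_len > 0)
  p <- n_anchors * window_len / genome_len
  if (p > 1) {
    warning("window expectation exceeds 1; clamped")
    p <- 1
  }
  p
}

#' Write a per-position vector as bedGraph
#'
#' Adjacent positions with equal value are merged into one interval;
#' zero runs are emitted too, so the vector round-trips exactly through
#' [read_bedgraph()]. The output is suitable for external conversion
#' to bigWig with `wigToBigWig`.
#'
#' @param values Numeric vector of per-position values.
#' @param chrom Chromosome name for the output records.
#' @param path Output path.
#' @param offset 0-based coordinate of `values[1]`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, chrom, path, offset = 0L) {
  stopifnot(all(is.finite(values)))
  if (!length(values)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  r <- rle(values)
  end <- offset + cumsum(r$lengths)
  start <- end - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end,
                     format(r$values, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a vector
#'
#' @param path bedGraph path.
#' @return List with `chrom`, `offset` and `values`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(list(chrom = NA_character_, offset = 0L, values = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  end <- vapply(parts, function(p) as.integer(p[3L]), integer(1))
  val <- vapply(parts, function(p) as.numeric(p[4L]), numeric(1))
  list(chrom = parts[[1L]][1L], offset = start[1L],
       values = rep(val, end - start))
}
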