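#' Does a prediction match a truth TSD at a threshold?
#'
#' Window semantics follow `bedtools window`: at a numeric window `w`
#' the prediction is correct when any part of its interval intersects
#' `[tsd_start - w, tsd_end + w)` by at least 1 bp (the lower bound is
#' clipped at 0). At `window = "exact"` the prediction interval must
#' equal the TSD exactly. When `family_required`, both sides are
#' resolved through the hierarchy to canonical families and must agree.
#' Orientation is never consulted.
#'
#' @param pred_chrom,pred_start,pred_end Prediction interval(s),
#'   0-based half-open; vectors are recycled against each other.
#' @param truth_chrom,truth_start,truth_end Truth TSD interval.
#' @param window `"exact"` or a non-negative number of bp.
#' @param pred_family,truth_family Families, required when
#'   `family_required`.
#' @param family_required Require the correct family?
#' @param hierarchy Optional instance-to-family map for
#'   [resolve_family()].
#' @return Logical vector.
#' @export
match_prediction <- function(pred_chrom, pred_start, pred_end,
                             truth_chrom, truth_start, truth_end,
                             window, pred_family = NULL,
                             truth_family = NULL,
                             family_required = TRUE,
                             hierarchy = NULL) {
  ok <- pred_chrom == truth_chrom
  if (identical(window, "exact")) {
    ok <- ok & pred_start == truth_start & pred_end == truth_end
  } else {
    w <- as.numeric(window)
    stopifnot(w >= 0)
    lo <- pmax(truth_start - w, 0)
    hi <- truth_end + w
    ok <- ok & pred_start < hi & pred_end > lo
  }
  if (family_required) {
    stopifnot(!is.null(pred_family), !is.null(truth_family))
    ok <- ok & resolve_family(pred_family, hierarchy) ==
      resolve_family(truth_family, hierarchy)
  }
  ok
}

#' Score a single-insertion sample batch at accuracy thresholds
#'
#' For every sample, nonreference predictions of the scoring method are
#' matched against the sample's single truth TSD at each threshold
#' (exact, then symmetric windows). Two statistics are computed per
#' sample and threshold: the raw count of matching predictions, and the
#' same capped at 1 ("was the insertion found"). The summary reports
#' per-(method, strand-batch) means across samples; the capped mean is
#' the headline statistic, bounded by 1, where 1 means a correct
#' prediction in every sample. Samples with no prediction records count
#' as zero predictions.
#'
#' @param predictions Standardized prediction table (may span methods).
#' @param truths Truth manifest from [generate_sample_set()]; one row
#'   per sample.
#' @param windows Threshold set; default `list("exact", 100, 300, 500)`.
#' @param family_required Require the correct family (default `TRUE`)?
#' @param hierarchy Optional instance-to-family map.
#' @return List with `summary` (per method and strand: `n_samples`,
#'   `mean_reference`, `mean_nonreference`, and per window
#'   `correct_<w>` capped and `raw_<w>` uncapped means) and `detail`
#'   (per sample and method counts).
#' @export
score_sample_set <- function(predictions, truths,
                             windows = list("exact", 100, 300, 500),
                             family_required = TRUE, hierarchy = NULL) {
  predictions <- standard_predictions(predictions)
  stopifnot(!anyDuplicated(truths$sample_id))
  methods <- sort(unique(predictions$method))
  if (!length(methods)) {
    methods <- "none"
  }
  wlab <- vapply(windows, function(w) {
    if (identical(w, "exact")) "exact" else format(w)
  }, "")
  detail <- list()
  for (m in methods) {
    pm <- predictions[predictions$method == m, , drop = FALSE]
    for (i in seq_len(nrow(truths))) {
      tr <- truths[i, , drop = FALSE]
      ps <- pm[pm$sample_id == tr$sample_id, , drop = FALSE]
      nonref <- ps[ps$category == "nonreference", , drop = FALSE]
      row <- data.frame(
        method = m, sample_id = tr$sample_id, te_strand = tr$te_strand,
        n_reference = sum(ps$category == "reference"),
        n_nonreference = nrow(nonref),
        stringsAsFactors = FALSE
      )
      for (k in seq_along(windows)) {
        n_match <- if (nrow(nonref)) {
          sum(match_prediction(
            nonref$chrom, nonref$start, nonref$end,
            tr$chrom, tr$start, tr$end, windows[[k]],
            nonref$family, tr$family,
            family_required = family_required, hierarchy = hierarchy
          ))
        } else 0L
        row[[paste0("raw_", wlab[k])]] <- n_match
        row[[paste0("correct_", wlab[k])]] <- min(n_match, 1L)
      }
      detail[[length(detail) + 1L]] <- row
    }
  }
  detail <- do.call(rbind, detail)
  groups <- unique(detail[, c("method", "te_strand")])
  summ <- list()
  stat_cols <- c("n_reference", "n_nonreference",
                 paste0("correct_", wlab), paste0("raw_", wlab))
  for (i in seq_len(nrow(groups))) {
    sel <- detail$method == groups$method[i] &
      detail$te_strand == groups$te_strand[i]
    row <- data.frame(
      method = groups$method[i], te_strand = groups$te_strand[i],
      n_samples = sum(sel), stringsAsFactors = FALSE
    )
    means <- colMeans(detail[sel, stat_cols, drop = FALSE])
    names(means) <- sub("^n_", "mean_", names(means))
    row <- cbind(row, as.data.frame(as.list(means)))
    summ[[i]] <- row
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(summary = summary, detail = detail)
}

#' Flag and remove recurrent nonreference sites across samples
#'
#' In a single-insertion batch every true site is unique to one sample,
#' so a nonreference prediction recurring at the same location (keyed
#' by method, chrom, start, end, family) in multiple samples marks a
#' likely false positive. Reference predictions are untouched.
#'
#' The filter presumes every truth site is unique to one sample. When a
#' design places insertions at the same sites in two strand batches,
#' apply the filter separately within each batch.
#'
#' @param predictions Standardized prediction table.
#' @param min_samples Minimum number of distinct samples for a site to
#'   be flagged (default 2, i.e. "multiple samples").
#' @return List with `kept` (predictions minus flagged nonreference
#'   records) and `flagged_sites` (data.frame of sites with their
#'   sample counts).
#' @export
recurrent_site_filter <- function(predictions, min_samples = 2L) {
  predictions <- standard_predictions(predictions)
  nonref <- predictions$category == "nonreference"
  key <- paste(predictions$method, predictions$chrom, predictions$start,
               predictions$end, predictions$family, sep = "\r")
  key[!nonref] <- NA
  tab <- tapply(predictions$sample_id[nonref], key[nonref],
                function(s) length(unique(s)))
  flagged_keys <- names(tab)[tab >= min_samples]
  drop <- !is.na(key) & key %in% flagged_keys
  flagged_sites <- unique(predictions[drop, c("method", "chrom", "start",
                                              "end", "family")])
  if (nrow(flagged_sites)) {
    fk <- paste(flagged_sites$method, flagged_sites$chrom,
                flagged_sites$start, flagged_sites$end,
                flagged_sites$family, sep = "\r")
    flagged_sites$n_samples <- as.integer(tab[fk])
    rownames(flagged_sites) <- NULL
  } else {
    flagged_sites$n_samples <- integer(0)
  }
  list(kept = predictions[!drop, , drop = FALSE],
       flagged_sites = flagged_sites)
}

#' Per-method correctness windows for concordance analysis
#'
#' Split-read-class methods are held to direct overlap with the TSD
#' (window 0); read-pair-class methods with coarser resolution get
#' 100-bp or 500-bp windows. Family and orientation are not consulted
#' in concordance scoring.
#'
#' @param methods Character vector of method names.
#' @param windows Numeric vector of windows (bp), recycled.
#' @return data.frame with `method` and `window` columns.
#' @export
concordance_config <- function(methods, windows = 0) {
  data.frame(method = methods,
             window = as.numeric(rep_len(windows, length(methods))),
             stringsAsFactors = FALSE)
}

#' Cross-method concordance (Venn) counts
#'
#' For every sample, each method is scored correct or not under its own
#' window (family-agnostic); samples are then tallied by the exact
#' subset of methods that were correct. All `2^k` regions, including
#' "none", are reported, and the counts total the number of samples.
#'
#' @param predictions Standardized prediction table spanning methods.
#' @param truths Truth manifest, one row per sample.
#' @param config [concordance_config()] assigning each method a window.
#' @return List with `regions` (data.frame `region`, `count`; region
#'   labels are `&`-joined sorted method names, `"none"` for no
#'   method) and `per_sample` (logical matrix, samples x methods).
#' @export
concordance_sets <- function(predictions, truths, config) {
  predictions <- standard_predictions(predictions)
  stopifnot(!anyDuplicated(truths$sample_id))
  methods <- config$method
  correct <- matrix(FALSE, nrow(truths), length(methods),
                    dimnames = list(truths$sample_id, methods))
  for (j in seq_along(methods)) {
    w <- config$window[j]
    pm <- predictions[predictions$method == methods[j] &
                        predictions$category == "nonreference", ,
                      drop = FALSE]
    if (!nrow(pm)) next
    for (i in seq_len(nrow(truths))) {
      tr <- truths[i, , drop = FALSE]
      ps <- pm[pm$sample_id == tr$sample_id, , drop = FALSE]
      if (!nrow(ps)) next
      correct[i, j] <- any(match_prediction(
        ps$chrom, ps$start, ps$end, tr$chrom, tr$start, tr$end,
        window = w, family_required = FALSE
      ))
    }
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(methods)))
  names(subsets) <- methods
  label <- apply(subsets, 1L, function(b) {
    if (!any(b)) "none" else paste(sort(methods[b]), collapse = "&")
  })
  sample_label <- apply(correct, 1L, function(b) {
    if (!any(b)) "none" else paste(sort(methods[b]), collapse = "&")
  })
  count <- as.integer(table(factor(sample_label, levels = label)))
  regions <- data.frame(region = label, count = count,
                        stringsAsFactors = FALSE)
  list(regions = regions, per_sample = correct)
}

#' Signed offsets of nonreference predictions from their sample's truth
#'
#' For each nonreference prediction, `start - tsd_start` of the truth
#' record of the same sample (NA when the sample has no truth or the
#' chromosome differs). Useful for recovering a caller's positional
#' error distribution.
#'
#' @param predictions Standardized prediction table.
#' @param truths Truth manifest.
#' @return Integer vector of offsets, one per nonreference prediction.
#' @export
prediction_offsets <- function(predictions, truths) {
  predictions <- standard_predictions(predictions)
  nonref <- predictions[predictions$category == "nonreference", ,
                        drop = FALSE]
  idx <- match(nonref$sample_id, truths$sample_id)
  off <- nonref$start - truths$start[idx]
  off[is.na(idx) | nonref$chrom != truths$chrom[idx]] <- NA_integer_
  off
}
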