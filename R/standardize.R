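#' Construct or validate a standardized prediction table
#'
#' The standardized prediction is the package's central record: one TE
#' call in reference coordinates, carrying the canonical family, whether
#' the call is a nonreference insertion or a reference TE, the sample
#' and method that produced it, and the evidence class (`sr` split-read,
#' `rp` read-pair, or `nonab` for a reference TE called non-absent).
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `family`, `category` (`"nonreference"` or
#'   `"reference"`), `sample_id`, `method`, `evidence` and optionally
#'   `strand` (default `"."`) and `score` (constant 0). Missing from a
#'   call, an empty table is returned.
#' @return Validated data.frame with all nine columns in canonical
#'   order.
#' @export
standard_predictions <- function(df = NULL) {
  cols <- c("chrom", "start", "end", "family", "category", "sample_id",
            "method", "evidence", "strand", "score")
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      family = character(0), category = character(0),
      sample_id = character(0), method = character(0),
      evidence = character(0), strand = character(0), score = integer(0),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  if (!"strand" %in% names(df)) df$strand <- "."
  if (!"score" %in% names(df)) df$score <- 0L
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("prediction table lacks columns: ", paste(missing, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 0L) || any(df$end <= df$start)) {
    stop("prediction intervals must satisfy 0 <= start < end")
  }
  if (!all(df$category %in% c("nonreference", "reference"))) {
    stop("category must be 'nonreference' or 'reference'")
  }
  if (!all(df$evidence %in% c("sr", "rp", "nonab"))) {
    stop("evidence must be one of 'sr', 'rp', 'nonab'")
  }
  if (any(df$evidence == "nonab" & df$category != "reference")) {
    stop("evidence 'nonab' is only valid for reference-category records")
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be '+', '-' or '.'")
  }
  rownames(df) <- NULL
  df[, cols]
}

# Components are joined with "_"; a component already containing the
# delimiter would make the name ambiguous, so it is sanitized to "-".
sanitize_component <- function(x, what) {
  bad <- grepl("_", x, fixed = TRUE)
  if (any(bad)) {
    message("sanitizing '_' to '-' in ", what, ": ",
            paste(unique(x[bad]), collapse = ", "))
    x <- gsub("_", "-", x, fixed = TRUE)
  }
  x
}

#' Compose the standardized BED name field
#'
#' Grammar: `<family>_<category>_<sample>_<method>_<evidence>` where the
#' category is spelled `non-reference` or `reference`. Components
#' containing the `_` delimiter are sanitized to `-` with a message.
#'
#' @param family,category,sample_id,method,evidence Component vectors
#'   (recycled to a common length). `category` uses the internal
#'   spelling `"nonreference"`/`"reference"`.
#' @return Character vector of name fields.
#' @seealso [parse_prediction_name()] for the inverse.
#' @export
make_prediction_name <- function(family, category, sample_id, method,
                                 evidence) {
  stopifnot(all(category %in% c("nonreference", "reference")))
  cat_lit <- ifelse(category == "nonreference", "non-reference", "reference")
  paste(
    sanitize_component(family, "family"),
    cat_lit,
    sanitize_component(sample_id, "sample_id"),
    sanitize_component(method, "method"),
    evidence,
    sep = "_"
  )
}

#' Parse a standardized BED name field
#'
#' @param name A single name field produced by [make_prediction_name()].
#' @return Named list with `family`, `category` (internal spelling),
#'   `sample_id`, `method`, `evidence`.
#' @export
parse_prediction_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 5L) {
    stop("name '", name, "' does not have five '_'-delimited components")
  }
  if (!parts[2L] %in% c("non-reference", "reference")) {
    stop("name '", name, "' has unknown category '", parts[2L], "'")
  }
  if (!parts[5L] %in% c("sr", "rp", "nonab")) {
    stop("name '", name, "' has unknown evidence code '", parts[5L], "'")
  }
  list(
    family = parts[1L],
    category = if (parts[2L] == "non-reference") "nonreference" else "reference",
    sample_id = parts[3L],
    method = parts[4L],
    evidence = parts[5L]
  )
}

#' Remove redundant records within one method's results
#'
#' Redundancy removal happens within each sample's result file for one
#' method: records identical on `(sample, chrom, start, end, family,
#' category)` collapse to one, keeping the first in input order, except
#' that when both `sr` and `rp` duplicates of one call exist the
#' split-read record is retained (split-read evidence is base-pair
#' accurate; read-pair evidence is not). Redundancy is never removed
#' across methods or across samples.
#'
#' @param predictions Prediction table; all records must share one
#'   method.
#' @return Deduplicated prediction table, order-stable.
#' @export
deduplicate_within_method <- function(predictions) {
  predictions <- standard_predictions(predictions)
  if (nrow(predictions) == 0L) {
    return(predictions)
  }
  if (length(unique(predictions$method)) > 1L) {
    stop("deduplicate_within_method expects records from a single method")
  }
  key <- paste(predictions$sample_id, predictions$chrom,
               predictions$start, predictions$end,
               predictions$family, predictions$category, sep = "\r")
  # prefer sr within each key, then input order
  pref <- match(predictions$evidence, c("sr", "rp", "nonab"))
  o <- order(match(key, unique(key)), pref, seq_len(nrow(predictions)))
  predictions <- predictions[o, , drop = FALSE]
  key <- key[o]
  out <- predictions[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split predictions on augmented TE chromosomes from the main results
#'
#' Reference genomes can be augmented with extra "chromosomes" made of
#' TE sequences; calls landing on those belong in a
#' `non-ref_chromosome_results` bucket, not the standard results.
#'
#' @param predictions Prediction table.
#' @param augmented_chrom_names Character vector of added chromosome
#'   names.
#' @return List with `main` and `non_ref_chromosome_results` tables; a
#'   disjoint exhaustive partition of the input.
#' @export
partition_augmented <- function(predictions, augmented_chrom_names) {
  predictions <- standard_predictions(predictions)
  on_aug <- predictions$chrom %in% augmented_chrom_names
  list(
    main = predictions[!on_aug, , drop = FALSE],
    non_ref_chromosome_results = predictions[on_aug, , drop = FALSE]
  )
}

#' Annotate strand of reference-TE calls from the reference annotation
#'
#' Reference-category records with strand `"."` gain the annotated
#' strand when a reference TE with identical coordinates exists in the
#' annotation; all other records are untouched.
#'
#' @param predictions Prediction table.
#' @param reference_annotation data.frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), e.g. from [read_gff_features()].
#' @return Prediction table with strands filled in where possible.
#' @export
annotate_reference_strand <- function(predictions, reference_annotation) {
  predictions <- standard_predictions(predictions)
  if (nrow(predictions) == 0L || nrow(reference_annotation) == 0L) {
    return(predictions)
  }
  key_pred <- paste(predictions$chrom, predictions$start, predictions$end)
  key_ann <- paste(reference_annotation$chrom, reference_annotation$start,
                   reference_annotation$end)
  idx <- match(key_pred, key_ann)
  fix <- predictions$category == "reference" & predictions$strand == "." &
    !is.na(idx)
  no_match <- predictions$category == "reference" &
    predictions$strand == "." & is.na(idx)
  if (any(no_match)) {
    message(sum(no_match),
            " reference call(s) had no positional match in the annotation")
  }
  predictions$strand[fix] <- reference_annotation$strand[idx[fix]]
  predictions
}

#' Write per-sample results in the standard directory layout
#'
#' Lays out `<out>/<reference>/<sample>/<method>/` with the method's
#' standardized BED inside, and a `non-ref_chromosome_results`
#' subdirectory holding calls on augmented TE chromosomes.
#'
#' @param predictions Prediction table (may span samples and methods).
#' @param out_dir Output root.
#' @param reference_name Name of the reference genome (top directory).
#' @param augmented_chrom_names Added chromosome names (may be empty).
#' @return Character vector of written BED paths, invisibly.
#' @export
write_results_tree <- function(predictions, out_dir, reference_name,
                               augmented_chrom_names = character(0)) {
  predictions <- standard_predictions(predictions)
  written <- character(0)
  for (s in unique(predictions$sample_id)) {
    ps <- predictions[predictions$sample_id == s, , drop = FALSE]
    for (m in unique(ps$method)) {
      pm <- ps[ps$method == m, , drop = FALSE]
      part <- partition_augmented(pm, augmented_chrom_names)
      dir <- file.path(out_dir, reference_name, s, m)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(dir, paste0(s, "_", m, ".bed"))
      write_standard_bed(part$main, p, sample = s, method = m)
      written <- c(written, p)
      if (nrow(part$non_ref_chromosome_results)) {
        sub <- file.path(dir, "non-ref_chromosome_results")
        dir.create(sub, showWarnings = FALSE)
        p2 <- file.path(sub, paste0(s, "_", m, "_nonrefchrom.bed"))
        write_standard_bed(part$non_ref_chromosome_results, p2,
                           sample = s, method = m)
        written <- c(written, p2)
      }
    }
  }
  invisible(written)
}
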