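#' Read a FASTA file into a named genome vector
#'
#' Sequences are uppercased and returned as a named character vector
#' (one element per record, names taken from the first word of each
#' header). Record order is preserved. All internal coordinates in this
#' package are 0-based half-open; only I/O boundaries convert.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences over `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in '", path, "'")
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence record in '", path, "'")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record '", names(seqs)[bad][1L], "'")
  }
  seqs
}

#' Write a named genome vector to FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param line_width Bases per body line (>= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  stopifnot(line_width >= 1L)
  if (length(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  set <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

#' Read features from a 1-based GFF file
#'
#' Coordinates are converted from GFF's 1-based inclusive convention to
#' the package-internal 0-based half-open convention
#' (`start = start_gff - 1`, `end = end_gff`). The feature name is taken
#' from the `ID` or `Name` attribute (first match), falling back to the
#' raw attribute column.
#'
#' @param path Path to a GFF file (1-based inclusive coordinates).
#' @param feature_filter Optional character vector: keep only rows whose
#'   type (column 3) is in this set.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`+`, `-` or `.`), `name`, `type`.
#' @export
read_gff_features <- function(path, feature_filter = NULL) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (any(g$end < g$start)) {
    stop("GFF record with end < start in '", path, "'")
  }
  if (!is.null(feature_filter)) {
    g <- g[g$type %in% feature_filter, , drop = FALSE]
  }
  name <- rep(NA_character_, nrow(g))
  for (field in c("ID", "Name")) {
    if (field %in% names(g)) {
      v <- as.character(g[[field]])
      name[is.na(name) & !is.na(v)] <- v[is.na(name) & !is.na(v)]
    }
  }
  name[is.na(name)] <- ""
  strand <- as.character(g$strand)
  strand[is.na(strand) | strand == "*"] <- "."
  data.frame(
    chrom = as.character(g$seqid),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = strand,
    name = name,
    type = as.character(g$type),
    stringsAsFactors = FALSE
  )
}

#' Write features to a 1-based GFF file
#'
#' Inverse of [read_gff_features()]: internal 0-based half-open
#' intervals are emitted with 1-based inclusive coordinates.
#'
#' @param features data.frame with `chrom`, `start`, `end`, `strand`,
#'   `name` and optionally `type` and `source` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_features <- function(features, path) {
  type <- if ("type" %in% names(features)) features$type else "feature"
  source <- if ("source" %in% names(features)) features$source else "tebench"
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
    features$chrom, source, type,
    features$start + 1L, features$end,
    features$strand, features$name
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a TE hierarchy file
#'
#' Two tab-delimited columns: reference TE instance name, canonical TE
#' family. Duplicate identical rows collapse; duplicate instance names
#' mapped to conflicting families are an error.
#'
#' @param path Path to the hierarchy TSV.
#' @return Named character vector mapping instance name to family.
#' @export
read_hierarchy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  if (any(n_col != 2L)) {
    stop("hierarchy line ", which(n_col != 2L)[1L],
         " does not have exactly two tab-delimited columns")
  }
  inst <- vapply(parts, `[[`, "", 1L)
  fam <- vapply(parts, `[[`, "", 2L)
  if (any(!nzchar(inst)) || any(!nzchar(fam))) {
    stop("empty instance or family name in hierarchy file")
  }
  keep <- !duplicated(paste0(inst, "\t", fam))
  inst <- inst[keep]
  fam <- fam[keep]
  if (anyDuplicated(inst)) {
    bad <- inst[duplicated(inst)][1L]
    stop("instance '", bad, "' maps to conflicting families")
  }
  stats::setNames(fam, inst)
}

#' Write a TE hierarchy file
#'
#' @param hierarchy Named character vector (instance -> family).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  writeLines(paste(names(hierarchy), hierarchy, sep = "\t"), path)
  invisible(path)
}

#' Resolve TE instance names to canonical families
#'
#' Names present in the hierarchy map are replaced by their family;
#' names absent from the map (already canonical, or unknown) pass
#' through unchanged.
#'
#' @param x Character vector of instance or family names.
#' @param hierarchy Named character vector from [read_hierarchy()], or
#'   `NULL` for the identity mapping.
#' @return Character vector of canonical family names.
#' @export
resolve_family <- function(x, hierarchy = NULL) {
  if (is.null(hierarchy)) {
    return(x)
  }
  hit <- x %in% names(hierarchy)
  x[hit] <- unname(hierarchy[x[hit]])
  x
}

#' Write standardized predictions to BED6
#'
#' Records are emitted as zero-based half-open BED6, sorted by
#' `(chrom, start, end)`. The name column carries
#' `<family>_<category>_<sample>_<method>_<evidence>` (see
#' [make_prediction_name()]); score is the constant 0. With
#' `with_header = TRUE` a single `track` line suitable for the UCSC
#' browser precedes the records, carrying the sample and method.
#'
#' @param predictions Prediction data.frame (see [standard_predictions()]).
#' @param path Output path.
#' @param sample,method Header identifiers; default to the (unique)
#'   values found in `predictions`.
#' @param with_header Emit the `track` header line?
#' @return `path`, invisibly.
#' @export
write_standard_bed <- function(predictions, path, sample = NULL,
                               method = NULL, with_header = TRUE) {
  predictions <- standard_predictions(predictions)
  if (is.null(sample)) {
    sample <- if (nrow(predictions)) predictions$sample_id[1L] else "sample"
  }
  if (is.null(method)) {
    method <- if (nrow(predictions)) predictions$method[1L] else "method"
  }
  o <- order(predictions$chrom, predictions$start, predictions$end)
  predictions <- predictions[o, , drop = FALSE]
  name <- make_prediction_name(
    predictions$family, predictions$category, predictions$sample_id,
    predictions$method, predictions$evidence
  )
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    predictions$chrom, predictions$start, predictions$end, name,
    predictions$strand
  )
  if (isTRUE(with_header)) {
    header <- sprintf('track name="%s_%s" description="%s %s"',
                      sample, method, sample, method)
    lines <- c(header, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read standardized predictions from BED6
#'
#' Inverse of [write_standard_bed()]. A leading `track` header line is
#' skipped if present; the name column is parsed back into its five
#' components.
#'
#' @param path Path to a standardized BED6 file.
#' @return Prediction data.frame (see [standard_predictions()]).
#' @export
read_standard_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], "track")) {
    lines <- lines[-1L]
  }
  if (!length(lines)) {
    return(standard_predictions())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  if (any(n_col < 6L)) {
    stop("BED record ", which(n_col < 6L)[1L], " has fewer than 6 fields")
  }
  fields <- lapply(1:6, function(i) vapply(parts, `[[`, "", i))
  comp <- lapply(seq_along(lines), function(i) {
    tryCatch(parse_prediction_name(fields[[4L]][i]), error = function(e) {
      stop("unparsable name field at record ", i, ": ",
           conditionMessage(e), call. = FALSE)
    })
  })
  standard_predictions(data.frame(
    chrom = fields[[1L]],
    start = as.integer(fields[[2L]]),
    end = as.integer(fields[[3L]]),
    family = vapply(comp, `[[`, "", "family"),
    category = vapply(comp, `[[`, "", "category"),
    sample_id = vapply(comp, `[[`, "", "sample_id"),
    method = vapply(comp, `[[`, "", "method"),
    evidence = vapply(comp, `[[`, "", "evidence"),
    strand = fields[[6L]],
    stringsAsFactors = FALSE
  ))
}
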