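#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse-complemented sequences.
#' @export
dna_revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Default upstream offset rules for active yeast TE families
#'
#' Active yeast LTR retrotransposons target the region upstream of
#' RNA-polymerase-III-transcribed tRNA genes and create a 5-bp target
#' site duplication (TSD) on insertion. Ty1, Ty2 and Ty4 insert within
#' the first ~200 bp upstream of the tRNA; Ty3 targets the
#' transcription-initiation region ~17 bp upstream. The rule
#' `(d_max, d_min, tsd_len)` places the TSD on the bases whose upstream
#' distances from the tRNA transcription start lie in `(d_min, d_max]`,
#' so `d_max - d_min = tsd_len`.
#'
#' @param families Character vector of family names to build rules for.
#' @param proximal_families Families that get the proximal (Ty3-style)
#'   17-12 bp rule; all others get the distal 200-195 bp rule.
#' @param tsd_len TSD length in bp.
#' @return data.frame with columns `family`, `d_max`, `d_min`,
#'   `tsd_len`.
#' @export
default_offset_rules <- function(families = c("Ty1", "Ty2", "Ty3", "Ty4"),
                                 proximal_families = "Ty3",
                                 tsd_len = 5L) {
  proximal <- families %in% proximal_families
  rules <- data.frame(
    family = families,
    d_max = ifelse(proximal, 12L + tsd_len, 195L + tsd_len),
    d_min = ifelse(proximal, 12L, 195L),
    tsd_len = as.integer(tsd_len),
    stringsAsFactors = FALSE
  )
  stopifnot(all(rules$d_max - rules$d_min == rules$tsd_len),
            all(rules$tsd_len >= 1L))
  rules
}

# tss: 0-based coordinate of the first transcribed base.
trna_tss <- function(trna) {
  ifelse(trna$strand == "+", trna$start, trna$end - 1L)
}

#' Plan one TSD site upstream of each tRNA gene
#'
#' Families are assigned by cycling through `families_cycle` in tRNA
#' order. The TSD occupies the `tsd_len` bases whose upstream distances
#' from the tRNA transcription start (tss), measured in tRNA
#' orientation, lie in `(d_min, d_max]`:
#' plus-strand tRNA `[tss - d_max, tss - d_min)`, minus-strand
#' `[tss + d_min + 1, tss + d_max + 1)`. tRNAs whose TSD window would
#' cross a chromosome edge are skipped with a warning.
#'
#' @param trna_genes data.frame with `chrom`, `start`, `end`, `strand`
#'   (`+`/`-` only), `name`; 0-based half-open, deterministic order.
#' @param families_cycle Character vector of family names to alternate.
#' @param offset_rules data.frame from [default_offset_rules()].
#' @param chrom_lens Named integer vector of chromosome lengths (used
#'   for edge checks); optional.
#' @return data.frame with one row per planned site: `trna_name`,
#'   `chrom`, `trna_strand`, `tss`, `family`, `tsd_start`, `tsd_end`.
#' @export
plan_insertion_sites <- function(trna_genes, families_cycle,
                                 offset_rules = default_offset_rules(families_cycle),
                                 chrom_lens = NULL) {
  stopifnot(nrow(trna_genes) > 0L, length(families_cycle) > 0L,
            all(trna_genes$strand %in% c("+", "-")))
  missing <- setdiff(families_cycle, offset_rules$family)
  if (length(missing)) {
    stop("no offset rule for family: ", paste(missing, collapse = ", "))
  }
  n <- nrow(trna_genes)
  fam <- families_cycle[((seq_len(n) - 1L) %% length(families_cycle)) + 1L]
  rule <- offset_rules[match(fam, offset_rules$family), , drop = FALSE]
  tss <- trna_tss(trna_genes)
  plus <- trna_genes$strand == "+"
  tsd_start <- ifelse(plus, tss - rule$d_max, tss + rule$d_min + 1L)
  tsd_end <- ifelse(plus, tss - rule$d_min, tss + rule$d_max + 1L)
  plan <- data.frame(
    trna_name = trna_genes$name,
    chrom = trna_genes$chrom,
    trna_strand = trna_genes$strand,
    tss = as.integer(tss),
    family = fam,
    tsd_start = as.integer(tsd_start),
    tsd_end = as.integer(tsd_end),
    stringsAsFactors = FALSE
  )
  ok <- plan$tsd_start >= 0L
  if (!is.null(chrom_lens)) {
    ok <- ok & plan$tsd_end <= chrom_lens[plan$chrom]
  }
  if (any(!ok)) {
    warning(sum(!ok), " tRNA(s) skipped: TSD window crosses a chromosome ",
            "edge (", paste(plan$trna_name[!ok], collapse = ", "), ")")
  }
  plan[ok, , drop = FALSE]
}

#' Build a genome carrying one synthetic TE insertion
#'
#' The canonical TE sequence (reverse-complemented for `te_strand`
#' `"-"`) is spliced in so that the TSD bases `ref[a, b)` are duplicated
#' on both sides of the element: the modified chromosome is
#' `ref[0, b) + TE + ref[a, len)`. Coordinates in the returned truth
#' record stay in reference coordinates.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param plan_entry One row of the plan from [plan_insertion_sites()].
#' @param canonical_te_seq Canonical sequence of the inserted family.
#' @param te_strand `"+"` or `"-"`: genome strand of the inserted TE,
#'   independent of tRNA orientation.
#' @param sample_id Sample identifier recorded in the truth.
#' @return List with `genome` (modified named vector) and `truth` (one
#'   row: `sample_id`, `family`, `te_strand`, `chrom`, `start`, `end`,
#'   `trna_name`).
#' @export
make_single_insertion_genome <- function(reference, plan_entry,
                                         canonical_te_seq, te_strand,
                                         sample_id = NULL) {
  stopifnot(te_strand %in% c("+", "-"), nzchar(canonical_te_seq))
  chrom <- plan_entry$chrom
  a <- plan_entry$tsd_start
  b <- plan_entry$tsd_end
  seq <- reference[[chrom]]
  if (a < 0L || b > nchar(seq)) {
    stop("TSD interval [", a, ",", b, ") out of bounds on ", chrom)
  }
  te <- if (te_strand == "+") canonical_te_seq else dna_revcomp(canonical_te_seq)
  modified <- paste0(substr(seq, 1L, b), te, substr(seq, a + 1L, nchar(seq)))
  genome <- reference
  genome[[chrom]] <- modified
  if (is.null(sample_id)) {
    sample_id <- paste(plan_entry$trna_name, plan_entry$family,
                       if (te_strand == "+") "plus" else "minus", sep = ".")
  }
  truth <- data.frame(
    sample_id = sample_id,
    family = plan_entry$family,
    te_strand = te_strand,
    chrom = chrom,
    start = as.integer(a),
    end = as.integer(b),
    trna_name = plan_entry$trna_name,
    stringsAsFactors = FALSE
  )
  list(genome = genome, truth = truth)
}

#' Generate the full single-insertion sample batch
#'
#' For each tRNA gene and each genome strand in `strands`, one sample
#' with a single TE insertion is produced; family alternation restarts
#' at the beginning of each strand batch. With 299 tRNAs and both
#' strands this yields the 598-sample design.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param trna_genes tRNA annotation (see [plan_insertion_sites()]).
#' @param canonical_tes Named character vector of canonical family
#'   sequences; its names define the family cycle order.
#' @param offset_rules Offset rules table.
#' @param strands Genome strands to simulate (default both).
#' @param keep_genomes Materialize the modified genome of every sample?
#'   Set `FALSE` for large batches where only the truth manifest is
#'   needed.
#' @return List with `truth` (data.frame, one row per sample) and
#'   `genomes` (named list of genome vectors, or `NULL`).
#' @export
generate_sample_set <- function(reference, trna_genes, canonical_tes,
                                offset_rules = default_offset_rules(names(canonical_tes)),
                                strands = c("+", "-"),
                                keep_genomes = TRUE) {
  stopifnot(nrow(trna_genes) > 0L)
  chrom_lens <- vapply(reference, nchar, integer(1))
  truths <- list()
  genomes <- if (keep_genomes) list() else NULL
  for (st in strands) {
    plan <- plan_insertion_sites(trna_genes, names(canonical_tes),
                                 offset_rules, chrom_lens)
    for (i in seq_len(nrow(plan))) {
      entry <- plan[i, , drop = FALSE]
      if (keep_genomes) {
        res <- make_single_insertion_genome(
          reference, entry, canonical_tes[[entry$family]], st
        )
        truths[[length(truths) + 1L]] <- res$truth
        genomes[[res$truth$sample_id]] <- res$genome
      } else {
        sample_id <- paste(entry$trna_name, entry$family,
                           if (st == "+") "plus" else "minus", sep = ".")
        truths[[length(truths) + 1L]] <- data.frame(
          sample_id = sample_id, family = entry$family, te_strand = st,
          chrom = entry$chrom, start = entry$tsd_start,
          end = entry$tsd_end, trna_name = entry$trna_name,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(truth = truth, genomes = genomes)
}

#' Extract annotated TE instance sequences from the reference
#'
#' @param reference Named character vector of chromosome sequences.
#' @param te_annotation data.frame with `chrom`, `start`, `end`,
#'   `strand`, `name` (0-based half-open).
#' @return Named character vector of instance sequences,
#'   reverse-complemented for minus-strand instances.
#' @export
extract_te_instances <- function(reference, te_annotation) {
  if (nrow(te_annotation) == 0L) {
    return(character(0))
  }
  seqs <- character(nrow(te_annotation))
  for (i in seq_len(nrow(te_annotation))) {
    chrom <- te_annotation$chrom[i]
    len <- nchar(reference[[chrom]])
    a <- te_annotation$start[i]
    b <- te_annotation$end[i]
    if (a < 0L || b > len) {
      stop("annotation interval [", a, ",", b, ") out of bounds on ", chrom)
    }
    s <- substr(reference[[chrom]], a + 1L, b)
    seqs[i] <- if (te_annotation$strand[i] == "-") dna_revcomp(s) else s
  }
  stats::setNames(seqs, te_annotation$name)
}

#' Augment a reference genome with TE "chromosomes"
#'
#' Adds each TE sequence as a new chromosome named after the TE and
#' appends, for each added chromosome, an annotation record spanning
#' `[0, len(TE))`. Original chromosomes are untouched. Name collisions
#' with existing chromosomes are disambiguated with a suffix and
#' logged.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param canonical_tes Named character vector of canonical family
#'   sequences (used in modes `canonical` and `both`).
#' @param reference_te_annotation Reference TE annotation (used in
#'   modes `extracted` and `both` to pull instance sequences).
#' @param mode One of `"canonical"`, `"extracted"`, `"both"`.
#' @return List with `genome` (augmented named vector),
#'   `added_chroms` (names of added chromosomes) and `annotation`
#'   (data.frame of appended records spanning each added chromosome).
#' @export
augment_reference <- function(reference, canonical_tes = NULL,
                              reference_te_annotation = NULL,
                              mode = c("canonical", "extracted", "both")) {
  mode <- match.arg(mode)
  add <- character(0)
  if (mode %in% c("canonical", "both")) {
    stopifnot(!is.null(canonical_tes))
    add <- c(add, canonical_tes)
  }
  if (mode %in% c("extracted", "both")) {
    stopifnot(!is.null(reference_te_annotation))
    add <- c(add, extract_te_instances(reference, reference_te_annotation))
  }
  nm <- names(add)
  taken <- names(reference)
  for (i in seq_along(nm)) {
    if (nm[i] %in% taken) {
      new <- paste0(nm[i], ".te")
      k <- 1L
      while (new %in% taken) {
        k <- k + 1L
        new <- paste0(nm[i], ".te", k)
      }
      message("chromosome name collision: '", nm[i], "' added as '", new, "'")
      nm[i] <- new
    }
    taken <- c(taken, nm[i])
  }
  names(add) <- nm
  annotation <- data.frame(
    chrom = nm,
    start = 0L,
    end = vapply(add, nchar, integer(1), USE.NAMES = FALSE),
    strand = "+",
    name = nm,
    type = "transposable_element",
    stringsAsFactors = FALSE
  )
  list(genome = c(reference, add), added_chroms = nm,
       annotation = annotation)
}

#' Write a truth manifest as BED6 plus a TSV run manifest
#'
#' The BED name column carries the family; the strand column carries
#' the genome strand of the inserted TE.
#'
#' @param truth Truth data.frame from [generate_sample_set()].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_truth_manifest <- function(truth, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    o <- order(truth$chrom, truth$start, truth$end)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       truth$chrom[o], truth$start[o], truth$end[o],
                       truth$family[o], truth$te_strand[o]), bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      truth[, c("sample_id", "trna_name", "family", "te_strand",
                "chrom", "start", "end")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(c(bed_path, tsv_path))
}
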