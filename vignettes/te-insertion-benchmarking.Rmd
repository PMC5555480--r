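---
title: "Benchmarking TE insertion callers with synthetic single-insertion genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking TE insertion callers with synthetic single-insertion genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tebench)
```

# The problem

Short-read callers for non-reference transposable element (TE) insertions
differ wildly in breakpoint resolution, family assignment, and
false-positive behaviour, and each emits results in its own format. A fair
comparison needs three things: a truth set whose insertion points are known
to the base pair, a common annotation scheme for predictions, and an
evaluation that separates *where* a call landed from *what* family and
orientation it claimed. `tebench` provides all three for the yeast-style
setting in which active LTR retrotransposons (Ty1–Ty4 in
*Saccharomyces cerevisiae*) insert upstream of RNA-polymerase-III-transcribed
tRNA genes and leave a 5-bp target site duplication (TSD).

# The simulation model

## Single synthetic insertions

Each simulated sample carries exactly one synthetic insertion. The TSD
interval is placed upstream of a tRNA gene in tRNA orientation using a
per-family offset rule $(d_{\max}, d_{\min}, \ell)$ with
$d_{\max}-d_{\min}=\ell$: the TSD occupies the $\ell$ bases whose upstream
distances from the transcription start lie in $(d_{\min}, d_{\max}]$. The
defaults encode the two empirically observed targeting modes: Ty1/Ty2/Ty4
insert within the first ~200 bp upstream (rule $(200, 195, 5)$) and Ty3
targets the transcription-initiation region (rule $(17, 12, 5)$). For a
plus-strand tRNA with start $t$ this yields the interval
$[t-d_{\max},\, t-d_{\min})$; minus-strand tRNAs are mirrored. A stated
range such as "200–195 bp upstream" spans six distances; since the TSD is 5
bp one endpoint must go, and we keep the distal endpoint so the distal TSD
edge sits exactly $d_{\max}$ bp upstream — the quantity the positional
metaplots anchor on.

Given a TSD $[a, b)$ on reference chromosome $r$, the modified chromosome is

$$ r' = r[0{:}b] \;\Vert\; \mathrm{TE} \;\Vert\; r[a{:}], $$

with the canonical family sequence reverse-complemented for minus-strand
insertions. This duplicates the 5 host bases $r[a{:}b]$ on both sides of the
element, exactly as integration does, so the modified length is the
reference length plus the element length plus $\ell$. TE strand is drawn
relative to the genome, independent of tRNA orientation; a full batch
produces one sample per tRNA per genome strand (598 samples for a 299-tRNA
annotation), with family assignment cycling through the library in tRNA
order and restarting at each strand batch. tRNAs whose TSD window would
cross a contig edge are skipped with a warning so the manifest bookkeeping
stays exact.

## Reads

`simulate_read_pairs()` is a minimal wgsim-style simulator: uniform
fragment placement (chromosomes length-weighted), fragment length
$\mathrm{Normal}(\mu, \sigma)$ rounded and truncated to
$[2L, \text{chrom length}]$, one read from each fragment end in opposite
orientations, and independent per-base substitutions at rate $e$. Defaults
($L = 101$, $\mu = 300$, $\sigma = 42$, $e = 0.01$, 100-fold coverage)
mimic the HiSeq-2000 yeast resequencing libraries this benchmark emulates.
The pair count for a target coverage $c$ is
$\lceil Gc/2L \rceil$, so realized depth lies in $[c, c + 2L/G)$. The model
deliberately omits indels, quality profiles, GC bias and duplicates: the
evaluation machinery downstream is caller-agnostic and none of its claims
depend on those read-level artefacts. "42-bp SE" in the source library
description is read as the standard deviation of insert size.

# Standardized predictions

Every call is reduced to a BED6 record in 0-based half-open coordinates
whose name field is `<family>_<category>_<sample>_<method>_<evidence>` with
category spelled `non-reference`/`reference` and evidence one of `sr`
(split-read), `rp` (read-pair) or `nonab` (reference TE present). The `_`
delimiter is a package choice (only the field's *content* is canonical);
components containing it are sanitized to `-` with a logged message, and
sample ids minted by the package use `.` separators so the issue does not
arise. Redundancy removal happens within one method's per-sample result
file only — never across methods — keyed on
(sample, chrom, start, end, family, category), retaining the split-read
record when `sr` and `rp` duplicates coexist, because split-read evidence
is base-pair accurate. Calls landing on augmented TE "chromosomes" are
partitioned into a `non-ref_chromosome_results` bucket rather than deleted.

# Evaluation

## Window matching

A nonreference prediction is correct at window $w$ when its interval
overlaps $[\mathrm{tsd}_{start}-w,\ \mathrm{tsd}_{end}+w)$ by at least one
base (the `bedtools window` convention; lower bound clipped at zero), and
exactly correct when it equals the TSD interval. Threshold scoring uses
windows exact/100/300/500 bp and requires the correct family (instance
names resolve through the hierarchy to canonical families first);
orientation is never consulted because several caller classes do not
predict it. Per sample we report both the raw count of matching predictions
and the count capped at one; the capped mean is the headline statistic
because with a single true insertion per sample "how many samples were
solved" is the meaningful ratio, while the raw mean exposes multiple
counting. Correctness is monotone in $w$ by construction, and the matcher
is tested for exact agreement against a brute-force per-base overlap oracle.

## Recurrence filtering and concordance

Because each true site exists in exactly one sample of a strand batch, a
nonreference site recurring across `min_samples` ≥ 2 samples of a batch is
flagged as a likely systematic false positive and removed before
visualization. The plus and minus batches intentionally share sites, so the
filter is applied within each batch. Concordance (Venn) analysis scores
each method per sample under its own window — 0 bp for base-pair-accurate
method classes, 100 or 500 bp for coarser read-pair classes — with family
and orientation ignored, and tallies samples over all $2^k$ method subsets;
the counts always total the sample count.

## Profiles and tRNA regions

`anchored_profile()` computes metaplots of prediction coverage around
anchors, flipping contributions for minus-strand anchors (tRNA mode) or
minus-strand sample batches (TSD mode) so both orientations share one axis.
In indicator mode a sample contributes at most 1 per position, bounding
single-insertion profiles by 1; multiplicity mode counts every overlapping
prediction and may exceed 1. A perfect caller yields a height-1 delta over
the five TSD positions.

The tRNA region of a gene with transcription start $t$ is
$[t-1000,\ t+500)$ in tRNA orientation (half-open, length exactly 1500 bp —
the inclusive/exclusive choice is ours, made to match the 1500-bp window
length used in the enrichment expectation). A prediction overlapping any
region counts once, however many regions it touches, but insertions present
in several samples count independently. The expectation under uniform
random placement is $n_{\mathrm{tRNA}} \times 1500 / G$, assuming
non-overlapping windows; at the yeast constants
$(299 \times 1500)/12{,}162{,}995 = 0.0369$, i.e. 3.7% of random
insertions, reported as the fraction `0.037` to two significant figures.
(Note the formula's value is a fraction, not a percentage, despite
sometimes being quoted with a percent sign.) `expected_random_proportion()`
clamps at 1 with a warning when the assumption is violated grossly.

# The synthetic universe and mock callers

`make_toy_reference()` builds a random genome with alternating-strand tRNA
genes, a canonical TE library, embedded reference TE copies, and the
hierarchy mapping. Feature spacing (default 1600 bp clearance) guarantees
insertion and ±500-bp evaluation windows never collide, keeping oracle
bookkeeping exact; the first two families optionally share an identical
80-bp terminal repeat to reproduce the Ty1/Ty2-style shared-LTR ambiguity.
The sequence composition is uniform random: no real yeast base composition,
chromatin, or recombination structure, and no heterochromatin-targeting
family is modelled. Consequently, passing tests demonstrate the
*evaluation machinery* is correct, not that any particular caller performs
well on real genomes.

Mock callers (`make_mock_predictions()`) operate on the truth manifest, not
on reads — read-level detection is precisely the external callers' job and
deliberately out of scope. Their parameters encode behaviours real callers
exhibit: detection probability, Gaussian positional jitter, a constant
directional shift, TSD-length under/over-calling, uniform false positives,
and family confusion. The test suite demonstrates each parameter is
recoverable from the evaluation outputs within 99% Monte-Carlo intervals,
which is the package's core correctness claim.

# Numerical choices and problem sizes

* All internal coordinates are 0-based half-open; GFF (1-based inclusive)
  converts only at I/O boundaries, eliminating off-by-one drift.
* The read simulator floors fragment lengths at $2L$ (overlapping mates
  rather than failure) and never spans chromosome junctions.
* Deduplication and recurrence keys use exact coordinates; strand is
  excluded from both keys since several caller classes leave it unset.
* bedGraph export merges equal-value runs *including zeros* so profiles
  round-trip exactly; bigWig conversion is left to external `wigToBigWig`.
* Default test and acceptance problem sizes — a 100-kb single-chromosome
  universe with 8 tRNAs, ~500-sample replicated batches for parameter
  recovery, 10^4 randomized matcher cases, 10^5 read pairs for the error
  estimate, and a 600-kb chromosome for the 299-tRNA batch — were chosen so
  each statistical check has comfortable power at its 99% interval while
  the whole suite stays interactive on a laptop.

# A worked example

```{r example, eval = FALSE}
fx <- make_toy_reference(fixture_spec(seed = 7))
batch <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                             keep_genomes = FALSE)
pred <- make_mock_predictions(
  batch$truth,
  mock_caller_profile("jittery", p_detect = 0.9, pos_error_sd = 50,
                      fp_rate = 0.5),
  vapply(fx$genome, nchar, integer(1)), seed = 1
)
score_sample_set(pred, batch$truth)$summary
```

# Known limitations

Single insertions only: no multi-insertion genomes, nested insertions,
solo-LTR recombination products, or allele-frequency structure. The read
simulator's substitution-only error model cannot probe indel-sensitive
breakpoint logic. The tRNA-region expectation assumes non-overlapping
windows, which densely packed annotations violate. Mock callers cannot
surface failure modes that originate in alignment itself; conclusions about
real callers require running them on the simulated FASTQ output.
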