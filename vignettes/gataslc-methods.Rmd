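---
title: "Methods: identifying and prioritizing GATA factor-regulated transporter genes"
author: "gataslc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and prioritizing GATA factor-regulated transporter genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `gataslc`, and what its synthetic-data tests do and do
not establish about real data.

## Biological setting

GATA2 and GATA1 are zinc-finger transcription factors that drive erythroid
differentiation in sequence: GATA2 acts in progenitors, GATA1 accumulates
later, takes over many GATA2 sites and represses *Gata2* itself. Both bind
the degenerate WGATAR element (`[A/T]GATA[A/G]`), often alongside E-boxes
(`CANNTG`) bound by bHLH partners in GATA complexes. The pipeline asks, for
a large gene family such as the ~456-member SLC transporter ensemble: which
members does each factor activate or repress, which are co-regulated, and
which carry direct regulatory evidence — GATA occupancy in an intron
coinciding with accessible chromatin and GATA motifs.

The two expression contrasts the pipeline expects mirror the two classic
experimental designs:

* a **gain-of-function** contrast (condition *b* activates GATA1, e.g.
  β-estradiol induction of an ER-GATA1 fusion in GATA1-null
  proerythroblasts), where "GATA1-activated" means *up* in *b*;
* a **loss-of-function** contrast (condition *b* removes GATA2 function,
  e.g. a *Gata2* enhancer knockout), where "GATA2-activated" means *down*
  in *b*.

`call_regulated_genes(active_condition = )` encodes this orientation so
that directions are always stated as the factor's action.

## Differential regulation

For each gene, `log2FC = log2((mean_b + pc)/(mean_a + pc))` with
pseudocount `pc = 0.5` TPM. The pseudocount is needed for genes expressed
in only one condition; genes with both means below `pc` are treated as not
expressed in the system and dropped before multiple-testing correction, so
the FDR is computed over the expressed universe.

Significance is an unpaired two-sided t-test on `log2(TPM + pc)`. The
default is the pooled-variance Student test (`var_equal = TRUE`): at the
replicate numbers typical of these designs (n = 3 per condition) the
pooled test is exact under the homoscedastic log-normal noise model the
generator implements, whereas Welch's test is noticeably conservative at
n = 3 (its Satterthwaite degrees of freedom are estimated from two
three-point variances). Welch's test remains available via
`var_equal = FALSE` for heteroscedastic data. Degenerate cases follow fixed
conventions: if both groups have zero variance, p = 1 when the means agree
and p = 0 otherwise; a group with fewer than two replicates yields p = 1
and `tested = FALSE`.

A gene is called regulated iff its fold-change magnitude `max(FC, 1/FC)` is
at least the threshold (default 1.5, **inclusive**, compared on the log2
scale with a 1e-12 tolerance so that a magnitude of exactly 1.5 passes) and
`FDR <= 0.05`. Both thresholds are config-exposed; the underlying studies
print the fold criterion but not the test or FDR level, so the significance
filter is a documented stand-in.

## Cohort partition and enrichment

`partition_cohorts()` is exact set algebra on gene ids: factor-1-only,
factor-2-only and shared sets are pairwise disjoint and tile the union.
Over the shared set, the four direction groups are keyed GATA2-first
(`up/up`, `up/down`, `down/up`, `down/down`, `up` = activated). Duplicate
conflicting calls for one factor are an error rather than silently resolved.

Substrate-class enrichment compares a cohort with the full registry
ensemble in a 2×2 table (in/out of cohort × in/out of class) using
Pearson's chi-square without continuity correction (1 df). The chi-square
statistic is always reported; when any expected cell is below 5 the
p-value is taken from Fisher's exact test instead and flagged in `method`
— the statistic remains comparable across classes while the p-value stays
honest in sparse tables. The default denominator is the full registry
(the 456-member-family analogue), not just expressed genes; callers who
want the expressed-only denominator can pass a subsetted registry. Classes
are single-label per gene: multi-substrate transporters take their primary
class from the registry file.

## Peak assignment and predicted intronic enhancers

A peak is assigned to a gene iff it overlaps the transcript extended by a
window (default 10 kb — chosen as a conventional locus neighborhood, since
browser-track occupancy reading has no explicit rule) by at least 1 bp.
Context is decided by the midpoint of the overlap, checked against introns
first, then exons, then the strand-aware promoter window upstream of the
TSS, else flanking; the intron-first order makes ties resolve toward
intronic, keeping enhancer counting unambiguous. Intron indices are
strand-aware: intron 1 is the first intron in transcription order.

A *candidate* is any non-empty intersection of a GATA2 peak with an intron
of an assigned gene, so a peak spanning an exon into two introns yields one
candidate per intron footprint, each clipped to its intron. Candidates are
flagged by ≥ 1 bp overlap with GATA1 peaks, ATAC peaks and cCREs, and the
clipped footprint sequence is scanned for WGATAR and E-box on both strands.
The emission rule for a **predicted intronic enhancer** is: GATA2-occupied
AND accessible AND ≥ 1 WGATAR hit. GATA1 occupancy and cCRE overlap are
corroborating annotations, not requirements, and E-boxes are never
required — the motif-enrichment stage tests them instead. The rule is one
consistent reading of a narratively described procedure and is deliberately
monotone: adding ATAC peaks can only add predicted enhancers.

## Motif scanning

IUPAC patterns are matched with the sequence letters fixed: an `N` in the
genome never satisfies a non-`N` pattern symbol (unknown sequence is never
evidence for a motif). Both strands are scanned — GATA factors bind
double-stranded DNA — with reverse-strand hits reported in forward
coordinates; when a palindromic pattern (e.g. the E-box class) matches the
same interval on both strands, the hit is counted once. All hits of a
pattern share its width, which the permutation machinery exploits: a window
contains a hit iff a hit start falls in a closed offset interval, so null
windows can be evaluated by binary search over precomputed per-intron hit
positions instead of rescanning sequence. A `method = "scan"` path rescans
every null window from the identical placement draws; the test suite checks
the two paths agree exactly.

## The matched-background permutation test

The observed group is the set of predicted-enhancer footprints. Its
statistic is, by default, the number of sequences containing ≥ 1 motif hit
("presence"); the total hit count across the group ("count") is available.
Each of `n_iter` (default 10,000) null groups replaces every observed
window with a random intronic window of exactly the same length on the same
chromosome, drawn uniformly over all (intron, offset) placements, with
replacement across items and iterations. "Same chromosome, any intron" is
the weakest operationalization of location matching; the intron space
defaults to all genes' introns (the eligible set is whatever gene models
are passed, so callers can restrict it).

Three p-values are reported:

* `p_empirical = #{null >= observed} / n_iter` — the plain proportion;
* `p_corrected = (k + 1) / (n_iter + 1)` — never below its floor
  `1/(n_iter+1)`, valid for thresholding;
* `p_mid = (#{null > observed} + 0.5 (#{ties} + 1)) / (n_iter + 1)` — the
  mid-p.

The distinction matters because the group statistic is discrete: with 8
windows the presence statistic takes only 9 values, so `p_empirical` and
`p_corrected` are conservative (their rejection rate at level α stays
below α, by an amount that depends on how the null mass clumps on integers).
The mid-p halves the tie mass and is the standard remedy; it is what the
calibration harness (`calibrate_permutation_test`) checks, drawing the
"observed" group from the background sampler itself so that it follows the
null exactly. Calibration is assessed with the count statistic, whose null
support is fine-grained; the presence statistic's conservatism is a known
limitation, not an error — it never overstates significance.

## The synthetic-data generator

`synthetic_config()` defaults define the study-condition scenario:

* 3 chromosomes × 1 Mb, 60 genes (2–6 exons of 150–300 bp, introns
  400–1200 bp, intergenic gaps 21–26 kb so a 10 kb assignment window never
  reaches a neighboring gene), uniform base composition (25% each), one
  transcript per gene;
* 40 SLC-labeled genes: 27 co-regulated (all GATA2-activated, mixed GATA1
  direction — the cohort the enhancer analysis walks into), 6 GATA1-only,
  4 GATA2-only, plus 3 regulated non-SLC genes that exercise the family
  filter and decoy genes with no signal;
* of the 27: 21 GATA2-occupied, 17 of those GATA1-occupied, 24 accessible,
  and 8 of the 17 host a planted accessible intronic enhancer carrying 2
  WGATAR and 1 E-box instance (inserted by substitution at non-overlapping
  offsets, never spanning the enhancer edges), covered by GATA2/GATA1/ATAC/
  cCRE intervals; occupied genes without an enhancer get an intronic GATA2
  peak with no ATAC overlap, accessible genes without one get a promoter
  ATAC peak, and decoy peaks live in intergenic space beyond any assignment
  window;
* expression: baseline TPM log-normal (log2 mean 5, sd 1.5; floored at 4
  TPM for genes with planted effects, since regulated genes are by
  construction expressed), condition-b mean × `2^lfc`, homoscedastic
  replicate noise `2^N(0, noise_sd)` with `noise_sd = 0.5` and n = 3 —
  matching the replicate depth of the underlying designs; planted |log2FC|
  is 2.5–3.5 for enhancer hosts (prioritization targets the strongest
  regulation) and 1.2–2.2 otherwise;
* registry: the 40 SLC genes plus 33 registry-only members emulating the
  rest of the family, with substrate classes drawn at fixed proportions
  (amino acid 25%, metal 20%, nucleoside/nucleotide 15%, vitamin 10%,
  other 30%) and a phenotype flag on 6 genes;
* `motif_free_background = TRUE` scrubs every WGATAR/E-box occurrence from
  the background before planting, making the constructed-null permutation
  result exact (`p_corrected = 1/(n_iter+1)`).

The uniform base composition keeps analytic motif expectations computable
(`motif_density_background` records the expected WGATAR per kb, ~0.98 per
strand pair). All outputs are pure functions of (config, seed); one global
seed is expanded into per-stage substreams by a fixed hash so stages can be
rerun independently.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: GC content and composition heterogeneity,
ChIP-signal shape and peak-calling uncertainty, mappability artifacts,
count-based (negative-binomial) expression noise, heteroscedasticity,
alternative isoforms, and correlated regulation between neighboring genes.
Recovery guarantees (exactly the 8 planted enhancers, 100% precision/recall
at zero noise) certify the plumbing and the rule logic, not biological
sensitivity.

## Problem sizes and numerical conventions

The test suite runs entirely on generated data: the study-condition genome
(3 Mb) for acceptance checks, a 0.66 Mb two-chromosome scenario for unit
tests, 1,000 random peaks against the brute-force assignment oracle, 500
random 200-mers against the naive motif-scan oracle, 100 random 2×2 tables
against the closed-form chi-square (tolerance 1e-9), 2,000 null genes for
the type-I band, and 1,000 calibration repetitions at 500 iterations each —
sizes chosen so the whole suite completes in a couple of minutes while
keeping binomial test bands tight enough to be meaningful.

Deterministic tie-breaks everywhere: magnitude ranking breaks ties
alphabetically by gene id; candidate ranking orders by score, then
magnitude, then id. Fold-threshold comparisons happen on the log2 scale
with a 1e-12 tolerance. Unknown strand (".") is ordered like "+" for intron
indexing. BED round trips preserve name/score/strand; GFF3's 1-based closed
coordinates are converted at the file boundary so everything internal is
0-based half-open.

## Known limitations

* The scoring system is a transparent linear stand-in (weights 1 per
  evidence flag, 2 for phenotype, 1 per log2 fold unit); the underlying
  studies describe prioritization narratively and never publish weights.
* The enhancer emission rule is one consistent reading of a narrative
  procedure; alternatives (requiring GATA1 co-occupancy, or cCRE overlap)
  are easy to evaluate from the annotated candidate table.
* The permutation null matches length and chromosome but not GC or distance
  to the observed locus; a distance-banded background would need denser
  gene models than the synthetic genome provides.
* Phenotype evidence is a boolean registry column, not literature mining.
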