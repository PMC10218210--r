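---
title: "Detecting conserved amyloidogenic regions in ortholog families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved amyloidogenic regions in ortholog families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloscan)
```

## The model

`amyloscan` asks whether the amyloid-forming potential of a protein is an
evolutionarily conserved *property* of a region, as opposed to an accident
of one sequence. The unit of analysis is an ortholog family: one protein
per species, each annotated with its taxonomic class and phylum. The
pipeline has four statistical ingredients.

**The amyloid-call rule.** Each residue carries two scores in [0, 1]: an
amyloidogenicity score (the role played by β-arch predictors in practice)
and an intrinsic-disorder score. A residue is *in-region* iff

- amyloid score > 0.575, and
- disorder score > 0.3,

both strict. The conjunction encodes the biological requirement that a
β-arch candidate is only credible inside an unstructured stretch: a high
amyloid score buried in a folded domain is not counted. Maximal runs of
in-region residues form the called amyloidogenic intervals, and a protein
with at least one interval is a *potential amyloid* (the per-phylum census
counts these). A score-only mode (`use_disorder = FALSE` in
`run_config()`, or `disorder_threshold = NULL`) is provided because column
conservation can also be defined on the raw amyloid score alone; the
default keeps the disorder condition, and every run's manifest records the
choice.

**Taxon balancing.** Ortholog databases oversample some clades by an order
of magnitude. Before alignment the family is filtered and resampled at the
class level: classes with fewer than 3 members are excluded, classes with
3–10 members enter whole, and larger classes contribute exactly 10 members
drawn uniformly without replacement — independently in each of 10
replicates. Dropping the small classes (rather than keeping them outside
the 3–10 window) is a deliberate reading of an ambiguous rule: a class of
one or two sequences cannot provide a meaningful within-class frequency,
and the filter is the same in every replicate, so it never introduces
replicate-to-replicate variance. The drop list and the seed-derivation
scheme are recorded in the output metadata.

**Column statistics.** Each replicate is aligned and the residue-level
calls are projected onto columns through the residue→column map; gap cells
carry `NA`, never a zero. Per column:

- `Gaps` = gapped rows / all rows;
- `AAC` (amino acid conservation) = count of the most frequent residue /
  non-gap rows;
- `CAP` (conservation of amyloidogenic properties) = rows whose residue is
  in-region / non-gap rows.

The non-gap denominator for AAC and CAP is a design decision: gaps are
tracked separately by `Gaps`, and the region rule below requires *both*
high CAP and low gaps, which would be partly redundant if gap rows already
dragged CAP down. Both denominators can be switched to all-rows
(`cap_denominator = "all"`, `aac_denominator = "all"`). Columns with no
non-gap cell report `NA` and always break region runs. The metrics table
carries `cap_minus_aac` as a convenience track for users who want to ask
whether property conservation exceeds sequence conservation at a column,
but the package asserts nothing about that comparison.

**Conserved regions and replicate aggregation.** A conserved amyloidogenic
region is a maximal run of at least `min_length = 10` columns with
`CAP >= 0.5` and `Gaps <= 0.25`. These three defaults are package choices
tuned to the motif scale of interest (a 10-column floor rejects isolated
high-CAP columns; CAP 0.5 demands the property in at least half the
sampled family; Gaps 0.25 rejects alignment regions dominated by indels) —
all three are arguments of `call_conserved_regions()` and `run_config()`.
Because the 10 replicates are aligned independently, their column axes are
not comparable; the package therefore reports per-replicate curves and
regions, and aggregates only scalar summaries (mean and sd of per-replicate
mean Gaps/AAC/CAP). No cross-replicate column merging is attempted.

## Surrogate scorers

The built-in scorers exist so that the pipeline is runnable and testable
without any external predictor; they are *surrogates* and are labelled as
such. Each is a sliding-window mean (default window 21, a typical
disorder-predictor smoothing scale; truncated at the termini) over a fixed
per-residue propensity table, min–max scaled to [0, 1] over the table's
20-residue range — a fixed scale, not per-sequence, so one threshold is
portable across proteins:

- amyloidogenicity: Chou–Fasman β-sheet propensity × Kyte–Doolittle
  hydropathy (shifted non-negative), which puts β-prone hydrophobics
  (I, V, F) high and charged/turn residues low;
- disorder: the TOP-IDP scale (high for P, E, K, S, Q; low for W, F, Y, I).

`X` is scored as the table mean. Pipeline tests never assert agreement
between surrogates and any published predictor; to use real predictions,
write them as the score-track TSV (`id`, `position`, `amylo_score`,
`disorder_score`) and pass `predictor_mode = "external"`. If an external
tool reports interval candidates rather than per-residue values,
`intervals_to_track()` assigns each residue the maximum score of any
candidate covering it — the maximum preserves "at least one candidate
above threshold" semantics.

## The aligner

The multiple aligner is a deterministic progressive stand-in, not a
reimplementation of any production tool: global affine-gap pairwise
alignment (Gotoh three-state DP, compiled; opening costs
`gap_open + gap_extend`, extension `gap_extend`, end gaps penalised;
BLOSUM62, gap open 10 / extend 0.5 by default), a guide tree from
average-linkage clustering of `1 − identity`, and profile–profile merging
along the tree (profiles are per-column residue frequencies scored as
expected substitution score; once a gap, always a gap). Tie-breaking is
fully specified — residue pairing over gap-in-first over gap-in-second, and
sequences sorted by id before anything else — so alignments are
reproducible and input-order independent. There is no iterative refinement
pass. For analyses where alignment quality matters, import an alignment
computed by a dedicated tool with `import_alignment()`; the column
statistics are agnostic to where the alignment came from.

## The simulator

`simulate_family()` exists to give every downstream stage a ground truth.
It emulates the *shape* of an ortholog family, not realistic molecular
evolution: a uniform-random ancestor, a taxonomy-shaped tree (root → one
ancestor per class → a star of species within the class, branch times
uniform on `branch_length_range`), per-site Poisson substitutions with
uniform replacement among the 19 alternatives, and Poisson indel events
with geometric lengths. One motif interval evolves at a reduced
substitution rate and — by default — receives no indels, so its
coordinates are tracked exactly into every tip (`allow_motif_indels`
relaxes this). `synthesize_score_tracks()` then paints score tracks from
the truth: mean 0.8 inside the motif, 0.2 outside, optional Gaussian noise
clipped to [0, 1], disorder constant at 1.

Defaults: 160-residue ancestor, motif at 61–100 (40 residues), background
0.3 substitutions/site per unit branch time with the motif at 0.2× that
rate, indel rate 0.01 events/site with mean length 3, branch times uniform
on (0.4, 1). These produce families whose background pairwise identity
across classes is low (≈30%) while the motif stays well-alignable —
deliberately a *hard* case for the flank alignment and an easy one for the
motif, which is what the recovery statistic needs. What passing tests show
is that the projection/CAP machinery recovers a region that is truly
conserved and truly amyloidogenic; they do not show that any real
predictor's scores behave like the painted tracks, nor that real indel
processes spare functional motifs.

## Numerical choices and degenerate inputs

- Coordinates are 1-based closed intervals everywhere (residues and
  columns); every exported TSV states this in a comment header.
- Thresholds are strict inequalities; a residue at exactly 0.575 (or
  disorder exactly 0.3) is excluded.
- All randomness flows through `derive_seed(seed, stage, index)` (a 31-bit
  string hash), so each stage and replicate has its own stream and adding
  stages never perturbs existing ones.
- Fisher's exact test: two-sided p by the probability-mass method (the sum
  of hypergeometric probabilities ≤ the observed table's, with 1e-7
  relative slack for ties), delegated to `stats::fisher.test` and verified
  in the tests against exhaustive enumeration; a zero margin returns p = 1
  by convention with a message. The odds ratio reported is the sample
  `(ad)/(bc)` with 0/`Inf`/`NA` handled explicitly.
- Aggregation-assay proportions come with two standard errors: the Wald
  `sqrt(p(1−p)/n)`, which collapses to 0 at k = 0, and an Agresti–Coull
  adjusted SE (add two successes and two failures), which does not. Both
  are reported because published error bars on such proportions are often
  nonzero at 0% and their definition is rarely stated; the adjusted form
  is the safer default display.
- Empty results are explicit: a filtration that removes every class warns
  and returns a zero-row table with metadata rather than failing silently.

## Validation scale

The test-suite and acceptance-script simulations use 10 families of 6
classes with 4–15 species each (the scale at which class filtration,
downsampling and multi-replicate alignment all engage), 10 replicates per
family, and 20 seeds for the paired CAP-inside-vs-outside comparison;
pairwise-aligner correctness is checked against a brute-force
memoized-recursion oracle on sequences up to length 12, and the Fisher
p-value against exhaustive enumeration of all 2×2 tables with total ≤ 30.

## Known limitations

- The progressive aligner has no refinement pass and will be beaten by
  modern aligners on hard families; it is a vehicle for the column
  statistics, with an import path for better alignments.
- Surrogate scores are propensity smoothing, not structure-aware
  prediction; conclusions about a real protein family should use imported
  predictor output.
- The simulator has no site-rate heterogeneity beyond the motif, no
  empirical substitution matrix, and no curation-style outliers (e.g.
  sequences with very long indels); the class-size filter is the only
  curation step modelled.
- Replicate aggregation deliberately avoids merging column spaces; there
  is no single "consensus coordinate" track across replicates.
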