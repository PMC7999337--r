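---
title: "Comparing SV callsets and their clinical performance with svconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SV callsets and their clinical performance with svconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svconcord)
library(dplyr)
```

## The problem

When two sequencing platforms — say standard whole-exome sequencing (WES)
and linked-read exome sequencing — are applied to the same tumor samples
and their reads pushed through the same structural-variant (SV) caller,
the resulting callsets can differ enormously in volume, type composition
and clinical usefulness. `svconcord` provides the evaluation machinery for
that comparison: callset concordance under a reciprocal-overlap rule,
detection of the cytogenetic events that matter clinically in multiple
myeloma (MM), ROC/AUC benchmarking against FISH as the gold standard,
SV-hotspot burden annotation, and a somatic short-variant filter cascade.
A synthetic-data generator reproduces the statistical signatures of the
two platforms so that every stage runs, and is tested, without any
external sequencing data.

## Coordinate conventions

All coordinates inside the package are 0-based half-open intervals; the
conversion from 1-based VCF happens once, at the I/O boundary. A VCF
record with `POS = 100` and `END = 200` becomes the interval `[99, 200)`.
The synthetic VCF writer emits `END = POS + |SVLEN| - 1`, so on generated
data an interval's length always equals `|SVLEN|` and records round-trip
bit-exactly. Manta's own convention places a padding base at `POS`
(`END = POS + |SVLEN|` for deletions); when reading such files the stored
interval is one base longer than `|SVLEN|`, which is irrelevant for the
70% overlap rule but worth knowing when cross-checking lengths.

Chromosome names are normalized by stripping a leading `"chr"` (a
configurable policy), because callsets, cytoband files, truth tables and
hotspot catalogs routinely come from mixed sources.

## Records, breakends and translocations

`read_sv_vcf()` keeps every candidate record, including those failing the
caller's FILTER and those shorter than 50 bp (flagged `is_sub50`): the
candidate tier and the quality-filtered tier are both legitimate objects
of analysis, so filtering is always a downstream predicate
(`pass_only = TRUE/FALSE`), never an import-time decision.

Translocations arrive as pairs of BND rows whose `MATEID` fields
reference each other. `pair_breakends()` collapses mutually referencing
pairs into one translocation event and moves every breakend whose mate is
absent, ambiguous (duplicated id) or non-reciprocal into an `unpaired`
table — nothing is dropped silently. The operation is a pure function of
the record table, hence idempotent and invariant to record order, and the
tests verify it against a brute-force all-pairs mate search. Only
inter-chromosomal pairs count as translocations for the event panel; the
caller does not document whether intra-chromosomal BND pairs should be
treated as inversions, so they are retained in the event table with an
`inter = FALSE` flag and excluded from panel scoring by default.

## Concordance: the 70% reciprocal-overlap rule

Two interval SVs of the same type match when their shared span is at
least a fraction F (default 0.70) of *both* interval lengths — the
bedtools `-f 0.70 -r` semantics. Whether the original comparison was
reciprocal or one-sided is not documented, so `reciprocal = FALSE`
switches to the one-sided rule. "Shared" counts unique A-side features
with at least one qualifying B match (the directional convention of
unique-feature overlap reporting); ties do not multiply counts, and
`shared + a_only = n_a` holds by construction.

Two conventions deserve a note:

* **Insertions** are points, so reciprocal span overlap is undefined;
  INS records match by insertion-point proximity, default 50 bp
  (`ins_window`).
* **Translocations** lack an end position and are compared separately:
  two events match when their unordered chromosome pairs agree and each
  corresponding breakend lies within `translocation_window` (default
  10 kb — the criterion used in the original R comparison is unstated,
  so the window is explicit configuration). Breakend correspondence is
  resolved by chromosome; for intra-chromosomal events the assignment
  minimizing the maximum displacement is used.

`match_callsets()` is tested for exact agreement with an O(n²)
brute-force matcher over random callsets, for monotonicity in F, and for
total self-concordance.

## The ten-event MM panel

The panel holds the alterations routinely assayed by FISH in MM:
del(1p), gain(1q), del(13q), del(14q), del(17p), and the IGH
translocations t(4;14), t(6;14), t(11;14), t(14;16), t(14;20). The
del(17p) choice follows the clinically standard arm (17p, where TP53
resides); a del(17q) event is equally constructible through
`build_event_panel()`'s arm table if needed.

Arm regions come from a cytoBand file: each arm is the union span of its
p* or q* bands. The bundled `default_arm_map()` is a coarse
two-band-per-chromosome GRCh38 table with approximate centromere
boundaries — arm-level resolution is all the panel semantics need; supply
a full cytoBand file for band-accurate arms.

Scoring is deliberately simple and transparent: an arm-loss event is
supported by every PASS deletion overlapping the arm by at least 1 bp
(gains likewise over duplications; no size threshold by default, since
none is documented — `min_sv_size` is exposed), and a translocation event
by every paired inter-chromosomal breakend event joining that chromosome
pair. Scores are therefore non-negative integers, monotone in the record
set, and reproducible by a per-record classification loop (the oracle
used in the tests).

## ROC/AUC against FISH

FISH labels over the (sample × event) grid are the truth; the per-event
SV support counts are the prediction scores. Binary FISH comparisons do
not by themselves yield a continuous ROC curve; using support counts as
the score is the declared convention here, giving one operating point per
unique count. A cell is predicted positive when its score reaches the
threshold; sweeping the threshold over the unique scores (plus a sentinel
at +Inf) produces a curve that provably starts at (0,0), ends at (1,1)
and is monotone in both coordinates. The AUC is computed by the trapezoid
rule, which gives tied scores half credit and makes the AUC exactly the
Mann–Whitney concordance probability — an identity the test suite checks
to 1e-12 by exhaustive pair enumeration on a thousand random instances.
Sensitivity is TP/P and specificity TN/N.

Confidence intervals use a percentile bootstrap (2000 replicates by
default) over resampled grid cells, redrawing degenerate resamples with
no positives or no negatives; the original method behind the published
intervals is unstated, so the bootstrap is the package's own documented
choice. P ≥ 1 and N ≥ 1 are required — AUC is undefined otherwise, and
the grid convention (which negatives are enumerated) is explicit in the
truth table rather than implicit in the code.

## Hotspot burdens

A hotspot catalog is a table of recurrently rearranged regions
categorized `gain`, `loss` or `fragile`. "Falling within" a hotspot is
interpreted as breakpoint containment by default: an SV hits a hotspot
when one of its interval endpoints — or either breakend, for
translocations — lies inside the region. This is robust for very large
SVs that span many hotspots end to end; whole-interval overlap semantics
are selectable (`mode = "overlap"`). A hotspot counts once per sample
however many calls support it, supporting calls are listed, and no
category/type consistency is imposed by default (a duplication may
support a loss hotspot) because the original counting imposed none.

The bundled `hotspots_mm_synthetic.tsv` is a synthetic stand-in catalog
with the published category structure of the MM hotspot landscape
(68 regions: 49 gain, 19 loss); it exists so the machinery runs and is
tested offline, and it is not the published table (which must be supplied
by the user, pre-converted to the working assembly — no liftover is
performed, and absent entries are simply absent rows).

## The short-variant filter cascade

Annotated somatic short variants pass through eight rules, in order:
caller filter (PASS required), genomic region (intronic and intergenic
dropped), exonic function (synonymous and non-frameshift dropped),
population allele frequency (any of three population AFs above 1%
dropped; a missing AF means a novel variant and is kept), calling quality
(< 40 dropped), depth (< 10 reads dropped), VAF (outside [2%, 30%]
dropped), and strand odds ratio (> 3 for SNVs, > 11 for indels dropped).
A removed variant is attributed to the first rule it fails; the kept set
is provably order-invariant (a variant survives iff it fails no rule),
and `kept + sum(removed) = n_input` always. Window and threshold
boundaries are inclusive on the kept side (VAF exactly 2% or 30% is
kept; SOR exactly 3 is kept for an SNV).

For cross-dataset overlap, variants are keyed by (chrom, pos, ref, alt)
after allele left-normalization — shared suffix then prefix trimmed with
the position advanced — because a 70% overlap rule is ill-defined for
1-bp substitutions; exact keyed identity is the default overlap notion
for short variants.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical* structure the analysis
consumes, not sequences or reads:

* **Type compositions**: the `wes_like` profile uses the WES composition
  (DEL 56.3%, INS 32.6%, translocations 6.7%, DUP 3.3%, INV 1.2%; the
  printed percentages sum to 100.1% and are renormalized — the profile
  constructor warns when handed an off-unit composition).
  `linkedread_like` is inversion-dominated (92.4%) with zero insertions,
  the residual split DUP-heavy (6.6% DUP, 0.3% DEL, 0.3% BND,
  renormalized); the residual split is a declared convention, as only the
  INV share and the absent insertions are documented.
* **Volumes**: default expected call counts are 4065 (`wes_like`) and
  18455 (`linkedread_like`) per sample, the two platforms' mean candidate
  volumes.
* **Size spectra**: log-normal with per-type medians (5 kb for
  DEL/DUP/INV, 100 bp for INS, sigma 1 on the log scale) — no size
  spectra are documented, so these are the package's fixed choice of a
  realistic spectrum; a `sub50_fraction` (default 0.2) of background
  calls is drawn at 10–49 bp to exercise the sub-50 bp candidate flag.
* **Genome model**: the arm map itself; calls are placed uniformly within
  arms, breakend pairs as mutually `MATEID`-referencing BND rows.
  Coordinates, not sequence, drive every downstream computation, so no
  reference FASTA is needed.
* **Truth and detection**: `simulate_truth()` plants panel events as
  Bernoulli draws (default prevalence 0.175, giving about 14 positives on
  an 8-sample × 10-event grid, the regime of a small MM cohort);
  `generate_callset()` emits one supporting call per planted event with a
  configurable per-method sensitivity, on top of the background
  composition.

What it does **not** emulate: read-level error, coverage structure,
capture bias, breakpoint microhomology, caller-specific FILTER behaviour
(every generated record is PASS), or any correlation between events.
Passing tests on synthetic data therefore demonstrate that the
*evaluation machinery* is correct and well-calibrated — they say nothing
about how either platform performs on real tumors.

## Simulation designs used in the tests

Problem sizes are chosen so the full suite runs in minutes: the overlap
oracle runs 100 random callset pairs up to 500 records per side at
F ∈ {0.5, 0.7, 0.9}; the AUC identity runs 1000 random score/label
vectors up to n = 50; composition recovery uses 10,000 calls per profile
(±0.02 per type).

The parameter-recovery experiment deserves a note on design. Detection
sensitivities of 0.9 and 0.5 are planted for two simulated platforms.
Sensitivity is re-estimated over 200 planted events in a background-free
run, where "any supporting call" is a consistent estimator (with
background present it is biased upward by construction), and checked
against exact 95% binomial intervals. The AUC-ordering claim — the
higher-sensitivity platform wins in at least 95 of 100 replicates of an
8-sample cohort — is tested with both experiment arms sharing an
*identical* background process (same composition, 50 background calls per
callset on the real arm map), so the only difference between arms is the
planted sensitivity. Giving each arm its own platform composition would
confound the contrast: a deletion-heavy background inflates arm-loss
scores while an inversion-dominated background contributes none, and the
comparison would then measure background asymmetry rather than
sensitivity. The 50-call background level corresponds to the
quality-filtered call tier, where clinically oriented scoring operates.

## Numerical choices and degenerate inputs

* Overlap fractions are exact rational arithmetic on integer
  coordinates; no floating-point tolerance enters the matching decision.
* AUC ties receive half credit via the trapezoid rule; tie-free scores
  satisfy AUC(s) + AUC(−s) = 1 exactly.
* Empty callsets: composition is an error (proportions undefined);
  panel scoring returns an all-zero row; hotspot annotation returns no
  hits.
* Truth tables must be complete 0/1 grids — a missing cell is an error
  naming the sample and event, and a "possible" FISH finding must be
  resolved to 0 or 1 by the user, not guessed by the package.
* All-positive or all-negative truth makes the ROC an error, not a
  silent NaN.
* The bootstrap redraws degenerate resamples rather than returning NA,
  keeping the interval defined whenever the point estimate is.
* `run_pipeline()` never overwrites an existing report bundle unless
  asked, records the seed and a config hash in its manifest, and skips
  the ROC stage with an explicit notice when no truth table is
  configured.

## Known limitations

* Arm-level scoring treats any overlapping PASS deletion as support for
  an arm-loss event; it does not estimate copy number, and focal
  deletions on an arm are indistinguishable from arm-level loss at this
  resolution.
* Translocation events are matched at chromosome-pair granularity, not
  at locus windows (e.g. 4p16 for t(4;14)); a per-event breakend-region
  restriction would sharpen specificity on real data and can be layered
  on top of the panel table.
* Hyperdiploidy and trisomies are outside the ten-event panel and are
  not called.
* The three-way short-variant comparison uses exact keyed identity after
  normalization; complex equivalent representations (MNV decompositions)
  are not unified.
* The synthetic generator's independence assumptions (events independent
  across samples and of each other, uniform placement) understate the
  clustering of real rearrangements.
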