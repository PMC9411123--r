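---
title: "Paired DNA-RNA splicing analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired DNA-RNA splicing analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedx)
library(dplyr)
```

## The problem

Germline panel testing for hereditary cancer predisposition reads the coding
exons of DNA plus a thin intronic margin. Variants that act through mRNA
splicing — especially deep-intronic ones that create or strengthen cryptic
splice sites — are invisible to that design, and even detectable splicing
variants are hard to interpret from sequence alone. Pairing DNA sequencing
with targeted RNA-seq addresses both limits: aberrant junction-spanning reads
reveal the transcript-level consequence, and that consequence serves as
functional evidence for classification.

`splicedx` implements the computational core of such a paired design as a
reusable, fully testable pipeline over splice-junction count tables
(STAR `SJ.out.tab`-style), gene models (BED12/GTF) and DNA variants
(VCF 4.2). Because the real diagnostic cohort is not distributable, the
package includes a first-class synthetic-data generator that emulates the
statistical structure the analysis assumes, so every stage — including the
end-to-end association logic — is exercised by tests without any download.

## Aberrant splicing events

Events are detected per sample by comparing observed junctions with the
canonical isoform's junctions and classified into five types:

* **ESF** — skipping of at least one full exon (both junction ends at
  canonical sites, at least one exon between them);
* **ESP** — an alternative exonic 5'/3' splice site excluding part of an
  exon;
* **ES** — a combination of at least one full and one partial skip;
* **IP** — an alternative intronic splice site including intronic sequence
  flanking an exon;
* **IC** — a cryptic exon: a pair of novel junctions wholly inside one
  intron bounding an exonized interval.

Full intron retention is deliberately *not* emitted: a capture-based junction
assay cannot distinguish retention from background pre-mRNA, so the type is
excluded from the taxonomy.

Design choices the taxonomy needed that the five definitions alone do not
fix:

* A novel junction must carry at least `min_reads = 3` unique reads
  (configurable) to seed an event.
* An IC call requires both novel ends strictly inside one intron and an
  exonized interval of 1–1000 nt; a candidate pair bounding a larger
  interval is left as two flagged junctions rather than auto-classified.
* A single novel junction with one intronic end adjacent to the used
  canonical site is IP; intronic ends in a *different* intron than the
  canonical end produce geometry outside the taxonomy and are returned as
  `UNCLASSIFIED` with a reason, never silently dropped.
* Event identity across samples is the sorted tuple of novel junction
  coordinates.

The classifier is verified against an independent oracle that derives the
event class from pure interval arithmetic (which exonic sequence is excluded,
which intronic sequence stays included), enumerated exhaustively over all
junction-end placements on 2–4-exon toy genes.

## PSI and the control pool

For an event with novel junction reads $a$ and reads $c$ on the canonical
junctions sharing a splice region with it,

$$\mathrm{PSI} = \frac{a}{a + c},$$

with $a$ the sum over the event's novel junctions (for an IC pair, the mean
of the two flanking junction counts, rounded half-up) and $c$ the rounded
mean over the sharing canonical junctions (for IC, the canonical junction of
the host intron). The denominator is junction-only: exon-body coverage is
not part of the region total. This makes PSI computable from junction tables
alone and matches sashimi-style read counting in which only junction reads
enter the PSI of an event. A zero denominator yields an undefined PSI with a
`no_coverage` flag rather than a numeric value.

Each event is profiled across a healthy-donor control pool (345 donors in
the emulated design): controls lacking the junction contribute PSI 0 when
canonical coverage exists and are excluded (and counted) when they have no
coverage at all. A carrier observation is **specific** when its PSI is at
least `min_psi = 0.10` *and* at least `fold = 5` times the control pool's
95th-percentile PSI; observations with denominator below
`min_denominator = 100` are *indeterminate*. The clinical criteria this models are
qualitative ("absence of the event at similar PSI in healthy controls"), so
the floor/fold quantification is this package's operationalization; both
knobs are exposed.

Coverage gates: events whose PSI denominator is below 500x require
orthogonal RT-PCRseq confirmation (strict inequality — exactly 500 does
not); upgrades are blocked until confirmed. Allelic imbalance at exonic
heterozygous SNPs — an indirect sign of nonsense-mediated decay — is tested
with a two-sided exact binomial test against 0.5 (skewed at p < 0.01,
indeterminate below 20 reads).

## DNA-side rules

* **Quality filter**: variants with Q score ≤ 30 *and* allele fraction
  < 10% are dropped. The clinical rule is stated as a conjunction and is
  implemented that way; because the clinical intent could also be two
  independent filters, a disjunctive mode is available behind a config
  switch, conjunction default.
* **Sanger exemption**: SNVs and ≤ 3-nt indels with allele fraction > 35%
  and ≥ 100x coverage skip confirmation; low-coverage regions and
  pseudogene-flagged calls always confirm. "100x coverage" is read
  inclusively (≥ 100).
* **Reporting range**: coding exons ± 5 intronic nt. Beyond it, a variant
  is reportable *only* with abnormal RNA detected; masked variants go to a
  separate audit table and can never reach a report (a property test sweeps
  a 1500-variant synthetic table and a full simulated cohort).
* **Splicing candidates**: in-silico deleterious, intronic within ± 5 nt,
  or abnormal RNA detected.

## Position bins

Variant positions use HGVS-style cDNA coordinates with signed intronic
offsets (`c.423-3958C>T`), parsed and formatted round-trip. Positions are
binned as exonic-internal, exonic last nucleotide (the donor-critical
position, singled out), canonical ± 1/2, intronic 3–5, 6–10, 11–20, and
> 20 nt. The bins partition every nucleotide of a gene; this is checked
exhaustively. Whether first-exonic-nucleotide variants should share the
last-nucleotide bin is a genuinely open choice; they are
binned `EXONIC_INTERNAL` here, and the alternative would only relabel the
acceptor-side analogue.

## Splice-site strength and mechanism

In place of a deep-learning splice predictor (out of scope), site strength
is a log-odds position-weight-matrix score over fixed windows: donor 9 nt
(exonic −3..−1 + intronic +1..+6), acceptor 23 nt (intronic −20..−1 +
exonic +1..+3), against a uniform background; `N` contributes zero. The
frequency tables are bundled as versioned CSV in the style of classical
mammalian consensus matrices; deriving them from the synthetic panel itself
would be circular (the generator embeds the consensus), so a fixed bundled
matrix is the cleaner design. The score is monotone toward consensus by
construction, which a property test confirms.

Mechanism inference scans every donor/acceptor window overlapping a variant
for both alleles and applies, in priority order: deletion overlapping the
branch-point window (18–44 nt upstream of a native acceptor — standard
branch-point biology) →
`BRANCH_POINT_DELETION`; native-site score drop ≤ −2 →
`NATIVE_SITE_WEAKENING`; non-native gain ≥ +2 → `NOVEL_SITE_CREATION`;
exonic substitution with an associated exon-skip event but no site-score
change → `POSSIBLE_ESE_DISRUPTION` (a flag, not a quantitative ESE model);
otherwise `UNKNOWN`. The ± 2 log-odds threshold is calibrated to the
weakest single-base consensus gain the bundled donor matrix treats as
meaningful (C→T at +6 scores +2.58).

## Association and reclassification

Association of an event with a variant weighs four strands of evidence: PSI
elevation, specificity against controls, reproducibility in additional
carriers of the same variant, and a plausible mechanism. The rule engine
declares `associated` when a specific event exists within ± 5000 nt of the
variant (covering the deep-intronic offsets seen in practice, up to ~4 kb)
and either at least one additional carrier reproduces it or the mechanism is
known. Absence of any event at adequate junction coverage is a determinate
negative; thin coverage or missing RNA yields `indeterminate`.

Reclassification replaces manual expert review with a deterministic,
reasoned rule set: VUS + associated + coding-region-altering event
(+ confirmation when coverage demands it) upgrades to LP; a
splicing-candidate VUS with a determinate negative at |offset| > 2
downgrades to LB; associated events under prior P/LP confirm without
counting as reclassifications; tandem-configured gross duplications with a
frameshifting back-junction upgrade. Guard invariants — no upgrade without
specificity, no downgrade on indeterminate coverage — are enforced by tests
with adversarial control pools.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the study conditions end to end:

* a 345-donor control pool whose per-event baseline PSI is drawn from
  Beta(0.5, 99.5) (mean 0.005) — low-level physiologic alternative
  splicing; the baseline level is a stated assumption of the generator;
* heterozygous carriers whose blueprint event is sampled binomially around
  a true PSI drawn from 0.30–0.50, the plausible heterozygous range after
  partial transcript decay (real per-event PSI magnitudes are reported only
  as plot distributions, not numerically); an `nmd_attenuation` multiplier
  (default 1.0) emulates decay when set below 1;
* 15 deleterious variants × 2 carriers each plus 20 benign single-carrier
  variants (50 carriers). Two carriers per deleterious variant is the
  deliberate default: bulk blueprint variants carry no engineered sequence,
  so reproducibility — not mechanism — is their realistic route to
  association. The four packaged fixtures exercise the mechanism route
  instead;
* deterministic, bitwise-reproducible output given the seed.

The four fixture cases engineer toy genes whose sequences realize the
canonical deep-intronic scenarios: a +6 C>T strengthening a cryptic donor
(IC), a −1 A>G creating an acceptor (IC), a +2 A>T creating a donor (IC),
and a 2827-nt intronic deletion removing a native acceptor's branch point,
re-routing splicing through two preexisting cryptic acceptors (two IP
events). Intronic offsets are kept at their realistic magnitudes (−3958,
−2661, −3384, +672/−23) so binning and masking run at the real values,
while coding-anchor positions are scaled to toy-gene sizes where necessary.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment and mapping artifacts, capture
efficiency gradients, overdispersed junction counts (reads are exactly
binomial), pseudogene interference, multi-gene panels with overlapping
events, isoform-level expression differences, and tissue-specific
physiologic splicing that makes real control pools noisier than a Beta
baseline. The pipeline's statistical behaviour on real cohorts must be
calibrated against real controls.

## Numerical choices

* Percentages print to one decimal, round half up.
* The IC numerator is the rounded-half-up mean of the flanking junction
  counts (minimum would be the conservative alternative; mean matches how
  both flanks evidence the same exonized segment).
* Per-patient frequencies ("one per N") default to nearest-integer
  rounding; a ceiling mode exists because a "one per N" figure for, say,
  45 carriers of 43,524 patients is ambiguous between conventions
  (43,524/45 = 967.2 rounds to 967 nearest, 968 ceiling).
* Quantiles use the default continuous type-7 estimator.
* Degenerate inputs: zero PSI denominators flag rather than divide; empty
  control manifests abort before any computation; junctions outside every
  gene span warn and are ignored.

## Problem sizes used by the test-suite and acceptance script

Exhaustive taxonomy enumeration runs on 2–4-exon toy genes (169 junction
placements); PSI recovery uses 500 replicates per level at depth 1000 over
four true-PSI levels; masking safety sweeps 1500 synthetic variants; the
end-to-end check runs the full 345-control, 50-carrier cohort. These sizes
make every property statistically meaningful while keeping the whole suite
in the order of a minute of CPU.
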