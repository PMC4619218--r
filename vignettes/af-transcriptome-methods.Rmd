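---
title: "Methods: amniotic-fluid cell-free RNA analysis across gestational stages"
author: "afmaturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amniotic-fluid cell-free RNA analysis across gestational stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmaturity)
```

## The problem

Amniotic fluid carries cell-free RNA shed by fetal tissues. Profiling it at
different gestational ages — a small prenatal group sampled at
amniocentesis (18–24 weeks), late preterm (34–36 weeks) and term (39–40
weeks) deliveries — exposes gene programs that mature with gestation and
tissue signatures (lung surfactant, oropharyngeal mucosa, skin, gut) whose
presence indicates organ maturity. The cohort structure this package
mirrors is small and unbalanced (4/6/6 samples), with clinically annotated
morbidity subgroups (respiratory support, gavage feeding) of only three
infants each, which dictates most of the statistical choices below.

## Normalization and filtering

`tmm_normalize()` computes a per-sample scaling factor as 2 to the weighted
trimmed mean of per-gene log2 ratios against a reference sample (the one
whose upper-quartile expression is closest to the cross-sample mean).
Ratios are taken on raw values, so the factor absorbs sequencing depth as
well as composition bias; the default trims are 30% per tail by log-ratio
and 5% per tail by average abundance, with inverse approximate binomial
variances as weights. Factors are rescaled to geometric mean one, which
makes the two-sample case with one library exactly doubled resolve to
(1/√2, √2). Genes are then kept when any sample exceeds 1 RPKM
(`filter_expressed()`), a strict inequality.

## Stage-wise differential expression

`anova_stage_test()` runs, per gene, a one-way F-test across the three
stages on log2(value + 1). The pseudocount of 1 bounds the transform at
zero expression and is standard for RPKM-scale data. ANOVA p-values are
Benjamini–Hochberg adjusted (`benjamini_hochberg()`, a validated front-end
to the step-up procedure). The three paired comparisons (PN/FT, PN/PT,
PT/FT) use the classical pooled two-sample t on the same log scale.

Fold change is reported as the ratio of linear group means with the
pseudocount acting as a *floor* on each mean, `max(m2, 1)/max(m1, 1)`,
rather than an addend. A floor keeps folds bounded when a group is
essentially unexpressed, yet reports the intuitive value for well-expressed
genes (group means 1 and 8 give fold 8, where adding the pseudocount to
both would report 4.5 and understate every fold). Direction is reported
with the later stage in the numerator, so "up" always means higher with
advancing gestation. A gene is differential when adjusted p ≤ 0.05 and at
least one paired fold reaches 1.5.

Degenerate genes (zero variance everywhere) get F = 0 and p = 1 rather than
NaN. Because of the pseudocount, the test is exactly invariant to sample
reordering but only asymptotically invariant to a uniform rescaling of all
samples; on realistically expressed data the differential call set is
stable under rescaling, which is what the suite asserts.

## Temporal trend classification

`classify_temporal_patterns()` labels differential genes. The default
`"sign"` method requires log-scale stage means to move monotonically
PN → PT → FT, allowing one flat step (tolerance 1e-8). The `"som"` method
trains a one-dimensional self-organizing map (k nodes, default 2;
rectangular grid; Gaussian neighbourhood with radius decaying linearly from
k/2 to 0.3; learning rate 0.5 → 0.01 over 500 epochs; seeded) on z-scored
stage-mean triples, and labels each node induced or suppressed by the slope
of its codebook vector. On noiseless planted data both methods agree for
every planted monotone gene, which is the property the suite tests; the SOM
additionally groups genes with similar shapes when patterns are noisy.

## Moderated t-test for morbidity subgroups

With three infants per morbidity group, per-gene variance estimates are
unusable on their own. `moderated_t_test()` shrinks the pooled per-gene
variance s² (d residual df) toward a prior: s̃² = (d₀s₀² + d·s²)/(d₀ + d).
The prior (d₀, s₀²) is estimated by moment matching on the log sample
variances: writing e = log s² − digamma(d/2) + log(d/2), the excess of
var(e) over trigamma(d/2) identifies trigamma(d₀/2), inverted by Newton
iteration, and the mean of e then gives s₀². The moderated statistic uses
d + d₀ degrees of freedom; when the observed variances are consistent with
a single value the prior df is infinite and the test tends to a z-test.
Setting `prior_df = 0` recovers the ordinary pooled t exactly, and the
Monte-Carlo check in the suite confirms the moderated test's power
advantage at n = 3 vs 3. A gene is "regulated" at adjusted p ≤ 0.05 and
fold > 2 — deliberately stricter on fold than the stage analysis, because
small groups inflate fold estimates.

## Tissue and cell of origin

Two independent approaches are implemented.

*Atlas scoring.* `abundant_genes()` takes, per stage, genes whose mean
across that stage's samples strictly exceeds the 90th percentile
(linear-interpolation quantile) of all gene means in the stage — the
percentile is interpreted per stage because the downstream comparison
(`stage_marker_profile()`) is across stages. `score_tissue_specificity()`
scores genes against a gene-by-tissue atlas: the candidate tissue is the
argmax (ties disqualify specificity), *enriched* means ≥ 3× the mean of all
other tissues, and *specific* additionally requires ≥ 1.5× every other
tissue. The stage profile reports, per tissue, the fraction of its specific
markers (those present in the expression matrix — absent genes are not
penalized) that are abundant at each stage.

*Marker-set enrichment.* `marker_enrichment()` tests each marker set
against a query gene list with the one-sided exact hypergeometric tail
P(X ≥ r) and reports the finite-population z-score
(r − nR/N)/√(n(R/N)(1 − R/N)(1 − (n − 1)/(N − 1))). Sets are intersected
with the universe before testing and empty intersections are skipped.

*Fetal origin.* `check_fetal_origin()` predicts each sample's fetal sex by
comparing mean chrY marker expression (RPS4Y1, DDX3Y, EIF1AY) with XIST —
male when chrY exceeds XIST — and flags concordance with the recorded sex.
Missing markers downgrade the prediction to "unknown" rather than erroring.

## Splicing analysis

Junction files are the BED12 dialect emitted by spliced aligners: a record
spans both exonic anchors as two blocks with the junction read count in the
score column; `read_junctions_bed()` derives 0-based half-open intron
coordinates from the block structure and skips (with a count) records whose
block number is not two. Strand is carried but ignored by detection, since
aligner-assigned junction strands are unreliable for short reads.

`detect_reciprocal_events()` works purely on coordinates: for a candidate
exclusion junction E, inclusion candidates share exactly one boundary with
E and end strictly inside its span. A left- and a right-anchored candidate
whose inner boundaries delimit a non-empty implied exon form a cassette
event (two inclusion junctions); candidates in no such pair form
single-inclusion alternative-splice-site events. Event ids are built
deterministically from sorted coordinates. The implementation is
hash-grouped by boundary; the test suite holds it equal to an independent
brute-force enumeration over random instances.

`compute_psi()` averages the inclusion junction counts of a cassette (so
PSI stays in [0, 1]) and reports PSI = inclusion/(inclusion + exclusion),
missing below 10 combined reads — a coverage floor chosen so that a PSI
value is never computed from fewer reads than could distinguish a 0.1
difference. `compare_psi_groups()` uses a two-sided Wilcoxon rank-sum test
with |ΔPSI| ≥ 0.1, unadjusted: with six samples a side the smallest
achievable exact p is ~0.002, so multiplicity correction would simply
disable the test. `filter_against_panel()` calls an event "found" in a
reference junction panel when its exclusion junction and at least one
inclusion junction match coordinates exactly; events absent from a deeply
sequenced adult/placental panel are candidate fetal-specific isoforms.

## The synthetic study generator

`simulate_study()` emulates the cohort: group sizes 4/6/6; morbidity flags
among the late preterm samples planted as 3 respiratory support and 3
gavage feeding with one infant carrying both; alternating fetal sexes.
Expression is log2-normal, 2^(μ + N(0, σ)) with σ = 0.4 by default —
positive values with multiplicative noise, the standard model for
RPKM-scale data. Planted structure:

- 200 monotone genes moving 1.5 log2 units per stage step, half induced and
  half suppressed. Their baselines are drawn Uniform(3, 6) on the log2
  scale so that a suppressed gene starts well expressed — a transcript
  declining from zero is unobservable in principle.
- A 66-tissue atlas with 10 markers per tissue, each 8-fold above that
  gene's level in the other tissues. Only 10 tissues are "AF-relevant":
  their markers are expressed in AF with per-stage activity fractions on a
  0.2 grid (active markers at log2 ≈ 10, inactive ≈ 0.5). Keeping the
  active-marker count near 50 per stage places them safely inside the
  top-decile abundance slots of a 2000-gene matrix, so the planted activity
  table is exactly recoverable.
- Sex markers XIST/RPS4Y1/DDX3Y/EIF1AY at log2 6 against ~0.03 for the
  inactive sex.
- 50 cassette-exon events on a synthetic chromosome, true inclusion 0.5
  shifted by ±psi_shift/2 between the late preterm and term groups
  (alternating sign). Per-sample counts are binomial at the group's true
  PSI with Poisson depth jitter around 60 reads; zero-count junctions are
  omitted from the BED files, as aligners omit unobserved junctions. Half
  of the events (seeded) are copied into a synthetic reference panel so the
  panel filter has a planted found/absent truth.

What the generator does *not* emulate: maternal RNA contamination, gene
length and GC effects, count overdispersion beyond log-normal noise,
correlated co-expression modules, and annotation-dependent event types
(intron retention, mutually exclusive exons). Passing recovery tests on
this generator therefore demonstrates the pipeline's correctness, not its
power on real cell-free RNA, where effect sizes and depths are unknown.

All randomness flows from a single integer seed; the same seed gives a
byte-identical bundle and, through `run_all()`, a byte-identical
`summary.json`.

## Numerical choices and degenerate inputs

- Quantiles are linear-interpolation (R type 7) throughout; abundance cuts
  are strict, so a constant matrix has no abundant genes.
- Argmax ties in atlas scoring disqualify specificity; all-zero atlas rows
  are skipped with a warning.
- Zero-variance genes: ANOVA and moderated t report p = 1 when means agree
  and p = 0 when they differ with zero residual variance.
- The trigamma inverse is solved by Newton iteration (relative tolerance
  1e-10); a non-positive excess of var(log s²) yields an infinite prior df.
- TMM errors on all-zero samples, naming them; heavy trims on tiny gene
  sets fall back to the untrimmed weighted mean.
- Problem sizes in the validation suite — 2000-gene matrices, 50 null
  replicates for type-I checks, 500 random instances for the detection
  oracle, 60 Monte-Carlo replicates for the power comparison — were chosen
  as the smallest sizes at which the binomial/normal error bounds used in
  the assertions are comfortably discriminating.

## Known limitations

- Fold changes use a pseudocount floor; folds for genes expressed near the
  floor are conservative.
- Event detection is coordinate-only; without annotation, alternative
  5' and 3' splice sites are not distinguished from each other and gene
  assignment requires a user-supplied junction-to-gene map.
- The moderated-t prior is estimated by moment matching rather than
  maximum likelihood; with very few genes (< ~50) the prior df estimate is
  noisy.
- The SOM is an online algorithm and depends on its seed; the default
  method for trend classification is the deterministic sign rule.

## A minimal run

```{r example, eval = FALSE}
res <- run_all(run_config(seed = 1), out_dir = "af_run")
res$summary$n_differential
res$stage_profile
```
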