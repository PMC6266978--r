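---
title: "Methods: DNA-methylation stratification of atRA sensitivity"
author: "atRAmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-methylation stratification of atRA sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atRAmeth)
```

## The problem

All-trans retinoic acid (atRA) is a differentiation-inducing retinoid
with low systemic toxicity, but unstratified use in breast cancer has
shown little overall benefit: triple-negative breast cancer (TNBC)
models span the whole range from tumor regression to outright
tumor promotion under atRA. Classical candidate predictors (the
FABP5/CRABP2 shuttling-protein ratio, receptor expression) do not
separate responders from non-responders. The working hypothesis behind
this package is that baseline CpG methylation does: a small panel of
CpG probes, discovered by supervised comparison of in-vivo-phenotyped
models and refined on patient-derived xenografts (PDXs), can classify
an untreated tumor as predicted-sensitive, ambiguous, or resistant.

`atRAmeth` implements that pipeline end to end:

1. **Phenotyping** — xenograft growth records to three response
   categories and a binary supervision contrast.
2. **Expression** — moderated differential expression at baseline and
   on per-model atRA induction; efficiency-corrected qPCR.
3. **Methylation** — probe blacklist filtering, moderated differential
   methylation, CpG-island context, probe-to-gene mapping, and the
   three-way gene-set intersection nominating methylation-regulated
   genes.
4. **Motifs** — direct-repeat response-element (RARE/PPRE) scanning
   and gene proximity within a fixed window.
5. **Classification** — cross-platform probe harmonization,
   PDX-augmented refinement to a top-*k* CpG signature, and one-at-a-time
   query classification against the labeled reference panel.
6. **Synthesis** — a cohort generator with planted ground truth that
   makes every stage testable without external array data.

## Response phenotyping

For each model the decision variable is the final tumor weight:
`FC = mean(treated) / mean(control)`, with a two-sided two-sample
t-test. Welch's unequal-variance form is the default — arms of 8 mice
with heterogeneous variance are the norm — and the pooled-variance
"student's t-test" is available via `var_equal = TRUE` for strict
replication. Categories are defined by significance plus direction:

* `sensitive` — p < α and FC < 1,
* `promoted` — p < α and FC > 1,
* `resistant` — otherwise (α = 0.05 by default).

The source study does not print the exact rule that produced its
three-way partition, so this rule is declared and exposed rather than
inferred; it is total, and monotone in p (raising p can only move a
model into `resistant`). Two identical constant arms are degenerate
and reported with p = 1. Volume time series are carried through
(caliper convention length × width × depth / 2, recorded as table
metadata) but not modeled; final weight decides.

Phenotype–covariate association uses a two-sided Fisher's exact test
on the 2×2 table of supervision class against a binary covariate;
tables with a zero margin carry no information and return p = 1.

## The shared moderated two-group engine

Both differential expression and differential methylation use one
engine (`two_group_test()`): a pooled-variance linear-model t-statistic
per feature, optionally with empirical-Bayes variance moderation.
Residual variances are modeled as s² ~ s₀²·F(d, d₀); the
hyperparameters are fitted by method of moments on log variances
(digamma/trigamma matching, with a Newton inversion of the trigamma
function), giving the posterior variance

s̃² = (d₀·s₀² + d·s²) / (d₀ + d)

and a t-statistic on d + d₀ degrees of freedom. The limits behave as
expected and are tested numerically: d₀ → 0 recovers the ordinary
pooled t-test, d₀ → ∞ a z-like statistic with the common prior
variance. Small panels (13 cell lines) are exactly the regime where
this shrinkage matters.

Methylation is tested on the M scale, M = log2(β/(1−β)) with β clipped
to [10⁻⁶, 1−10⁻⁶], because M is approximately variance-stabilized for
linear modeling; effect sizes are always reported as Δβ (mean
sensitive-class β minus mean other β), the scale on which arrays are
read and plotted. Both test scales are selectable. No covariates
beyond the two-class factor are used. The default significance rule is
raw p < 0.01 — the only methylation threshold the source analysis
states — with Benjamini–Hochberg q-values always emitted alongside;
recovery is assessed at the raw threshold while false-discovery
control is assessed on the q < 0.05 call set, since a raw 1% threshold
over ~10⁴ mostly-null probes cannot bound the FDR by construction.

The `induced` expression contrast first collapses each model to its
induction value (treated − control log2 expression per feature) and
then tests inductions between classes, matching the notion of
differential atRA-inducibility; testing treated values directly is
available as an option.

## Island context, gene mapping, motifs

CpG-island relations use fixed flanks with a half-open convention:
distance 0 = `island`, [1, 2000) bp from the nearest edge = shore,
[2000, 4000) = shelf, ≥ 4000 bp = open sea; north/south by which side
of the island the probe lies on. A probe exactly 2,000 bp from an edge
is therefore a shelf. Distal probes are never excluded. Probes map to
genes with union semantics (a probe annotated to two genes counts for
both), and the predicted methylation-regulated gene list is the triple
intersection of the differentially methylated, baseline-DE and
induced-DE gene sets.

Response elements are modeled as exact-IUPAC direct repeats of the
canonical nuclear-receptor half-site `RGKTCA`: spacers {1, 2, 5}
(DR1/DR2/DR5) for RARE, {1} for PPRE, both strands, overlapping hits
all reported, and an `N` in the genome never matching a non-N code.
There is deliberately no PWM scoring or mismatch tolerance — the
consensus is declared and overridable via `motif_spec()` rather than
hidden in a tool default. Gene proximity is measured from the whole
gene span (the stated 10-kb window has no anchor point; a TSS-anchored
variant would be a trivial change of the input intervals), with
distance = bp between closest bases, so a hit exactly window+1 bp
beyond the span is excluded.

## Signature refinement and classification

Candidate probes (significant DMPs) are first harmonized to the
probes present on both the HM450 and EPIC platforms — a deployment
constraint, since reference panel and queries may come from either
array. Refinement then re-runs the same two-group test with the PDXs
added to the sensitive class, keeps p < 0.01, and ranks by ascending
p, breaking ties by descending |Δβ| and then probe id (fixed for
reproducibility); the top 6 probes form the signature. With PDXs
removed and the threshold loosened this reproduces the discovery-stage
ranking exactly — same machinery, different labels — which is asserted
in the tests.

Classification is one query at a time, never co-clustering the cohort:
the query is appended to the 17-sample reference matrix over the
signature probes, clustered (Euclidean distance, complete linkage on
β-values by default — common heatmap defaults, recorded in the model
for provenance; Manhattan/correlation and average/Ward are available),
and called by the label purity of the smallest dendrogram cluster
containing the query and at least one reference: all sensitive-class →
`predicted-sensitive`, all other-class → `resistant`, mixed →
`ambiguous`. The underlying appendix rule of the source study is not
printed, so this rule is declared, and pluggable: a
nearest-centroid-with-margin alternative (`rule = "centroid"`, margin
25% of the between-centroid distance) is provided. Degenerate cases
are defined explicitly: a reference panel constant on every signature
probe yields `ambiguous` for any query, and a panel containing only
sensitive references can never produce a `resistant` call.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure of the study's
inputs; it is a testbed, not a simulator of any real dataset.

* **Methylation.** Per-probe baseline M-values from a
  hypo/hyper/intermediate mixture (modes −2.5 / +2.5 / 0, weights
  0.4/0.4/0.2); per-probe residual variances from a scaled
  inverse-chi-square prior (defaults d₀ = 4, s₀² = 0.04 on the M
  scale, i.e. typical per-probe noise sd ≈ 0.2 M-units — array-like
  technical plus modest biological noise). Effects are planted on the
  M scale but specified as β differences: a planted probe gets a
  baseline β₀ drawn so that β₀ ± Δβ stays inside (0.08, 0.92), and the
  sensitive class (sensitive lines + PDXs + truly sensitive queries)
  is shifted by the corresponding M difference, sign random per probe.
  β = 2^M/(2^M+1) throughout, so all emitted values are strictly
  inside (0, 1) and the β↔M round trip is exact to numerical
  precision.
* **Design.** Panel of 5 sensitive / 4 resistant / 4 promoted cell
  lines plus 4 PDXs (one array per model, as in a 13+4 panel), 70
  queries with a true sensitive fraction of 0.17, 10,000 probes with
  100 planted DMPs at Δβ = 0.3 — the effect size at which the
  moderated test on 5-vs-8 panels has high but not trivial power.
* **Platforms and blacklist.** 85% of probes are on both platforms
  (roughly the HM450/EPIC overlap), the rest split evenly. The
  blacklist (0.5% of probes, ≥5) deliberately includes 3 planted,
  non-coupled DMPs so the cross-reactive/SNP filter is consequential:
  planted-marker recovery is capped at 97% by design, and the tests
  verify those probes never surface downstream.
* **Expression.** Gene baselines N(7, 1.5²) log2 units, noise sd 0.25;
  50 planted baseline and 50 planted induced genes at |log2FC| = 1.5.
  17 coupled probe–gene pairs tie expression to the probe's M-value
  with a negative slope scaled to reproduce the planted fold change
  (plus sd 0.15 noise), enforcing the negative monotone
  methylation–expression relation; coupled genes also carry the
  induction effect, so they are the designed occupants of the Venn
  triple intersection. Coupled probes are placed at their gene's TSS
  so manifest proximity mapping links them.
* **Growth.** Lognormal final weights (sdlog 0.25 around a 1 g control
  geometric mean — a realistic coefficient of variation for xenograft
  endpoints) with multiplicative treated-arm factors 0.4 / 1.0 / 1.8
  for sensitive / resistant / promoted models, 8 mice per arm.
* **Toy genome.** Two chromosomes totalling 6 Mb; 300 genes on a
  regular 20-kb grid with spans ≤ 6 kb, which keeps every gene span
  ≥ 12 kb from its neighbors so a motif planted inside a gene is
  within 10 kb of that gene only. Incidental direct-repeat matches in
  the random background are scrubbed (iterated single-base
  disruption) before planting, so the truth file's per-gene motif
  flags (30% of genes by default) are exact rather than approximate.
  This is what makes motif-recovery tests sharp; it is obviously not a
  property of real genomes.

Determinism: the generator derives independent sub-seeds for layout,
labels, methylation, expression, growth and genome from the config
seed, so the same config reproduces byte-identical files, and
restricting `components` does not perturb the parts that are
generated. The caller's RNG state is saved and restored.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: probe type I/II chemistry differences,
batch and normalization effects, cell-composition mixtures,
copy-number distortion of β, correlated probe blocks (every probe is
independent given its class), and any realistic genome composition.
Planted effects are homoscedastic across classes and bidirectional
but individually constant.

## Numerical choices and edge cases

* β clipping at ε = 10⁻⁶ before the logit; round trip within 10⁻¹²
  on [ε, 1−ε].
* Variance-prior fitting guards zero variances by flooring at
  10⁻¹²·median and falls back to d₀ = ∞ when the log-variance spread
  is below the trigamma noise floor.
* Zero-variance features: t = 0, p = 1 when the group means also
  agree; p = 0 otherwise.
* Spearman p-values: exact permutation distribution for n ≤ 9 without
  ties, t-approximation otherwise; constant inputs return NA with a
  degenerate-input note rather than an error.
* Refinement tie-breaks (p, then |Δβ|, then probe id) and the
  smallest-pair tie-break of the agglomerator make every ranking
  deterministic.
* Fewer than k probes passing refinement returns all passing probes
  with a warning flag; zero passing is an error, as is an empty
  platform harmonization.

## Validation scale

The test suite validates the statistics against independent oracles
(closed-form Welch/pooled t, exhaustive hypergeometric enumeration of
all 2×2 tables with N ≤ 20, full 8!-permutation Spearman null, a regex
motif scanner over 100 kb, a brute-force interval scan for 1,000
probes, and a naive agglomerator for n ≤ 7 dendrograms), and exercises
recovery on cohorts of 10,000 probes: null calibration, planted-DMP
recovery and BH false-discovery control, signature membership,
classifier sensitivity/specificity on 100 balanced queries, the
predicted-sensitive fraction over 20 cohorts of 70 queries, and
growth-phenotyping power over 200 replicates per effect. These sizes
were chosen so the whole suite runs in a couple of minutes on one CPU
while keeping Monte Carlo error well inside the asserted bounds; the
same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## A worked miniature

```{r example}
cfg <- synthetic_config(n_probes = 2000, n_genes = 100,
                        genome_length = 2e6, n_planted_dmp = 50,
                        n_planted_de = 30, n_coupled = 10, seed = 7)
cohort <- generate_cohort(cfg, components = "meth")

lines <- cohort$samples$type == "cell_line"
panel <- cohort$samples$type != "query"
beta <- filter_probes(cohort$beta_panel, cohort$manifest)

dmp <- differential_methylation(beta[, cohort$samples$sample_id[lines]],
                                cohort$samples$supervision_class[lines])
both <- cohort$manifest$probe_id[cohort$manifest$platform == "both"]
cand <- intersect(harmonize_probes(both, both,
                                   dmp$probe_id[dmp$significant]),
                  rownames(beta))
sig <- refine_signature(beta[cand, cohort$samples$sample_id[panel]],
                        cohort$samples$supervision_class[panel])
sig

calls <- classify_cohort(cohort$beta_queries, sig)
cohort_summary(calls)
```

## Known limitations

* The pipeline consumes normalized β and log2 expression matrices;
  array preprocessing (SWAN/RMA), intrinsic subtyping, and external
  database retrieval are out of scope.
* The classification rule and the response-categorization rule are
  declared package conventions where the source analysis left them
  unstated; both are configurable, and conclusions that depend on the
  exact rule should say which was used.
* Region-level (DMR) calling, cell-composition deconvolution and
  non-CpG methylation are not implemented.
* Printed result counts from any particular study depend on its
  deposited cohorts; this package reproduces the *procedures* and
  validates them on synthetic ground truth, not those counts.
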