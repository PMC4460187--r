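---
title: "Methods: gene-set enrichment analysis of case-control CNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set enrichment analysis of case-control CNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Large, rare copy-number variants (CNVs) are strongly associated with
schizophrenia and other neurodevelopmental disorders. The question this
package addresses is not *whether* cases carry more CNV burden — they do —
but *which biological functions* that burden disrupts. Given a table of
case and control CNVs pooled from several genotyping studies, a gene map,
and a battery of curated gene sets (synaptic complexes, behavioral and
neurodevelopmental annotations, and so on), the package asks, for each set:
do case CNVs hit members of this set more often than control CNVs do, after
accounting for the things that trivially inflate hit counts — CNV size, the
total number of genes a CNV hits, and which study/array the call came from?

# The enrichment model

The unit of analysis is the CNV, not the individual. For each gene set the
package compares two nested logistic regressions of per-CNV case-control
status:

    (a)  logit pr(case) = stratum + size + total genes hit
    (b)  logit pr(case) = stratum + size + total genes hit
                          + genes hit in the gene set

where *stratum* is the study-by-chip combination (one factor absorbing
platform and calling differences), *size* is the CNV length in kb, and the
set covariate counts how many set members the CNV overlaps (a CNV hitting k
members contributes a covariate value of k to one row — never k rows — so
co-localized set members cannot inflate set-level significance). A gene is
"hit" when the CNV overlaps any base of its genomic span; exon structure
and strand are deliberately ignored.

The test statistic is the deviance difference between (a) and (b). Because
only enrichment in *cases* is of interest, the test is one-sided, built as
the signed root of the deviance drop:

    z = sign(beta_set) * sqrt(dev_a - dev_b),    p = 1 - pnorm(z)

Under the null z is asymptotically standard normal (one degree of freedom),
the construction is exact under the chi-square asymptotics, and it yields
p = 0.5 at beta_set = 0 — which is also what the degenerate cases return
(set never hit, set hit count constant, or set covariate collinear with the
model). The one-sided construction is a design choice of this package: the
convention "small p only when cases are enriched" determines everything
downstream (battery corrections, permutation counts), so it is applied
uniformly to set tests, single-gene tests and burden tests.

Odds ratios are `exp(beta_set)` per additional set gene hit, with Wald 95%
intervals. Under complete separation (a set hit only in case CNVs) the ML
estimate diverges while the deviance converges; the p value remains valid,
and `firth = TRUE` switches the reported OR/CI to a Jeffreys-penalized fit
that stays finite. The p value is never taken from the penalized fit.

Multiple testing uses Bonferroni with a *caller-supplied* test count, so a
battery of 134 sets examined under three analyses (all CNVs, deletions
only, duplications only) is corrected by 402 regardless of how the calls
are batched.

# Quality control

The QC chain reproduces standard post-calling practice for array CNVs, in
this order, with these defaults:

* **Fragment joining** — calls from the same sample, chromosome and
  copy-state are merged when the gap between them is less than 50% of their
  combined length, iterated to a fixpoint (a merged span can absorb further
  neighbours). Probe counts are summed.
* **Low-copy-repeat filter** — a call is dropped when the union of LCR
  intervals covers strictly more than 50% of its length.
* **Probe density** — dropped below 1 probe / 20 kb, counted from the probe
  map rather than the stored `n_probes` field (post-merge sums can
  double-count); without a probe map the stored counts are used with a
  warning.
* **Frequency** — calls of the same copy-state are single-linkage clustered
  at ≥ 50% reciprocal overlap; a cluster carried by more than 1% of all
  genotyped samples is dropped. The operationalization of "frequency" is
  not uniquely determined by the rule "frequency > 1%"; reciprocal-overlap
  clustering per copy-state is the field-standard reading and both the
  overlap fraction and the per-state behaviour are exposed as parameters.
* **Size / support** — calls under 100 kb or under 15 probes are dropped
  (both thresholds inclusive on the keep side).

Coordinates are 0-based half-open everywhere; 1-based inclusive input is
converted on read (`coords = "1based"`). The intensity-based outlier
validation step used with raw array data cannot be reproduced from call
tables; `cnv_qc(pass_samples = ...)` accepts an externally derived list of
passing samples instead.

For sensitivity re-analyses, `remove_known_loci()` drops calls overlapping
established risk loci by **any** overlap (≥ 1 bp). A threshold overlap
would also have been defensible; any-overlap is the stricter reading and is
flagged here as a package decision.

# Permutation test for a global excess of enriched sets

Whether "more sets than expected" reach a significance threshold is
assessed by permutation: case-control labels are shuffled *between CNVs
from the same study and chip*, preserving each stratum's case/control CNV
totals exactly, and the whole battery is re-tested per permutation. For a
threshold P (0.01 and 0.001 by default) the report gives the observed count
`n_obs`, the mean permuted count `n_exp`, and the empirical probability of
a permuted count reaching `n_obs`, reported as the bound `< 1/n_perm` when
no permutation reaches it. The permutation unit is the CNV (matching the
per-CNV regression), so an individual with several CNVs can receive
discordant permuted labels; that is the convention of the method, accepted
here. Permutation j draws its seed deterministically from the master seed,
so results are identical regardless of execution order, and an exhaustive
mode enumerates all within-stratum assignments on tiny inputs, making the
empirical p exact.

Because p values under the null are approximately uniform, `n_exp` at
threshold P is approximately `P × n_sets` — with 134 sets and P = 0.01,
about 1.3. This is a property of the method's calibration, not of any
particular dataset, and it is what the acceptance script recomputes.

# Conditional analyses and burden

`minimal_set_selection()` runs greedy forward selection over the sets that
survive correction: at each step every remaining candidate is re-tested
with the already-selected sets' hit counts added to model (a); the smallest
residual p is added while it is below 0.05 (uncorrected). Candidates are
ranked by uncorrected p, ties broken by name; both choices are flagged
decisions (the source convention is ambiguous between corrected and
uncorrected ranking — they order identically under a common Bonferroni
factor, so this matters only for reporting). All per-step p values are kept
for audit. `conditional_scan()` then re-tests any other battery (e.g. whole
GO or mammalian-phenotype collections) with the minimal set as fixed
covariates, asking what enrichment remains beyond the already-established
terms.

`burden_analysis()` compares CNV size, total genes hit, and genes hit
within a designated union set (`build_union_set()` collects all sets
passing correction, the "associated CNS" union) as predictors of case
status, each tested by the same one-sided signed-root deviance against a
baseline of stratum covariates plus any conditioning predictors. One-sided
testing toward case excess mirrors the enrichment convention; sidedness is
a package decision flagged here.

# The synthetic-data generator

Real case-control CNV datasets of this kind are governed access, so the
package carries a generator that emulates their structure and doubles as
the truth source for calibration tests:

* a toy genome (default: 4 chromosomes × 50 Mb) with 1,500 non-overlapping
  genes of log-normal length (median 30 kb), probes on a jittered 3 kb
  grid, and low-copy-repeat intervals covering ~3% of each chromosome;
* a battery of 134 gene sets with log-uniform sizes (10–150 genes),
  optionally sharing members through a common pool sized to hit a target
  expected pairwise Jaccard overlap;
* three study-by-chip strata (2,000 + 1,000 + 1,000 CNVs) echoing a
  multi-study design; 40% deletions; log-normal CNV lengths per copy-state
  (deletions median 180 kb, duplications 250 kb, all ≥ 100 kb);
* phenotypes drawn per CNV from exactly the logistic model the test fits,
  with baseline, stratum offsets, small size and total-gene effects, and
  any per-set log-odds the caller embeds (`beta_sets`). Case/control totals
  per stratum are therefore *realized*, not forced, and the permutation
  machinery conditions on the realized totals.

The defaults were fixed once, before any calibration was measured, to
resemble a desk-scale multi-study CNV dataset; the analysis-facing
quantities (strata count, ~4,000 CNVs, 134 sets) match the study design the
method targets. Covariates are computed by the package's own annotation
code, so generator and analysis cannot drift apart. A `per_individual`
mode groups CNVs into samples sharing one label, for probing the
independence assumption the per-CNV regression makes implicitly.

What the generator does **not** emulate: recurrent CNV hotspots and
mutational mechanisms, linkage structure, genome-build differences between
studies, batch-specific calling artifacts, and gene clustering by function
along the genome. Passing calibration tests on synthetic data therefore
demonstrates the statistics are implemented correctly and calibrated under
the model's own assumptions — not that those assumptions hold in any real
dataset.

# Numerical choices

* Logistic fits use iteratively reweighted least squares (Newton steps with
  step-halving), convergence at a relative deviance change below 1e-10,
  capped at 50 iterations; under separation the deviance at the cap is
  used, which is exactly what the deviance test needs.
* Exact collinearity is resolved as in `stats::glm`: aliased columns get NA
  coefficients; the set covariate being aliased (or its projection residual
  on the baseline design being numerically zero) yields the degenerate
  result `p = 0.5`, flagged in the output.
* Strata containing only cases or only controls make their indicator a
  perfect predictor; their rows are dropped with a warning.
* Constant covariates are dropped with a warning; an all-case or
  all-control dataset is an error.
* The independent oracle used in the tests is a literal iterative
  grid-refinement maximizer of the log-likelihood (no IRLS), with columns
  scaled to unit maximum so the search box is comparably conditioned;
  implementation and oracle agree in deviance to 1e-6 on ≤ 3-parameter
  fixtures.

# Problem sizes used by the test suite

The statistical checks run at sizes chosen to make the suite complete in
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances: the permutation-calibration check uses the default
study (4,000 CNVs, 134 sets) with 200 permutations; the type-I check pools
2,000 set tests from 100 independent null datasets (600 CNVs, 20 sets
each); interval coverage of an embedded log(2) effect uses 1,000 replicates
of 1,200 CNVs; the permutation-p calibration uses 200 replicates of small
studies (200 CNVs, 10 sets, 60 permutations). Exact identities (label-swap
antisymmetry, merge fixpoints, singleton equivalence, exhaustive
permutation equality) are checked exactly.

# Known limitations

* Per-CNV regression treats CNVs from the same individual as independent;
  the `per_individual` simulation mode exists precisely to study the
  effect, but the analysis itself follows the per-CNV convention.
* Wald intervals degrade under near-separation unless `firth = TRUE`.
* Bonferroni over a battery of overlapping sets is conservative; the
  permutation excess test is the intended complement, not a replacement.
* The QC frequency filter's single-linkage clusters can chain through
  intermediate calls; this is inherent to the standard definition.
* Gene-level conclusions from `extract_top_genes()` inherit the resolution
  limit of large CNVs: a recurrent multi-gene CNV nominates every gene it
  spans.
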