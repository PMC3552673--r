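---
title: "Methods: dose-response analysis of cadmium-exposed proximal tubule cells"
author: "cdtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response analysis of cadmium-exposed proximal tubule cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtox)
```

# The study design this package targets

`cdtox` analyzes single-replicate, multi-dose microarray studies of cadmium
nephrotoxicity in cultured human proximal tubule (HPT) cells: two exposure
blocks — 1 day at 0/9/27/45 µM Cd²⁺ and 13 days at 0/4.5/9/27 µM — with one
array per condition, summarized by a MAS5-style algorithm into a per-probe
signal and a Present/Marginal/Absent detection call per sample. Such designs
are common in toxicogenomics and statistically awkward: there are no
replicates, only a dose gradient, so every inference leans on the regression
structure across doses and on honest accounting of how little information
eight samples carry.

The pipeline has five stages, each usable on its own:
present-call filtering → per-block dose regression → hypergeometric
enrichment and cross-block overlap tests → pooled variance-filtered
clustering → mutual-information network modules. A simulator generates
studies with known ground truth so that each stage's operating
characteristics can be measured rather than assumed.

# Per-gene dose regression

Within one block, for each probe, expression $y$ is regressed on dose $x$
(µM) by ordinary least squares; the two-sided P value comes from the $t$
statistic of the slope with $n-2$ residual degrees of freedom ($n$ = number
of samples in the block, 4 by default, hence df = 2). The blocks are
analyzed independently, each with its own control.

Assumptions worth stating: linearity of the (possibly log-transformed)
response in dose, homoscedastic approximately normal residuals, and
independence across samples. With df = 2 the $t$ critical values are
brutal ($t_{0.995,2} \approx 9.9$), so the P < 0.01 reporting lists capture
only strong responders and the false-discovery rate at conventional
thresholds cannot reach 0.05 — the package therefore reports BH q values
(`bh_fdr`) alongside raw P values but treats the raw-P selections as the
operative lists, as is standard for this design.

**Scale.** The default regression scale is the raw signal; a `log2` flag
regresses $\log_2(\text{signal}+1)$ instead. Microarray noise is closer to
log-normal, and the simulator's effects are linear on the log2 scale, so
power-sensitive analyses in this package's own tests use the log2 flag; the
raw default reflects how signal-level analyses of this design are usually
reported. The +1 offset only guards degenerate zero signals.

**Degenerate fits.** Single-replicate designs make two degeneracies
reachable, and the pipeline must not abort on them: a zero-variance
response reports slope 0, direction "flat", P = 1; an exactly linear
response (residual SS numerically zero, tolerance $10^{-12}$ relative to
the response SS) reports P = 0 with a `perfect_fit` flag. Selections use a
*strict* inequality (P < cutoff), so a P value exactly at the cutoff is
excluded.

# Hypergeometric enrichment and overlap

Both bespoke tests reduce to the same question: a universe of $M$ genes
contains $K$ marked (significant) ones; a set of $n$ genes is drawn; is the
observed number $r$ of marked genes in the draw surprisingly large? The P
value is the strictly-greater upper tail

$$P(X > r) \;=\; \sum_{k=r+1}^{\min(K,n)} \frac{\binom{K}{k}\binom{M-K}{n-k}}{\binom{M}{n}},$$

evaluated by summing log-binomial terms with a log-sum-exp reduction —
naive factorials overflow long before $M \approx 30{,}000$. The same
function drives gene-set enrichment (`enrich_gene_sets`, with $n$ the set
size inside the universe) and the cross-block overlap test
(`overlap_significance`, with $K$ and $n$ the two list sizes). By the
strictly-greater convention $P(X > r) = 0$ when $r = \min(K,n)$: the tail
beyond the maximum is empty. The universe for both tests is the
present-call universe (the $M$ genes analyzed), which is the only
denominator under which the implied probability function normalizes.

Two properties are enforced by tests rather than trusted: the tail equals
exhaustive subset enumeration for every $M \le 15$, and it matches
`stats::phyper(..., lower.tail = FALSE)` at genomic scale (`phyper` is used
as a cross-check only; the implementation is the explicit log-domain sum).

A caution for readers comparing tail values across reports: the tail is
extremely sensitive to $M$. For list sizes 403 and 366 with 17 shared genes,
moving the universe from 28,720 to 28,400 genes changes $P(X>17)$ by ~16%.
Published P values for nominally identical counts can therefore differ from
the exact tails when the effective universe after data-dependent filtering
is slightly different from the headline count; `cdtox` always reports the
exact tail for the stated $M$.

**Probe collapsing.** Pathways are gene-level but arrays are probe-level,
and several probes may interrogate one gene. `collapse_probes` keeps one
row per symbol, by default the probe with the smallest P value (`min_p`;
`max_abs_t` available), recording the representative probe. Enrichment is
computed on the collapsed table; unannotated probes drop out of the
gene-level universe.

**Multiplicity across sets.** Raw set P values are reported with BH q
values appended as an extra column; no correction is silently applied.

# Pooled clustering

For the pooled 8-sample analysis, the matrix is centered by subtracting the
single grand mean (the literal reading of "normalized to a grand mean of
0"; per-gene centering is available via `center = "gene"`, and changes
which genes pass the SD filter). Genes with SD (denominator $n-1$) strictly
above the threshold — default 1.0 — are retained as the high-variability
set. The pipeline applies this on the $\log_2$ scale: on raw MAS5-type
signals, where values span hundreds of units, SD > 1 would retain nearly
every probe and the filter would be vacuous; on the log2 scale it selects a
few-percent tail, consistent with the intent of the filter.

Samples are clustered on Pearson dissimilarity $d = 1 - r$ (range [0, 2])
with Ward linkage. The Ward dialect is the squared-dissimilarity
formulation (`ward.D2`, the default in modern implementations); the
historical unsquared `ward.D` and the `average`/`complete` linkages used
for robustness checks sit behind the same flag — on simulated studies the
high-dose/low-dose split is insensitive to this choice. Merge heights are
validated in tests against an independent Lance–Williams recurrence. Genes
are clustered with the same metric solely to order heat-map columns.

Under the default simulator with dose effects present, cutting the sample
tree at $k = 2$ separates the two high-dose acute samples (27 and 45 µM,
day 1) from all low-dose samples; the chronic 27 µM sample joins the
high-dose side only when enough responders are shared across blocks, which
with one array per condition is seed-dependent.

# Mutual-information network modules

Relations between the high-variability genes are quantified by plug-in
mutual information on binned profiles:

$$\widehat{MI} = \sum_{a,b} \hat p(a,b)\, \log_2 \frac{\hat p(a,b)}{\hat p(a)\,\hat p(b)} \quad \text{(bits)},$$

with $0 \log 0 := 0$. Binning is per-gene equal-frequency with $B = 3$ bins
by default for 8 samples (bin sizes differ by at most one; ties broken by
value then input position, deterministically; a constant gene occupies a
single bin). Equal-frequency binning makes marginal entropies comparable
across genes, which in turn makes MI values comparable; $B=3$ is the
largest bin count for which the $3\times3$ joint table is not hopelessly
sparse at $n=8$. The adjacency is computed for all pairs at once from
bin-indicator matrix products — algebraically identical to the per-pair
estimate (tests assert exact equality) but $O(B^2 G^2)$ vectorized.

With $n = 8$ the raw MI bias is large, but it is common to all pairs, so no
bias correction is applied by default; module significance is judged
against a permutation null (below), never against absolute MI. A
consequence of rank-based binning worth knowing: any two genes whose
profiles are monotone in the same ordering — e.g. two strong dose
responders — have *identical* labels and hence maximal MI. MI at this
sample size cannot distinguish "co-regulated module" from "both responding
monotonically to dose"; a module stands out only when its shared activation
profile deviates from pure dose order.

MI is turned into a distance by normalized MI, $d = 1 - MI_{ij}/\sqrt{H_i
H_j} \in [0,1]$ (`one_minus_nmi`; `max_shift` is the bounded alternative
$\max(MI) - MI$ rescaled to [0,1]). Zero-entropy genes cannot be
normalized; their distances are set to 1 and flagged.

**Module detection.** The distance matrix is clustered hierarchically
(average linkage by default — Ward's variance reasoning presumes
Euclidean-like distances, which MI distances are not). Every cluster
appearing anywhere in the dendrogram (each internal node's leaf set, i.e.
the union of all tree cuts) is a candidate module; restricting candidates
to a few cuts demonstrably misses the best-separated set when a tight
cluster sits inside a larger loose one. Candidates of size `min_size`
(default 4) up to $G-1$ are scored by

$$\text{separation} = \underbrace{\text{mean pairwise MI inside}}_{\text{intra}} - \underbrace{\text{mean MI of members to non-members}}_{\text{extra}},$$

and only positive-separation candidates survive. Because nested tree
clusters overlap heavily, reported modules are made disjoint: candidates
are accepted greedily by descending separation, skipping any that shares a
gene with an accepted module. The first reported module is "the most
prominent". Significance is assessed by `null_module_separation`: each
gene's samples are permuted independently (destroying all gene-gene
dependence while keeping marginals), the top separation is recorded per
permutation, and an observed module is credible only above the null's 95th
percentile.

# The simulator: what it emulates and what it does not

`simulate_study` generates, on the log2 scale,

$$y_{gs} = \text{baseline}_g + \text{slope}_{g,\text{block}(s)}\cdot\text{dose}_s + \text{loading}_g\, z_{m(g),s} + \varepsilon_{gs},$$

signal $=2^y$, with $\varepsilon \sim N(0, \sigma)$, baselines
$N(7, 2^2)$ in log2 units (typical MAS5 signals of a few hundred with a
wide spread), and detection calls Absent with probability
`absent_prob_low_expr` (default 0.3) per sample for genes in the lowest
baseline quartile, Present otherwise. Defaults: 2000 genes, 2% positive and
2% negative responders per block, half of the chronic responders shared
with the acute block (sharing is defined as: that fraction of each block-2
sign class is drawn from the block-1 responders of the same sign),
per-gene |slope| uniform on $0.05 \times [0.5, 1.5]$ log2 units/µM, noise
SD 0.3, one 8-gene module, 5% of probes sharing a symbol with another probe
to exercise collapsing. Effects multiplicative on the signal scale match
how microarray fold changes behave; the slope default gives at most
~2–3 log2 units at the top acute dose, a strong but realistic stress
response.

**Module driver.** All members of a module share one realization of a
latent activation profile: the samples are ordered by dose trend plus a
latent jitter ($N(0, 0.5)$ on the unit dose scale, per module), and the
driver takes equally spaced levels across that ordering, scaled to a total
range of `driver_strength` log2 units; each member multiplies it by a
loading in [0.8, 1.2]. This produces a graded, monotone-in-expectation
activation whose realized sample ranking deviates from pure dose order —
exactly the property that lets a rank-based MI estimator tell a module
apart from generic dose responders (see above). Well-separated activation
levels, rather than trend-plus-small-noise, are what make the module
internally coherent at $n=8$: members' bin labels coincide unless the
per-gene noise crosses half the level spacing. A `driver_strength` of 6
(64-fold range, heat-shock-like) gives a module the package's detector
recovers in ≥85% of seeds; the default 1.5 plants a weak module that is
intentionally near the detection floor.

**Not emulated:** probe-level (PM/MM) data and the MAS5 algorithm itself,
spatial artifacts, batch effects, correlated noise between genes outside
planted structure, heavy-tailed or signal-dependent noise, and realistic
marginal signal distributions (no public calibration target exists for
these samples). Passing tests therefore demonstrate that the *methods*
behave correctly under their own assumptions — calibrated type-I error,
monotone power, recoverable planted structure — not that real HPT data
would yield any particular gene list.

# Numerical choices collected

* Hypergeometric tail: log-domain `lchoose` sum with log-sum-exp; exact-0
  convention at $r=\min(K,n)$; validation rejects non-integers and
  $r > \min(K,n)$.
* Regression: closed-form vectorized OLS; degenerate tolerances relative to
  response SS ($10^{-12}$); strict selection inequality.
* Binning: equal-frequency tie-break by value then input position (stable
  `order`); constant genes collapse to one bin; equal-width bins are
  half-open with the right edge closed.
* MI: $0\log 0 = 0$; tiny negative FP results clamped to 0 in the adjacency
  (never in the scalar estimator, which tests compare to an oracle at
  $10^{-12}$ absolute); adjacency symmetrized by averaging with its
  transpose (exact, removes FP asymmetry).
* Distances: NMI distance clipped to [0,1]; Pearson dissimilarity floored
  at 0.
* Ward: `stats::hclust` dialects; deterministic given the input matrix.
* Reproducibility: the simulator uses a private RNG stream restored on
  exit; identical config + seed gives byte-identical studies and
  end-to-end reports.
* File IO: numerics written with 17 significant digits, which round-trips
  IEEE doubles exactly.

# Problem sizes used by the test-suite studies

Simulation-based properties are measured at 2000 genes × 8 samples over 20
seeds (50 seeds for the P-value uniformity check), with 100 permutations
for module-null quantiles — sizes at which each study completes in seconds
while estimating the relevant proportions to a few percent.

# Known limitations

* With 2 residual df, the dose regression has essentially no power at
  P < 0.01 for effects below ~1 log2 unit per dose range; the reporting
  lists are sensitive only to strong responders, and FDR control at 0.05 is
  unattainable by construction.
* MI with 8 samples and 3 bins saturates for monotone relationships; the
  module detector cannot, even in principle, separate a module whose
  activation follows dose order exactly from the dose-responder bulk.
* The overlap test assumes the two lists are drawn independently from the
  universe under the null; both lists being derived from the same array
  universe (but disjoint sample sets) satisfies this only approximately.
* The 8-sample dendrogram is a descriptive display; no uncertainty
  (bootstrap support) is attached to it.
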