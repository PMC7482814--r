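---
title: "Profiling tandem 3'UTR APA from probe-level intensities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tandem 3'UTR APA from probe-level intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemAPA)
```

## The problem

Tandem 3'UTR alternative polyadenylation (APA) produces, for one gene, a
short and a long mRNA isoform that share the 3'UTR start but end at a
proximal or a distal poly(A) site. On an exon-level expression array, probes
upstream of the proximal site (the *common* region) report the total
abundance of both isoforms, while probes between the proximal and distal
sites (the *extended* region) report only the long isoform. If `f` is the
long-isoform fraction of a sample, the extended probes sit `log2(f)` below
the common probes on the log2 scale. A shift toward the short isoform
(3'UTR shortening, ubiquitous in proliferating and tumor tissue) therefore
appears as a *downward step* in the probe-intensity series at the proximal
poly(A) site.

`tandemAPA` turns this observation into a pipeline: build tandem-3'UTR
models from an annotation and a probe map; normalize probe intensities;
detect the step position per tandem with a multivariate Bayesian
change-point model; summarize each sample's isoform balance as a short
3'UTR index (SUI); discover tumor subtypes from SUI profiles with
non-smooth NMF and consensus clustering; classify new samples by nearest
shrunken centroids; test differential APA with moderated statistics; and
analyze pooled shRNA proliferation screens of cleavage/polyadenylation
(C/P) factors. Every stage can be exercised against synthetic data with
planted ground truth.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions under which the pipeline is validated. Probe-level log2
intensities follow

```
y[p, s] = beta_p + a[t, s] + I(p in extended) * log2(f[t, s]) + eps,
```

with probe affinity `beta_p ~ N(0, 0.3^2)`, per-(tandem, sample) abundance
`a ~ N(0, 0.5^2)`, and Gaussian residual noise (`sd` 0.25 by default) —
Gaussian log-scale noise is the standard description of RMA-processed
intensities. Normal samples are generated exactly at the baseline
long-isoform fraction `f0`, so their true SUI is 0 by construction and SUI
recovery is directly testable. Tumors of subtype `k` use
`f = f0 * 2^effect[t, k]` clipped to 1; negative effects plant 3'UTR
shortening. The full-size configuration mirrors a tumor/normal cohort
(subtype sizes 36/36/67/26, 33 paired normals); validation runs use the
reduced sizes listed under *Validation problem sizes* below. Minus-strand
tandems are written with genomic coordinates reversed relative to
transcript order, and all coordinates are 0-based half-open (BED).

Screen counts are multinomial per sample — `counts ~ multinomial(L, w_h *
2^(phi_h * d / 7))` with `phi_h` the per-week log2 depletion of hairpins
targeting depleted genes — because a fixed sequencing depth `L` is the
dominant constraint of real screen libraries; hairpin baseline abundances
`w_h` are log-normal (`sd` 0.5 log2 units), matching the wide abundance
range of pooled libraries.

What the generator does *not* emulate: probe-level cross-hybridization,
RMA/quantile preprocessing artifacts, batch effects, copy-number-driven
abundance changes, or multiple functional APA sites per 3'UTR (one planted
change point per tandem). Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
every artifact of real arrays.

## Tandem models and filters

Transcripts of a gene sharing a 3'UTR start with at least two distinct
ends form a tandem 3'UTR; when more than two ends share a start, the
shortest is the proximal and the longest the distal site, one candidate
per shared start — most significant isoform-abundance changes involve the
first functional APA site, so the analysis is restricted to it. Probes
contained in more than one tandem are discarded entirely (only uniquely
mapped probes carry interpretable signal); a probe straddling the proximal
site joins the segment holding the majority of its bases, ties going to
the common segment (the conservative choice: it cannot fabricate a step).
Tandems need at least four probes on each side of the candidate site — the
change-point model cannot usefully localize a boundary with fewer.

## Normalization

Two normalizations, used by different branches:

* **Transcript median** (expression branch): per sample, subtract the
  median log2 intensity of the probes of each transcript. Subtraction in
  log space rather than division in intensity space — the values are
  already log2, and the two are equivalent up to the monotone transform.
* **Normal median** (APA branch, applied before change-point analysis):
  per probe, subtract the median across the normal reference samples. The
  phrase "the normal sample" is read as the panel of all normals — with
  tens of paired normals a per-probe median over the panel is the stable
  reference. After this step a normal-like sample is centered at zero and
  probe affinities cancel, which anchors the SUI of normals at 0.

Raw CEL processing (RMA background correction, quantile normalization) is
out of scope; inputs are assumed to be post-RMA log2 intensities.

## The multivariate change-point model

All samples of a tandem are treated as one multivariate series with a
common change point. The model is the product-partition formulation of
Bayesian change-point analysis: a binary indicator per inter-probe
boundary defines a partition of the probe ordinals into blocks; within a
block each sample series has its own mean; the boundary change probability
has a `U(0, p0)` prior and the signal-to-noise weight a `U(0, w0)` prior
(`p0 = w0 = 0.2`, the reference defaults of the cited implementation). A
Gibbs sampler (50 burn-in, 500 retained sweeps) updates one indicator at a
time; the conditional odds integrate the two priors in closed/quadrature
form, with the within- and between-block sums of squares pooled over all
sample series so that every sample informs the same partition. The sweep
fraction with a change at boundary `j` is the posterior change probability
`rho_j`; the change point is `argmax rho` (ties to the smallest index);
posterior means are sweep-averages of within-block means per sample.

Numerical choices: the weight integral is evaluated by 40-node
Gauss-Legendre quadrature in log space (the integrand spans hundreds of
orders of magnitude once `m(n-1)/2` exponents appear); log-odds are
clamped at ±500; a matrix with essentially zero total variance skips the
data term and samples from the prior alone — no boundary is favored and
the maximal `rho` stays near `p0/2`. Noiseless inputs make the weight
integral improper at 0; the quadrature then returns a large finite value
that deterministically favors the step-explaining state, which is the
correct limiting behavior for localization. The sampler is written in
C++ (Rcpp), as change-point packages in this space are, and is
deterministic given its seed.

Fits are excluded when the posterior suggests more than one APA site or an
unreliable segmentation. Both rules the original analysis applied by
manual curation needed explicit definitions here:

* `MULTI_PEAK`: more than one local maximum of `rho` reaching 50% of the
  global maximum, maxima at least 2 boundaries apart (adjacent-boundary
  wobble around a single site is not a second APA).
* `UNSTABLE`: averaged over samples, the within-segment standard deviation
  of the posterior means exceeds 0.5 times the absolute between-segment
  mean difference in either segment.

## The short 3'UTR index

For sample `i`, with the change point splitting probes into common and
extended segments, `SUI_i = wbar_ic − wbar_ie`: the difference of the
posterior segment means. On normal-median-normalized input the common
level carries the sample's abundance offset and the extended level adds
`log2(f/f0)`, so the difference is `−log2(f/f0) = log2(f0/f)`: 0 for
normals, positive under shortening, monotone decreasing in `f`. The
published definition of the index could not be recovered verbatim (the
defining equation is an unrendered figure in the source we had); the
difference form is the one consistent with the stated interpretation
("larger SUI, more short isoform") and is isolated in `compute_sui()` so a
ratio or weighted form can be substituted in exactly one place. Z-scores
use the sample (n−1) standard deviation, as does the coefficient of
variation throughout.

## Subtype discovery

Features are ranked by the absolute coefficient of variation of SUI
(`|sd/mean|`; SUI can be negative, and an exactly zero mean is treated as
maximally variable) and the top 25% retained. NMF needs nonnegative input;
each feature is min-max scaled to [0, 1] (the choice is invertible and
preserves the per-feature ordering of samples, which is all that matters
for clustering).

Non-smooth NMF factorizes `X ≈ W S H` with the smoothing matrix
`S = (1−θ)I + (θ/k)J`, `θ = 0.5` by default; multiplicative KL-divergence
updates absorb `S` alternately into the basis and coefficient updates, and
`θ = 0` recovers plain KL-NMF. Each fit is the best (lowest divergence) of
`n_runs` uniform random restarts; the per-iteration divergence trace is
retained and asserted non-increasing in the tests. "50 and 200 iterations"
in the source protocol are read as restart counts for the rank survey and
the final fit respectively — that is the `nrun` semantics of the cited NMF
package — with the inner iteration cap a separate parameter (2000).

Rank selection surveys `k = 2..10` (validation uses 2..6, see below) and
scores the restart-consensus matrix with the cophenetic coefficient,
dispersion, and mean silhouette width; the selected rank maximizes the
mean of the three, with exact ties going to the largest rank (the finest
perfectly-stable partition). The robustness check is consensus k-means:
1000 subsamples of 80% of samples (a conventional resampling fraction; the
protocol fixes only the iteration count), k-means++ seeding, consensus
entries normalized by co-sampling counts, never-co-sampled pairs imputed
at 0.5 with a warning. Final labels are reported both from `argmax H` and
from the consensus dendrogram — the source does not say which it used, so
both are exposed.

## Classification of new samples

Nearest shrunken centroids with the standard parameterization:
standardized centroid deviations `d_ik = (xbar_ik − xbar_i)/(m_k (s_i +
s0))`, fudge `s0 = median(s_i)`, soft-thresholding by `Δ` chosen by
stratified cross-validation (ties to the largest `Δ`, the sparsest
classifier). New samples are quantile-normalized to the training pooled
quantiles (mean-of-sorted reference) before prediction, and assigned by
the usual discriminant including the log prior.

## Differential APA and association statistics

The two-group test is an ordinary linear-model t with empirical-Bayes
variance moderation: the pooled variance is shrunk toward a prior with
strength estimated by moment matching of the scaled-F distribution of the
sample variances (digamma/trigamma matching on `log s²`), and the
statistic has `d0 + d` degrees of freedom. The implementation is
self-contained for the one-covariate two-group design; the test suite
cross-checks it against an established microarray implementation and
against the ordinary pooled t in the `d0 → 0` limit. Events are called at
`|ΔSUI| ≥ 0.2` and BH FDR ≤ 0.05 — the effect threshold applies at
reporting only. The tumor-vs-normal "significant APA event" convention is
the same moderated test with q < 0.05. SUI-expression association uses
Pearson correlation per gene, with the shape of the correlation
distribution summarized by a seeded 2-component Gaussian mixture (EM, 10
restarts). IQR summaries use type-7 (linear interpolation) quantiles for
bit-reproducibility.

## Screen statistics

Counts are normalized to counts-per-million; enrichment is
`log2((cpm_d + 1)/(cpm_0 + 1))` per hairpin/replicate against the same
replicate's day 0 (pseudocount 1 cpm); gene scores average over hairpins
and replicates. Depletion is a one-sided Mann-Whitney test of the gene's
endpoint ratios against the control hairpins' ratios — chosen for
robustness at 3–5 hairpins per gene, with the exact tail when sizes permit
— followed by BH. The diversity shift between two timepoints is a
two-sample Kolmogorov-Smirnov test on `log10(cpm + 1)` (the natural test
for a shifted cumulative-frequency curve), and replicate concordance is
Spearman's rank correlation with mid-ranks.

## Validation problem sizes

The test suite and the acceptance script validate the pipeline at these
sizes, chosen to exercise every claim while keeping a single-CPU run
comfortable:

* change-point oracle agreement: 200 random instances, `n ≤ 12`, `m ≤ 4`;
* localization: 300 tandems, 4+4 probes, 40 samples, effect 1 log2,
  noise sd 0.25;
* SUI recovery: 20 tandems, 6+6 probes, three planted shortening depths,
  noise sd 0.1;
* subtyping: 200 features x 60 samples, four planted subtypes of 15,
  40 signature features each, effect 1, noise sd 0.25; rank survey over
  `k = 2..6` with 10 restarts per rank, 10 seeds;
* screens: 23 genes x 4 hairpins + 3 controls, depth 5x10^5, 2 replicates,
  days 0/7/14/21; 20 seeded power runs and 50 null seeds.

## Known limitations

* With only 3 control hairpins, all 23 gene-level depletion tests share
  one 6-value reference set. When those control ratios drift high by
  chance, many genes cross the BH threshold together: the *probability of
  any* false call stays at the FDR level (measured 0.16 at q < 0.25), but
  the *expected count* of false calls is heavy-tailed and exceeds one per
  screen. This is a property of testing against a tiny common control
  group, not of the implementation; it persists when hairpin abundances
  are made nearly homogeneous. Screens with more non-targeting controls
  would not show it.
* A tandem with no isoform shift in any sample has a flat posterior and is
  excluded as `MULTI_PEAK`/unlocalizable rather than assigned a change
  point; the pipeline quantifies APA only where a step exists.
* The moderated test supports the two-group design only; multi-factor
  designs should use a full linear-model framework.
* Rank-selection metrics plateau at 1 for every perfectly stable rank;
  the largest-tied-rank rule resolves this, but with very few restarts an
  over-split rank can appear spuriously stable — the survey should use at
  least ~10 restarts per rank.
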