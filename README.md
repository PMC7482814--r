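# tandemAPA

Quantify tandem 3'UTR alternative polyadenylation (APA) from probe-level
expression-array intensities, and work with the result: tumor subtyping,
sample classification, differential-APA statistics, and pooled shRNA
proliferation-screen analysis.

## Who this is for

Tandem 3'UTR APA gives one gene a short and a long mRNA isoform sharing a
3'UTR start but ending at proximal vs distal poly(A) sites. Probes upstream
of the proximal site see both isoforms; probes in the extended region see
only the long one, so a sample with long-isoform fraction *f* shows a step
of `log2(f)` at the proximal site. `tandemAPA` is for analysts who have
probe-level log2 intensities (plus a probe map and a 3'UTR annotation) and
want per-sample APA quantification and everything downstream of it —
without access to raw sequencing reads.

## The core model

For each tandem 3'UTR, all samples are treated as a multivariate series
with a common change point. A Gibbs sampler over the binary
change-indicator vector of a Bayesian product-partition model (uniform
priors `U(0, 0.2)` on the boundary change probability and the
signal-to-noise weight, sums of squares pooled across samples) yields a
posterior change probability per inter-probe boundary; the boundary with
maximal posterior probability is the APA change point. The short 3'UTR
index of sample *i* is the contrast of posterior segment means,

    SUI_i = wbar_ic − wbar_ie ,

which on normal-median-normalized data equals `log2(f0/f)`: zero for
normal-like samples, positive under 3'UTR shortening. Downstream: top-25%
CV feature selection, non-smooth NMF (`X ≈ W S H`, `S = (1−θ)I + (θ/k)J`)
with consensus-based rank selection and consensus k-means, nearest
shrunken centroids for new samples, moderated two-group tests with BH
correction (events at `|ΔSUI| ≥ 0.2`, FDR ≤ 0.05), and CPM/log-ratio
screen statistics with Mann-Whitney depletion tests.

## Worked example

```r
library(tandemAPA)

## synthetic cohort: 4 tandems, 5 normals, 6 tumors, planted shortening
cfg <- simulation_config(n_tandems = 4, n_normals = 5, subtype_sizes = 6,
                         f0 = 0.7, subtype_effects = matrix(-1, 4, 1),
                         noise_sd = 0.1, seed = 13)
sim <- simulate_probe_dataset(cfg)

out <- run_profile(pipeline_config(intensity = sim$intensity,
                                   transcripts = sim$transcripts,
                                   probe_map = sim$probe_map,
                                   samples = sim$samples, seed = 99))
out$counts
#>     candidates probe_filtered             ok     multi_peak       unstable
#>              4              4              4              0              0
out$qc[1, ]
#>        tandem_id change_index max_rho qc_status
#> 1 gene0001:10440            6       1        OK
round(out$sui[1, ], 2)
#> normal001 normal002 normal003 normal004 normal005  tumor001  tumor002
#>      0.00      0.04     -0.03     -0.02     -0.03      1.09      1.01
#>  tumor003  tumor004  tumor005  tumor006
#>      0.93      1.06      0.92      1.02
```

Every tandem's change point lands at probe 6 — the last common-segment
probe, where the planted proximal APA site sits — with posterior
probability 1. Normals score SUI ≈ 0 and tumors ≈ 1, matching the planted
halving of the long-isoform fraction (`log2(f0/f) = 1`). From here,
`run_subtype()` clusters tumors on SUI profiles, `run_classify()` assigns
new samples, `moderated_two_group_test()` + `classify_direction()` call
shortening/lengthening events, and `run_screen()` analyzes hairpin count
tables.

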