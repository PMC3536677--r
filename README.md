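# notchpulse

Integrative analysis of transcriptional responses to a **short pulse of
Notch signalling**: timecourse differential expression on two-colour
arrays, Dirichlet-process clustering of temporal profiles, ChIP
tiling-array peak calling, RNA polymerase II pausing-state classification,
peak–gene association with logistic modelling of differential-expression
odds, and Su(H)/Hairy motif and paired-site (SPS) scanning — plus a
synthetic-data generator with planted ground truth so the whole pipeline
can be exercised and validated end-to-end.

The package is aimed at computational biologists studying immediate
transcriptional responses to signalling pulses, where the questions are:
which genes respond, with what kinetics, and whether transcription-factor
occupancy and polymerase state explain the differences.

## The models at the package's core

**Expression.** A transcript's log2 ratio over time is
`M(g,t,r) = mu_k(g)(t) + c_g + d_(g,t) + e_(g,t,r)` with a gene-level
amplitude offset `c_g ~ N(0, sigma_c^2)`, a replicate-shared time deviation
`d ~ N(0, sigma_t^2)` and replicate noise `e ~ N(0, sigma_r^2)`.
Differential expression is a natural-cubic-spline F-test of each transcript
against an intercept-only null, with Benjamini–Hochberg q-values.

**Clustering.** The mean profiles `mu_k` carry a Dirichlet-process prior, so
the number of clusters K is estimated from the data.  Inference is collapsed
CRP Gibbs sampling (cluster means integrated out analytically; the
compound-symmetric covariance `lambda_b I + sigma_c^2 J` makes every weight
closed-form), with conjugate mean draws and log-scale random-walk updates of
the variance components.  Label switching is resolved against the
least-squares partition of the co-clustering matrix, yielding per-transcript
primary/secondary allocation probabilities.

**ChIP.** Peaks are maximal runs of `>= min_run` consecutive probes at
`>= threshold` log2 enrichment (gaps of `<= merge_gap` probes merged); peak
area is rectangle-rule quadrature in log2-enrichment·bp.  Pol II states are
UB / P / AP / AU from promoter and gene-body binding, with AP vs AU decided
by the pausing ratio `log2(max promoter) / log2(median body) >= 2`.

**Integration.** A gene-level logistic regression links DE odds to Su(H)
binding within 10 kb, Pol II class (UB baseline) and basal expression
(logC0); `effect_to_odds()` converts log-odds effects to odds multipliers
(e.g. `e^2.78 = 16.12`).  Motif scanning is a bit-score PWM scan of both
strands; an SPS is two Su(H) sites in opposite orientation spaced 10–22 nt
apart.

## Worked example

Simulate 60 transcripts in three planted response clusters, test for DE,
cluster the profiles, and fit the DE-odds model on a generated gene table:

```r
library(notchpulse)

cfg <- synth_config(
  n_genes = 60,
  cluster_spec = tibble::tibble(shape = c("early_up", "late_up", "down"),
                                amplitude = c(3, 2.5, 2.5), n = c(20, 20, 20)),
  sigma_c = 0.1, sigma_t = 0.05, sigma_r = 0.15, seed = 11)
sim <- synth_expression(cfg)

de <- timecourse_de(sim$expression)
head(de, 3)
#> # A tibble: 3 × 7
#>   transcript_id     F   df1   df2        p        q  rank
#>   <chr>         <dbl> <dbl> <int>    <dbl>    <dbl> <int>
#> 1 g0027-RA       980.     4    67 1.22e-58 7.35e-57     1
#> 2 g0038-RA       866.     4    67 7.09e-57 2.13e-55     2
#> 3 g0021-RA       854.     4    67 1.14e-56 2.27e-55     3
sum(de$q < 0.05)
#> [1] 60
```

All 60 planted responders are detected.  Clustering recovers the three
planted profiles with certainty on this well-separated design:

```r
fit <- dp_fit(sim$expression, n_sweeps = 2000, burn_in = 500, seed = 3)
cl  <- dp_summarize(fit)
cl
#> <dp_summary> posterior modal K = 3; 60 transcripts
head(tidy(cl), 3)
#> # A tibble: 3 × 5
#>   transcript_id primary primary_prob secondary secondary_prob
#>   <chr>           <int>        <dbl>     <int>          <dbl>
#> 1 g0001-RA            1            1         2              0
#> 2 g0002-RA            1            1         2              0
#> 3 g0003-RA            1            1         2              0
autoplot(cl)   # posterior mean profile per cluster
```

`primary_prob = 1` means the transcript lands in the same (relabeled)
cluster in every retained posterior sample.  The DE-odds model, fitted to a
table generated at known coefficients, recovers them:

```r
tb   <- synth_logistic(5000, seed = 42)   # generating betas: 2.78, 0.77, -0.49
lfit <- fit_de_logistic(tb)
tidy(lfit)[2:3, c("term", "estimate", "odds_multiplier", "significant")]
#> # A tibble: 2 × 4
#>   term         estimate odds_multiplier significant
#>   <chr>           <dbl>           <dbl> <lgl>
#> 1 suh             2.71             15.0 TRUE
#> 2 polii_classP    0.741            2.1  TRUE
effect_to_odds(2.78)
#> [1] 16.12
```

So in this simulation Su(H) binding within 10 kb multiplies the odds of
differential expression about 15-fold (truth: `e^2.78 = 16.12`).

`run_pipeline(pipeline_config(...), outdir)` chains every stage —
simulate → normalize → DE → cluster → peaks → Pol II → integrate → motifs —
and writes the per-transcript master table, per-stage TSV/BED/GFF3/FASTA
outputs and a manifest with parameters, seed and file hashes; a config plus
one seed reproduces every output byte-for-byte.

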