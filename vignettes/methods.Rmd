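---
title: "Models and methods behind notchpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind notchpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

notchpulse analyses what happens in the first two to three hours after a
short pulse of Notch pathway activation: which transcripts change, in what
temporal pattern, and how those patterns relate to binding of the pathway
transcription factor Su(H)/CSL, to the state of RNA polymerase II on each
gene, and to sequence motifs near the genes.  This vignette explains the
models the package implements, the parameters that matter, and the choices
made where the design was genuinely open.  Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The generative model for expression timecourses

A transcript's log2 ratio against a common reference, over `T` timepoints
and `R` replicate timecourses, is modelled as

$$ M_{g,t,r} = \mu_{k(g)}(t) + c_g + d_{g,t} + e_{g,t,r} $$

where $\mu_k$ is the mean temporal profile of cluster $k$; $c_g \sim
N(0,\sigma_c^2)$ is a gene-level amplitude offset, constant across the
profile; $d_{g,t} \sim N(0,\sigma_t^2)$ is a time-specific deviation shared
by all replicates (transcriptional burstiness that all arrays see); and
$e_{g,t,r} \sim N(0,\sigma_r^2)$ is replicate measurement noise.  The three
components are our concrete reading of the three sources of variability a
timecourse of this kind exhibits — response amplitude, temporal profile,
and expression noise.  The same parameterization drives both the
synthetic-data generator and the clustering likelihood, so the model fitted
is exactly the model simulated.

Units are log2 throughout.  Defaults: $\sigma_c = 0.15$, $\sigma_t = 0.08$,
$\sigma_r = 0.2$.  No published estimates of these magnitudes exist for the
platform emulated; the defaults are plausible for spotted two-colour arrays
and are placeholders chosen once for test power, not estimates.

The default design is 18 timepoints spanning 0–150 min with 4 replicate
timecourses for expression, and 7 timepoints (0, 10, 20, 30, 40, 60, 100
min) with 3 replicates for ChIP, matching the experimental design the
package emulates.

### Response shapes

`profile_mean()` provides five canonical shapes, all zero at $t = 0$:
`early_up` (peak near 20 min, relaxing after), `late_up` (sigmoidal rise
after ~60 min), `down` (exponential decay to $-a$), `transient` (Gaussian
bump at 30 min) and `flat`.  Amplitudes are in log2 units; a planted
amplitude of 2 is a 4-fold change at the profile peak.

## Normalization and differential expression

`compute_ma()` is the standard two-colour transform.  `normalize_ma()`
removes intensity-dependent dye trends with a per-array loess of M on A
(span 0.4, degree 1, symmetric family), then subtracts the residual median
so every array has median M exactly 0.  Arrays with degenerate A fall back
to median centring.

`timecourse_de()` regresses each transcript's replicate M values on a
natural cubic spline basis of time (default 4 df) against an intercept-only
null, by F test.  This detects smooth temporal structure of any shape
without specifying it — the strategy of spline-based timecourse DE tools.
We deliberately emulate that strategy rather than clone any specific
implementation: the acceptance surface is property-based (type-I error at
nominal level under the null, power on planted signals), not
number-matching against another package's internals.  A permutation null
(shuffling time labels within replicate) is available but off by default
for speed; with Gaussian noise the parametric F reference is exact.
Q-values are Benjamini–Hochberg; the multiple-testing method behind the
original analysis is unstated, and BH is the standard default.  Genes with
several transcript isoforms are tested per transcript; a gene counts as DE
if any isoform is.

`compute_logc0()` is the basal absolute-expression proxy: the mean over
replicates of log2 reference-channel intensity at $t = 0$ — meaningful up
to a constant, which is all its downstream uses (class comparisons,
logistic regression) need.

## Dirichlet-process clustering

Profiles of DE transcripts are clustered with a Dirichlet-process Gaussian
mixture, so the number of clusters is estimated from the data rather than
fixed in advance.  The likelihood is the generative model above;
conditional on a cluster mean, $c_g$ and $d_{g,t}$ are marginalized
analytically.  The per-time replicate means then have compound-symmetric
covariance $\lambda_b I + \sigma_c^2 J$ with $\lambda_b = \sigma_t^2 +
\sigma_r^2 / R$, whose eigenstructure gives a closed-form likelihood — no
matrix decompositions in the inner loop.

Because the $N(0, \tau^2 I)$ prior on cluster means is conjugate to this
likelihood, allocations are sampled by **collapsed** CRP Gibbs: the cluster
mean is integrated out and the posterior-predictive covariance for a
member profile is again of the form $aI + bJ$.  We first implemented the
auxiliary-component sampler (Neal's algorithm 8, 3 auxiliaries); with
18-dimensional profiles and a vague prior it essentially never opened a new
cluster, because a random prior draw is almost surely far from any data.
The collapsed sampler proposes new clusters with the prior-predictive
density instead and mixes well; since the model is fully conjugate this is
the textbook-preferred sampler, and it is the one shipped.  Cluster means
are still instantiated by conjugate draws each sweep (for output and for
the variance updates), making the scheme a valid partially collapsed Gibbs
sampler.

Variance components move by random-walk Metropolis on the log scale
(proposal SD 0.3) under weak inverse-gamma(1, 0.5) priors; divergent
proposals are rejected and counted, with a warning above a 20% rate.  The
concentration parameter defaults to $\alpha = 1$, with optional resampling
under a Gamma(1,1) prior by the auxiliary-variable method.  Defaults of
2000 sweeps with 500 burn-in are sized for problems up to a few hundred
transcripts.

Label switching would corrupt averaged allocations, so `dp_summarize()`
relabels: it computes the pairwise co-clustering matrix, takes as reference
the sampled partition minimizing the least-squares distance to it, and maps
every sample's clusters onto the reference by greedy maximum-overlap
matching.  Reported "allocation probabilities" are exactly that — the
posterior probability of a transcript belonging to each (relabeled)
cluster; we do not re-badge them as p-values.  Primary and secondary
clusters are the top two, ties broken toward the lower cluster index.

Two internal checks validate the sampler: with the likelihood disabled the
occupied-cluster count matches the Chinese-restaurant closed form
$\sum_{i<n} \alpha/(\alpha+i)$ within Monte-Carlo error, and on
well-separated planted clusters the posterior mode recovers the planted
partition exactly (adjusted Rand index 1).

## Peak calling and peak areas

Tiling-array enrichment peaks are called by a run-length rule that combines
the magnitude of enrichment with the number of consecutive enriched probes:
replicate values are averaged per probe (a stringent min-combine mode
exists); maximal runs of probes at or above `threshold` are found; runs
separated by at most `merge_gap` sub-threshold probes are merged; merged
runs with at least `min_run` enriched probes become peaks, with boundaries
extended half a probe spacing beyond the outermost enriched probes.
Defaults (threshold 1.0 log2, `min_run` 4, `merge_gap` 2) suit 50 bp probe
spacing and are deliberately config-exposed rather than hard-coded: the
original analysis names the strategy but not its constants.

Peak "area" is rectangle-rule quadrature of the non-negative enrichment
over probes inside the interval, in log2-enrichment·bp.  Peaks from
different timepoints are matched by any-overlap union regions, and each
region's area is quantified at every timepoint, giving binding-dynamics
profiles.  On synthetic pulse tracks, whose planted Su(H) height profile
peaks at 20–30 min, the recovered area timecourse is unimodal with its
maximum at the planted time — the round-trip the tests assert.

One caveat, documented rather than hidden: "raising the threshold never
increases the peak count" is a theorem only for unimodal peak shapes.  A
merged peak with an internal dip can split into two qualifying runs at a
higher threshold.  The property test therefore uses unimodal planted bumps;
monotonicity in `min_run` holds unconditionally and is tested on arbitrary
tracks.

## Pol II state classification

Each transcript at each timepoint is classified as UB (unbound), P
(poised: promoter-proximal binding only), AP (active poised: promoter peak
plus gene-body binding) or AU (active uniform: body binding without
promoter-proximal excess).  Promoter and body binding use the same
run-length logic as peak calling, restricted to each region.  AP and AU are
separated by the pausing ratio

$$ \text{ratio} = \frac{\max(\text{log2 enrichment in } [TSS-w, TSS+w])}
                       {\max(\text{median log2 enrichment over body},\ 0.25)} $$

with cutoff 2.  Two conventions deserve emphasis: the ratio is of **log2**
values as displayed on the arrays, not of linear fold enrichments; and the
denominator is floored at 0.25 to avoid blow-up on unbound bodies.  The
promoter window default is TSS ± 500 bp (about 10 probes at default
spacing), strand-aware; the body is the promoter-window end to the
transcript end.  Whether the median should span the whole transcript or the
body only is ambiguous; body-only is the default, with `body_only = FALSE`
provided.

Genes with several transcripts take the highest-precedence state under
`AU > AP > P > UB`.

## Peak–gene association and the DE-odds model

Distances are between transcript extents and peak intervals, 0-based
half-open, 0 meaning overlap; the association radius (default 10 kb) is
inclusive.  A nearest-2 mode assigns each peak to its two closest genes
irrespective of distance (ties toward the leftmost gene start), the variant
used when asking what fraction of binding sites have any responsive
neighbour.

The DE-odds model is a logistic regression of the gene-level DE indicator
on: Su(H) bound within the radius at a chosen timepoint (binary), Pol II
class indicators (UB baseline), and logC0 (entered linearly; whether the
original model binned it is unstated).  Wald p-values are Holm-adjusted
across the non-intercept coefficients — the original analysis says
"adjusted for multiple testing" without naming a method, and Holm is the
conservative default — with significance flagged at adjusted p < 0.005.
Complete separation is detected and reported, with ridge-penalized point
estimates as a labelled fallback.  `effect_to_odds()` converts log-odds to
the odds-multiplier scale on which such effects are quoted (e.g.
$e^{2.78} = 16.12$).

`logc0_class_tests()` runs the one-way ANOVA of logC0 across Pol II classes
plus all pairwise Welch t-tests, one-sided in the direction
higher-activity > lower-activity (AU, AP > P > UB); the AU/AP pair is
two-sided since neither dominates a priori.  `regime_compare()` contrasts
per-gene log2 fold changes under two activation regimes by OLS slope and
$r^2$, flagging genes whose responses differ more than 2-fold on the
linear scale.

## Motif and paired-site scanning

PWMs are built from count matrices with pseudocount 0.5 and scored in bits
against a supplied background; scanning slides the matrix over both strands
(reverse strand via the reverse-complement matrix, coordinates on the
forward axis) and reports windows at or above the threshold, default 60% of
the maximal score — "high affinity" is qualitative in the source material,
so the fraction is config-exposed.  Windows containing N are skipped.

Paired Su(H) sites (SPS) are two matches on opposite strands with an
inter-site gap of 10–22 nt inclusive.  Two conventions are ours to fix and
documented here: spacing is the gap between the end of the left site and
the start of the right site (not centre-to-centre), and both head-to-head
and tail-to-tail opposite-strand arrangements qualify, since the source
constraint says only "opposite direction".  Overlapping pairs are reported
independently.

`motif_gene_counts()` counts matches within a window of each gene's
transcription unit and reports the percentage of genes with at least one
match, rounded to the nearest integer (the convention under which 10 of 13
genes reads as 77%).

The shipped example matrices under `inst/extdata/` are **synthetic
stand-ins** built from the consensus strings used by the generator; the
matrices used in the original study are not published in a reusable form.

## The synthetic-data generator: what it does and does not emulate

The generator plants: cluster structure in expression (with the three-part
noise model); per-gene basal intensities whose class shifts make logC0
track Pol II activity; canonical Pol II shapes per class — P and AP with a
promoter block at log2 4 and (for AP) a body at 1.5, chosen so the pausing
ratio is 2.67 ≥ 2 by construction, AU uniform at 1.5 (ratio 1), UB
background only; Su(H) peaks at recorded enhancer coordinates whose height
profile over ChIP timepoints rises to its maximum at 20–30 min and declines
after; and exact-consensus motif instances, including SPS pairs at
configurable gaps, in an i.i.d. uniform background from which accidental
exact-consensus matches are scrubbed (only bases outside planted instances
are redrawn).  ChIP background is Normal(0, σ_bg) truncated at zero —
truncated, not shifted, mirroring non-negative log2 enrichment displays.

What it does **not** emulate: microarray image artifacts, spatial or
print-tip effects, dye bias beyond a simple intensity-dependent offset,
cross-hybridization, probe-specific affinity, or correlated backgrounds.
Passing tests therefore demonstrate that the algorithms are correct on data
satisfying their stated assumptions, not that the assumptions hold for any
particular real array platform.

## Numerical choices and degenerate inputs

* Spot intensities must be positive; offending spots are dropped with a
  logged count before the log transform.
* Loess normalization requires ≥ 50 spots per array and falls back to
  median centring when A is constant.
* The DP sampler requires complete transcript × time × replicate grids;
  median-collapsed input (one pseudo-replicate) is accepted, the replicate
  variance then being absorbed by the time component.
* `fit_de_logistic()` drops constant predictor columns with a warning and
  warns when events are scarce (< 10 per predictor).
* ANOVA on values with zero total variance reports F = 0, p = 1; pairwise
  t-tests on essentially constant data report NA rather than failing.
* All genomic coordinates are 0-based half-open in memory; GFF3 is 1-based
  inclusive on disk and converted at the IO boundary.
* One global pipeline seed is split deterministically per stage
  (`stage_seed()`), so a config plus one integer reproduces every output
  byte-for-byte while stages stay decoupled.

## Problem sizes used by the tests and acceptance script

The shipped checks run at desk scale, chosen once as the package's own
test conditions: DP clustering recovery on 60 transcripts in 3 planted
clusters (2000 sweeps); DE calibration on 1000 null transcripts; peak-caller
oracle equivalence on 100 seeded tracks; Pol II recall on 300 noisy genes;
logistic recovery at n = 5000 with 50-replicate interval coverage; and an
end-to-end 500-gene synthetic run executed twice to verify byte-identical
outputs.  Dataset-level figures from the study that motivated the package
(counts of DE genes and clusters on the real arrays) depend on the original
raw data and are out of scope here; the package's claims are the
property-based ones its tests compute.

## Known limitations

* The spline F-test assumes Gaussian noise after normalization; heavy tails
  inflate the type-I error (the permutation null is the remedy).
* The collapsed sampler conditions on shared variance components; clusters
  with genuinely different noise scales are not modelled.
* Peak boundaries are probe-resolution (± half spacing) and areas use the
  rectangle rule; both are adequate at 50 bp spacing but coarse for sparse
  designs.
* The pausing-ratio convention (log2-scale, floored median) makes the
  AP/AU cutoff platform-specific; porting to other data requires
  recalibrating the cutoff.
* The logistic model treats genes as independent; clustered genomic
  neighbourhoods violate that mildly.
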