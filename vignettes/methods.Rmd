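---
title: "Methods: networks, backbones, topology and statistics in braintopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: networks, backbones, topology and statistics in braintopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`braintopo` implements a complete analysis chain from per-subject brain
data (vertex-wise morphometry and parcel-average BOLD series on a
30-parcel cortical parcellation) to covariate-adjusted associations
between network topology and behavioral scores. This vignette documents
the models and procedures, the parameters that matter, the numerical
choices, and what the synthetic data generator does and does not emulate.

## The parcellation and the vertex filter

Nodes are the parcels of a 51-parcel functional parcellation of the
cortical surface grouped into the seven canonical resting-state networks
(visual, somatomotor, dorsal attention, ventral attention/salience,
limbic, frontoparietal control, default mode). Parcels with fewer than 50
surface vertices are dropped (`filter_parcels()`, threshold 50,
*inclusive*: a parcel with exactly 50 vertices — the right precentral
dorsal-attention parcel — is retained, which is what the published roster
of 30 retained parcels implies even though the accompanying caption says
"> 50"). `retained_parcels()` carries the published names and vertex
counts; the 21 sub-threshold parcels are not published, so
`full_parcellation()` pads the roster with synthetic small parcels purely
so the filter is exercisable.

## Morphological similarity networks

For one subject and one measure (cortical volume mm³, surface area mm²,
or thickness mm), each parcel is a list of vertex values. For a pair of
parcels the package builds `B` uniform bins spanning the **pooled**
min–max range of both parcels (one shared set of edges, so the two
frequency vectors are comparable), counts vertices per bin, and takes the
Pearson correlation of the two count vectors as the edge weight.
Conventions:

* bins are left-closed, and the last bin is closed on both sides so the
  pooled maximum is never lost;
* the pooled range is computed per subject (each subject's own values
  define it). Whether the range should instead be fixed across subjects
  is genuinely open; per-subject ranges keep the similarity scale-free
  with respect to overall brain size, which suits a measure meant to
  compare distribution *shapes*;
* a pair with zero pooled range is a degenerate error; a zero-variance
  count vector makes the correlation undefined and returns `NA` with a
  warning.

The bin number `B` is the spatial-scale parameter: `sweep_bin_numbers()`
rebuilds the network for `B = 24, 26, …, 36` (7 scales), with `B = 30`
as the single-scale default. A worked example: 30 bins over a pooled
range `[5.4, 55.8]` give width 1.68; over `[5.4, 61.2]` they give
`(61.2 − 5.4)/30 = 1.86`.

## Functional connectivity networks

`static_fc()` is the Pearson correlation of parcel-average BOLD series
over the whole scan (default 235 time points at TR = 2 s);
`sliding_window_fc()` computes the same within windows of 50 TRs (100 s,
long enough to contain a full period of the 0.01 Hz lower band edge)
shifted by 1 TR, yielding `235 − 50 + 1 = 186` dynamic networks. Window
lengths of 60 or 70 TRs are plain arguments. No detrending or filtering
happens inside these functions — inputs are assumed preprocessed. A
zero-variance parcel row is an error naming the parcel.

## OMST backbones

Connectivity matrices are signed; `absolutize()` takes entrywise absolute
values and zeroes the diagonal. `omst_backbone()` then applies orthogonal
minimal spanning tree thresholding:

1. round *m* extracts the maximum-weight spanning tree of the remaining
   edges — equivalently the minimum spanning tree under the distance
   transform `d = 1/w` (stronger = shorter), the convention used
   throughout the package for weighted path lengths;
2. the tree's edges are removed from the pool (orthogonality =
   edge-disjointness), and the global cost efficiency of the union so far
   is recorded: `GCE(m) = Eglob(union) − cost(m)`, where the efficiency
   term uses weights divided by the maximum original weight (so GCE is
   scale-free, like the cost term, the retained fraction of total
   weight);
3. rounds stop when the remaining edges no longer span the graph, when
   GCE has decreased for two consecutive rounds, or at
   `floor((N−1)/2)` rounds; the returned backbone is the union with
   maximal GCE (smallest such *m* on ties).

The minimum spanning tree is computed by Kruskal's algorithm with
lexicographic tie-breaking on `(distance, node a, node b)`, so the result
is deterministic even with tied weights; with distinct weights each
round's tree is unique and the whole procedure is verified against an
exhaustive spanning-tree-enumeration search in the test suite.
Disconnected inputs (or inputs with fewer than `N − 1` nonzero edges) are
errors: every backbone is connected by construction.

## Topological measures

All seven measures operate on the backbone's weight matrix. Path lengths
use `d = 1/w`. Choices the definitions leave open were resolved as
follows and are stated on each function:

* **degree centrality is binary** (a count of retained edges) — its
  defining sum runs over an adjacency indicator;
* **eigenvector and pagerank centrality are weighted** — their defining
  equations act on the association matrix itself. Pagerank normalizes by
  node strength (which reduces to the degree on unit weights), with
  damping `d = 0.85` (teleport probability 0.15), solved by damped
  iteration to a `1e-12` residual (cap 10,000 iterations; non-convergence
  is an error reporting the residual);
* **betweenness** sums over unordered pairs (the graph is undirected) and
  is un-normalized;
* **local efficiency** of a node is the global efficiency of the subgraph
  induced on its neighbors; nodes with fewer than two neighbors, or
  neighborhoods without internal edges, get 0, and disconnected neighbor
  pairs contribute `1/∞ = 0`.

Two identities hold exactly and are asserted at machine precision in the
tests: the mean nodal efficiency equals the global efficiency, and
pagerank sums to 1. Everything else is checked against independent
brute-force oracles (Floyd–Warshall, exhaustive path enumeration, shifted
power iteration, dense linear solve).

## Variation across scales and windows

`coefficient_of_variation()` is the sample SD (denominator `n − 1`) over
the mean of a measure's values across the 7 bin settings (spatial) or 186
windows (temporal); a zero mean is an error, flagged per series (the
pipeline records `NA` there — this occurs for betweenness of nodes that
are leaves at every scale). Distribution statistics for the temporal axis
use 20-bin histograms: the median comes from the raw values (strictly
more accurate than a binned median; the bin count then only affects mode
and FWHM), the mode is the center of the maximal-count bin (lowest bin on
ties), and the FWHM is found by linear interpolation on bin-center/count
pairs at the outermost half-maximum crossings, clamped to the outermost
bin centers when the peak sits at a boundary. The "fitted curve" is a
Gaussian kernel density estimate (Sheather–Jones plug-in bandwidth,
rule-of-thumb fallback for heavily tied samples, 512-point grid) — no
parametric family is imposed; its median, mode and FWHM are read off the
estimated density. The full-width reading of "FWHM" is used throughout:
for a Gaussian it equals `2√(2 ln 2)·σ ≈ 2.3548σ`, the closed form the
tests check against. Those checks draw 40,000-point samples: the
Monte-Carlo standard error of a 20-bin histogram FWHM is about 4% of the
true value at 10,000 draws, which is the same order as the 5% acceptance
band, so the sample size was set at 40,000 (estimator noise ≈ 2%) to make
the band meaningful.

## Association statistics

`partial_correlation()` residualizes outcome and predictor on the
covariates plus intercept via QR least squares and correlates the
residuals; `t = r√df/√(1 − r²)` with `df = n − k − 2`. This is
numerically identical (asserted in tests) to the GLM route in which the
predictor enters the model alongside the covariates. Covariate sets
follow the arm: structural — age, gender (binary indicator), education,
intracranial volume, and the measure-matching morphometric total (total
volume, total area, or mean thickness); functional — age, gender,
education, the minimal BBR registration cost and mean framewise
displacement. Covariates enter raw; `r` and `p` are invariant to their
scaling. Tests are two-sided. `fdr_correct()` is Benjamini–Hochberg over
one family = the 30 parcels of a single (measure × statistic × anxiety
dimension) combination — the narrowest family the design statement "FDR
over 30 parcels" supports; pooling across measures or dimensions is left
to the caller by concatenating p-values. Rank-deficient covariates are an
error naming the collinear columns; a predictor with no residual variance
is flagged degenerate (`NA`).

## The synthetic cohort generator

The generator exists because the study cohort's MRI data are not public.
It emulates the *statistical structure the analysis assumes*, not the
data themselves:

* **behavior** — state anxiety 34.20 ± 9.33, trait anxiety 34.63 ± 9.24,
  state–trait correlation 0.848, age 37.81 ± 13.10 y, education
  15.48 ± 3.10 y, age–education −0.464 and the small anxiety–demographic
  correlations, sampled from a multivariate normal (an indefinite
  requested correlation matrix is an error; a singular-but-PSD one, e.g.
  a requested correlation of exactly 1, is a legal degenerate case).
  Gender is Bernoulli(0.5), matching the near-balanced cohort (32/35).
  STAI scores are kept continuous and unclipped: truncating to the 20–80
  instrument range would distort the very moments being matched, and at
  these moments fewer than ~7% of draws fall outside it;
* **morphometry** — vertex values are lognormal per parcel (positive and
  right-skewed, two parameters), with per-parcel location offsets, a
  subject-level scale factor, and volume parameters chosen so per-vertex
  values span roughly 5–60 mm³ like the worked histogram example. A
  planted effect multiplies the parcel's log-scale spread by
  `exp(β·z)` with `z` the standardized anxiety score — a *shape* change,
  because histogram-correlation similarity is insensitive to pure
  location shifts;
* **BOLD** — white noise masked in the frequency domain to the 0.01–0.1
  Hz band (exact band control, no filter transients; a band above the
  Nyquist frequency `1/(2·TR)` is an error), with block correlation by
  network: parcel = `√c ·` shared network signal `+ √(1−c) ·` private
  noise, coupling `c = 0.3` by default. Piecewise-stationary coupling
  states (`bold_states > 1`) exercise the dynamic-FC machinery; a planted
  effect shifts one parcel's coupling by `β·z`, clipped to `[0, 1]`.

All randomness derives from one integer seed (sub-seeds per stage), and
the same seed reproduces cohorts bit-identically, including through the
TSV fixtures (numbers are written with 17 significant digits so the
write/read round trip is exact).

What the generator does **not** emulate: spatial autocorrelation on the
cortical surface, subject-level registration error, head-motion artifact
structure, heavy-tailed or multimodal morphometry, scanner drift, or any
real anatomical covariance between parcels. Passing tests therefore
demonstrate that the *pipeline* is correct and calibrated under its own
assumptions — not that the published cohort's effect sizes would
replicate.

## Calibration results the tests compute

On null synthetic cohorts (n = 60, independent parcel statistics), the
per-parcel partial-correlation test has empirical type-I error within
binomial error of the nominal 5% (1,000 replicates × 30 parcels). With an
effect planted at partial r = 0.5 in one parcel, the estimated partial
correlation recovers the planted sign in ≥ 95% of replicates of the
BH-corrected analysis; the probability of the parcel also being
*BH-flagged* at q < 0.05 over 30 parcels is high but necessarily below
95% at this effect size and n (the acceptance script reports the measured
rate). This is an inherent power limit: by the Fisher-z approximation the
two-sided per-parcel threshold after BH with one true effect is near
p ≤ 0.05/30, giving power ≈ 0.8 at r = 0.5, n = 60 — no implementation
can reach 95% there.

## Problem sizes and runtime choices

Unit and property tests run on graphs of 4–12 nodes (where brute-force
oracles are exhaustive), 200 random backbones for the measure oracles,
100 complete graphs for the OMST oracle, 1,000 replicates for the
statistical calibration, and pipeline integration runs on 3-subject,
10-parcel cohorts — sizes chosen so the full suite completes in a couple
of minutes while every code path is exercised. A full 60-subject,
two-arm run at the default settings (1,260 structural networks, 11,220
window backbones) is a few minutes of compute and is intended as a
script-level job (`run_pipeline()`), not part of the tests.

## Interface note

The package is driven from R — `simulate_cohort()`/`write_fixtures()` for
data, `run_pipeline()` for the arms, `run_family()` for statistics alone,
and the TSV/JSON writers for reporting — in the style of other analysis
packages in this space; there is no separate shell executable, and
`scripts/acceptance.R` shows the scripted usage pattern.

## Known limitations

* OMST selection evaluates GCE on the recorded curve only; if GCE dipped
  for two rounds and rose much later, that later optimum would be missed
  (the cited scheme's own stopping behavior; configurable via
  `max_trees`).
* The betweenness oracle (path enumeration) limits exhaustive
  verification to ≤ 7 nodes; larger graphs rely on the igraph Brandes
  implementation behind the module surface.
* The "histogram-fitted curve" has no published functional form; the KDE
  choice is a stand-in and a parametric Gaussian fit would give slightly
  different fitted statistics.
* Associations assume complete cases; rows with missing values must be
  excluded upstream (the QC helper exists for exactly that bookkeeping).
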