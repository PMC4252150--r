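---
title: "Postural sway, recurrence analysis, and vection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Postural sway, recurrence analysis, and vection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayrqa)
```

## The scientific problem

Vection — the illusion of self-motion induced by large-field optic flow —
varies enormously between people. One candidate explanation is *visual
dependence*: the degree to which a person relies on vision to stabilise
upright stance. swayrqa implements an analysis pipeline that quantifies
postural sway from force-plate centre-of-pressure (CoP) recordings, both
with conventional linear measures and with recurrence quantification
analysis (RQA), and correlates those sway signatures with vection strength
ratings collected while seated. The package also ships a synthetic cohort
generator with a known latent structure, so the entire pipeline is testable
end to end without laboratory data.

## Sway measures

**Path length.** The total distance travelled by the CoP over a trace,
$L = \sum_{i=1}^{N-1}\sqrt{(x_{i+1}-x_i)^2+(y_{i+1}-y_i)^2}$ with $x$ the
anterior-posterior (AP) and $y$ the medial-lateral (ML) excursion in mm.
The *Romberg ratio* is eyes-closed path divided by eyes-open path; values
above 1 index visual dependence.

**95% confidence-ellipse area.** The prediction ellipse of the (AP, ML)
scatter, from the eigen-decomposition of the $2\times2$ sample covariance
matrix (denominator $n-1$): semi-axes $\sqrt{q\,\lambda_k}$ and area
$\pi q \sqrt{\lambda_1\lambda_2}$, with $q = \chi^2_{2}(0.95) \approx
5.991$ by default. A small-sample $F$-corrected quantile,
$q = \tfrac{2(n-1)}{n-2}F_{2,n-2}(0.95)$, is available via
`confidence_ellipse(..., small_sample = TRUE)`; at posturographic sample
sizes (thousands of points) the two are indistinguishable. The
*log area ratio* is $\log(\text{area}_{EO}/\text{area}_{EC})$; the natural
log is used — any other base only rescales correlations.

**Visually evoked postural responses (VEPRs).** In blocked standing
optic-flow sessions (30 s blank / 30 s flow / 30 s blank / 30 s fixation,
repeated three times), the VEPR of each flow block is the mean AP position
during the flow exposure minus the mean AP position over the *entire*
immediately preceding block, which controls for slow postural drift. The
whole preceding block is used because no shorter baseline sub-window is
better motivated. Internally AP is always forward-positive (some plotting
conventions are negative-forward; readers flip the sign via
`ap_forward_sign`), so expanding flow yields negative (backward) VEPRs and
contracting flow positive (forward) ones.

**Vection outcomes.** Per trial: a verbal rating (0–100), the maximum of
the continuous throttle rating, and the onset latency — the time at which
the throttle first reaches a 5% cutoff. Trials that never reach the cutoff
have a *missing* latency; these are excluded pairwise in correlations and
counted, never imputed.

## Recurrence quantification

The AP quiet-stance series is embedded by time delay:
$\vec v_i = (x_i, x_{i+\tau}, \ldots, x_{i+(m-1)\tau})$, giving
$N-(m-1)\tau$ state vectors. The recurrence matrix is
$R_{ij} = \Theta(\varepsilon - \lVert \vec v_i - \vec v_j \rVert)$; a
distance exactly equal to the radius counts as recurrent. The recurrence
rate is the plain density $RR = N^{-2}\sum_{ij} R_{ij}$, which includes
the identity line — the formulation used with no Theiler exclusion. A
Theiler band is available (`theiler > 0` zeroes $|i-j|\le$ band, identity
line included) for users who prefer the stricter convention.

Line-based measures follow the standard recurrence-plot literature (their
definitions vary slightly across toolboxes, so the exact formulas are
spelled out here):

* `det` — fraction of off-identity recurrent points on diagonal lines of
  length $\ge \ell_{\min}$;
* `l_mean`, `entr` — mean and Shannon entropy (nats) of the diagonal
  line-length distribution over lines $\ge \ell_{\min}$;
* `lam`, `tt` — the vertical-line analogues (laminarity, trapping time);
* `trend` — the least-squares slope of per-diagonal recurrence density
  against distance from the identity line, fitted over offsets up to 90%
  of the maximum (the outermost diagonals are short and their densities
  noisy).

Diagonal lines are counted once each (upper triangle); vertical lines are
counted over the matrix as stored. When no line reaches $\ell_{\min}$ the
affected measures are returned as `NA` — missing, not zero — so downstream
correlations drop them pairwise instead of absorbing a fake 0.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 8 | embedding dimension |
| `tau` | 15 samples | embedding delay (150 ms at the 100 Hz reduced rate) |
| `radius` | 30 | recurrence threshold, signal units |
| `lmin` | 4 | minimum line length |
| `norm` | euclidean | phase-space norm (`maximum` available) |
| `theiler` | 0 | exclusion band half-width |
| `radius_mode` | absolute | or `fraction_of_mean_distance` |

The defaults are a widely used CoP parameter set. Two of them deserve
comment. The *norm*: Euclidean is the common choice in the classic RQA
toolbox lineage, and the maximum norm is one flag away. The *radius of
30* is meaningful only in a specific hardware's signal units: on
millimetre-scale synthetic sway it saturates the matrix
($RR \to 1$). For that reason every cohort-level analysis in this package
(tests, the acceptance script, the examples) uses
`radius_mode = "fraction_of_mean_distance"` with `radius = 0.15`, i.e. a
threshold of 15% of the mean pairwise phase-space distance — a standard
scale-free heuristic that puts recurrence rates in the fraction-of-a-percent
to few-percent range typical of published CoP RQA. The reference distance
is computed over at most 1024 evenly spaced embedded vectors; this is exact
for the series lengths used here after reduction and deterministic always.

### Preprocessing order

Raw 1000 Hz traces are zero-phase filtered (order-5 Butterworth low-pass,
two passes, so the effective magnitude response is squared and no lag is
introduced), then — for the RQA branch only — reduced by non-overlapping
10-sample boxcar averages to 100 Hz. Descriptions of CoP smoothing in the
applied literature are often ambiguous about pass direction; since CoP
signal energy lies below ~10 Hz and the purpose of this stage is removing
high-frequency noise, the filter is implemented as a *low-pass* with a
configurable cutoff defaulting to 10 Hz, and the cutoff is recorded in
every run report rather than presented as a universal constant. Filtering
uses odd-reflection end padding so a constant input passes through
exactly. Boxcar windows are true downsampling (not a moving average) so
that $\tau = 15$ at the reduced rate spans 150 ms, matching published CoP
RQA setups; a `moving` mode exists for comparison. A trailing remainder
shorter than the window is discarded — never padded — and the discard
count is reported. Path length and the ellipse are computed on the
filtered (not reduced) trace, because downsampling shortens paths;
`path_on = "raw"` is available since conventions differ on whether path
lengths are taken from raw or conditioned data.

## The synthetic cohort generator

The generator's purpose is to reproduce the *statistical structure the
analysis consumes*, not postural physiology. One latent scalar per subject
— visual dependence $v \in [0,1]$ — drives every contrast:

* **Quiet stance.** AP and ML are stationary mean-reverting (OU / AR(1))
  processes (reversion 0.8 s$^{-1}$, stationary SD ~2 mm, drawn
  log-normally per subject). Eyes open, AP additionally carries a slow
  sinusoid of amplitude $a(1-v)$ ($a \approx 5$ mm, 0.12–0.18 Hz): low
  visual dependence means more recurrent eyes-open structure. Eyes closed,
  the noise SD is scaled by $(1+v)$: sway grows with visual dependence,
  giving Romberg ratios above 1.
* **Standing flow.** The AP mean shifts by $-g\,v$ during expanding flow
  and $+7.7\,g\,v$ during contracting flow ($g \approx 2.3$ mm), matching
  the direction and the roughly eightfold forward/backward asymmetry of
  real visually evoked responses (one can lean much further forward than
  backward).
* **Seated vection.** Verbal ratings are
  $\mathrm{clip}(100(b_0 + b_1(v - \tfrac12)) + \text{offset}_{contr} +
  \text{noise})$ with $b_0 = 0.376$, a contracting offset of +23 points,
  and slope $b_1 = -0.75 \times \text{coupling}$. The cohort-level
  `coupling` parameter is the *target correlation between the
  eyes-open-minus-eyes-closed recurrence signature and mean vection* (the
  headline association this analysis is designed to detect); because the
  construction makes eyes-open recurrence decrease in $v$, a negative
  coupling makes vection increase with $v$. Throttle traces rise
  sigmoidally from exactly zero at onset to a maximum drawn as 0.65–0.95
  of the trial's verbal rating, with onset time decreasing in $v$;
  low-vection trials never reach the 5% cutoff and so exercise the
  missing-latency path.

Between-subject rating noise defaults to 8 percentage points (trial-level
noise is 0.6 of that), which leaves the latent coupling recoverable at
realistic strength without making it trivial. Every generated object is a
pure function of its parameters and seed: subject seeds are drawn once
from the master seed, and each (subject, condition) pair uses a distinct
fixed sub-seed offset, so cohorts rebuild bit-identically.

What the generator does **not** emulate: non-stationary drift, heavy-tailed
or intermittent sway, fatigue and order effects across the session,
biomechanical coupling between AP and ML, and any mechanistic model of
multisensory reweighting. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind assumed*, not that real force-plate
data carry that structure.

## Numerical and design choices

* Sampling is required to be hardware-clocked: uniformity tolerance is
  1e-9 s and resampling is deliberately out of scope (gaps are an error).
* Degenerate geometry (collinear or constant CoP clouds, eigenvalue ratio
  beyond 1e12) raises a classed error instead of returning an unstable
  ellipse.
* Pearson correlations use pairwise-complete observations (preserving
  per-measure $n$ when latencies are missing) and two-sided p-values from
  the $t$ transform on $n-2$ df. No multiplicity adjustment is applied —
  matching the raw-p reporting style of the analyses this package
  reimplements — but every correlation table carries an `n_tests`
  attribute so users can adjust.
* Paired t-tests with zero-variance differences raise a degenerate-data
  error rather than returning an infinite statistic.
* Signed VEPRs are used in correlations; a magnitude mode would discard
  the direction information that distinguishes expanding from contracting
  responses.

## Problem sizes used in the shipped checks

The test suite runs the oracle-equivalence checks on up to ~120 embedded
vectors (exhaustive $O(n^2)$ oracles), the ellipse calibration on 60 000
draws, the direction-contrast cohort at the full design scale (20 subjects,
60 s quiet stance and 360 s flow sessions at 1000 Hz), and the
coupling-recovery study on 20 replicate cohorts of 50 subjects with 30 s
quiet-stance traces (2 895 embedded vectors per condition — the same
embedding density as the full 60 s series, at a quarter of the pairwise
cost). The acceptance script analyses one cohort of 13 subjects at the
full design scale. These sizes are the package's own choices: large enough
that every recovered quantity is stable, small enough to run routinely.

## Known limitations

* RQA here is univariate (AP only, following the source analyses); ML
  recurrence is computable by passing the ML channel but is not part of
  the default feature set.
* Embedding parameters are taken as given; automatic selection (false
  nearest neighbours, average mutual information) is out of scope.
* The generator's latent model is intentionally one-dimensional; real
  individual differences in sway are not reducible to a single visual
  dependence scalar.
* The absolute-radius default reproduces the published parameter set but
  is only meaningful in matching signal units; cross-study comparisons
  should prefer the relative radius mode.
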