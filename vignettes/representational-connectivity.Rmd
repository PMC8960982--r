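---
title: "Model-free and model-based representational connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free and model-based representational connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repconn)
```

## The problem

Multivariate functional connectivity asks whether the information carried by
the activity *patterns* of two brain regions is statistically related, rather
than whether their average activations covary. Representational connectivity
analysis (RCA) answers this at the level of representational geometry: each
region is summarized by its representational dissimilarity matrix (RDM),
whose entry $(i, j)$ is $1 - r_{ij}$, the Pearson-correlation distance
between the activity patterns of conditions $i$ and $j$ across that region's
channels. All comparisons operate on the $n(n-1)/2$ upper-triangle entries
(the RDM is symmetric with a zero diagonal), vectorized in row-major order.

Three estimators are implemented, for two regions with RDM (series)
$D_1(t)$, $D_2(t)$ and model RDMs $M$, $M_1$, $M_2$:

* **Model-free RCA** — $\mathrm{corr}(D_1(t), D_2(t+\tau))$ averaged over
  valid $t$ (static data: a single correlation). Sensitive to *any* shared
  structure, of interest or not.
* **1-model RCA** — the fit courses $c_k(t) = \mathrm{corr}(D_k(t), M)$ are
  computed for a single common model and correlated across time,
  $\mathrm{corr}(c_1(t), c_2(t+\tau))$. Tests whether one hypothesized
  representational content waxes and wanes together in the two regions.
* **2-model RCA** — as above but with region-specific models $M_1$, $M_2$:
  $\mathrm{corr}\bigl(\mathrm{corr}(D_1(t), M_1),\,
  \mathrm{corr}(D_2(t+\tau), M_2)\bigr)$. Because the models may differ, it
  can detect *transformed* information with congruent temporal dynamics.

Group inference uses a one-sided Wilcoxon signed-rank test of the
per-subject estimates against zero at a global threshold of $\alpha =
0.001$; only significantly *positive* correlations are interpreted as
connectivity. For model-based connectivity through a common model, the
verdict additionally requires that the two regions' fits to the model are
not significantly different (a two-sided signed-rank test on the paired
fits, same threshold; see "Design choices").

## The factorial design and its model geometry

The packaged experiments use 16 conditions: 4 visual-field positions
crossed with 4 object categories. ROI 1 ("V2", 120 channels) represents
position; ROI 2 ("ITC", 150 channels) represents category. The binary
factor models (0 when a pair shares the factor level, 1 otherwise) have a
useful closed-form geometry:

```{r}
d <- factorial_design(position = 4, category = 4)
pos <- binary_factor_model(d, "position")
cat_ <- binary_factor_model(d, "category")
compare_rdms(pos, cat_)
```

Each 120-element model vector has 24 zeros; the zero sets are disjoint, so
$\mathrm{cov} = 72/120 - 0.8^2 = -0.04$ and $r = -0.04/0.16 = -0.25$: two
regions representing the two different factors are *negatively* related at
the RDM level. The intermediate model counts the factors on which a pair
differs (equivalently, the sum of the two binary models); it correlates
identically with both components at $\sqrt{3/8} \approx 0.612$:

```{r}
int <- intermediate_model(d)
c(compare_rdms(int, pos), compare_rdms(int, cat_))
```

This is the smallest construction consistent with "larger dissimilarity for
pairs differing in both factors", and its exact symmetry between the
factors is what makes the intermediate-model confound in Experiment 1
clean: both regions fit such a model equally well even though they share no
information.

## The synthetic-data generator

`sim_config()` holds the study conditions; its defaults are the conditions
under which all packaged results are computed.

| parameter | default | meaning |
|---|---|---|
| conditions | 4 x 4 = 16 | full factorial crossing |
| `channels_roi1/2` | 120 / 150 | channels (voxels/vertices) per region |
| `signal_variance` | 0.5 | per-channel variance of each level prototype |
| `noise_variance` | 0.5 | per-channel variance of i.i.d. Gaussian noise |
| `n_subjects` | 20 | group size for inference |
| `n_time` | 200 | samples of the time-resolved scenarios |
| `common_input_variance` | 7 | per-channel variance of the injected input |
| `mixing` | `"orthonormal"` | how the common input maps into ROI 2 |
| `window_roi1` | \[30, 60\] | ROI 1 information window (0-based, inclusive) |
| `base_delay`, `jitter_range` | 20, \[0, 10\] | inter-ROI delay and its per-subject jitter |
| `analysis_lag` | 20 | fixed lag used by the lagged estimators |

**Prototype construction.** Each region draws one prototype pattern per
level of its factor; all conditions sharing the level share the prototype,
so the noiseless RDM has the binary-model block structure. The prototypes
are exactly mean-centered and orthonormalized (QR of a Gaussian matrix
restricted to the centered subspace) before scaling to `signal_variance`.
This makes the noiseless RDM *equal* the binary factor model to machine
precision — different-level pairs sit exactly at dissimilarity 1 — so the
zero-noise limits of all estimators reproduce the analytic model geometry
($-0.25$ between regions, fits of exactly 1) rather than hovering near it.
Raw (non-orthogonalized) Gaussian prototypes would leave $\pm 0.03$-scale
jitter in those limits while changing none of the noisy-regime results.

**Common input.** At every time sample an independent
conditions-by-channels Gaussian pattern $E_t$ (variance 7) is added to
ROI 1, and $E_t A^\top$ to ROI 2. The input must be condition-specific:
only then does it impose shared RDM structure across the regions. The
default mixing $A$ is a random isometry scaled to preserve per-channel
variance, so the injected geometry ($E_i^\top E_j$) is carried into ROI 2
exactly. Two Gaussian alternatives are selectable (`"scaled"`, scaled by
$1/\sqrt{\text{ch}_1}$, and `"literal"`, unscaled). They transmit the
injected geometry only noisily: for i.i.d. Gaussian $A$ the correlation
between $E_i^\top E_j$ and $E_i^\top A^\top A E_j$ is bounded by
$1/\sqrt{1 + \text{ch}_1/\text{ch}_2} \approx 0.745$ regardless of the
input variance, which caps the post-injection model-free RCA well below
what an isometric mixing yields. Since the point of the common-input
scenario is that a *shared* pattern drives spurious connectivity, the
geometry-preserving isometry is the default.

At the default variances (signal 0.5, noise 0.5, common input 7) the mean
post-injection model-free RCA across subjects is about 0.71 (the value
`scripts/acceptance.R` recomputes as `t4`). The private (signal + noise)
per-channel variance of 1 bounds it there: the common-to-private variance
ratio of 7 yields shared fractions of roughly $\sqrt{7/9}$ per region even
under a perfect isometry. A markedly higher value would require the private
variance to total about 0.5 — i.e. reading "variance 0.5" as the variance
of the final noisy patterns rather than of signal and noise separately. We
keep the separate-variances reading as the stated condition; the
pre-injection value (about $-0.22$) is invariant to that choice because it
depends only on the signal-to-noise *ratio*.

**Windowed information.** In the transformation scenario, information is
present only within a window: samples inside it contain prototype signal
plus noise, outside only noise. ROI 2's window is ROI 1's shifted by
$+\texttt{base\_delay} - j$ (congruent) or $-\texttt{base\_delay} - j$
(incongruent), with $j$ drawn once per subject, uniformly on
`jitter_range`. With the defaults, the congruent ROI 2 window starts in
\[40, 50\] and ends in \[70, 80\]; the incongruent window lies inside
\[0, 40\]. The analysis lag stays fixed at 20 for every subject — the lag
is an analysis parameter the researcher sets, not a per-subject quantity —
and time indexing is 0-based with inclusive windows.

**Seeds.** `subject_seed(master, i, stream)` is a pure counter scheme
(multiply-and-add modulo $2^{31}-1$), so regeneration is bit-identical,
adding subjects never perturbs existing ones, and distinct components
(static data, time series, common input, windowed data, random models)
draw from distinct streams. Internally seeded constructors save and
restore the caller's RNG state.

## Numerical choices

* Upper-triangle vectorization is row-major ($i < j$), fixed and
  documented, so saved vectors are comparable across sessions.
* Pearson correlations use the sample ($n-1$) normalization throughout;
  the test suite checks agreement with explicit sum-formula implementations
  to $10^{-10}$.
* Dissimilarities are validated, never repaired: entries outside
  $[0, 2]$ or asymmetries beyond $10^{-12}$ raise errors; degenerate
  (zero-variance) pattern rows raise an error naming the condition, and a
  degenerate sample in a series reports its time index.
* Lagged estimators use the truncated range $t \in [0, T-1-\tau]$ — a
  shift, not a circular correlation; no padding.
* The signed-rank test drops zero differences, assigns average ranks to
  ties, and computes the exact null distribution for $n \le 25$ by
  convolution on the doubled-rank lattice (valid under ties, unlike the
  textbook recursion); beyond that, a normal approximation with continuity
  and tie corrections. The exact branch is verified against full $2^n$
  enumeration in the tests.
* A constant fit course (zero variance over the analysis range) is an
  error rather than an `NA`, since its course correlation is undefined.

## Design choices

**Equality-of-fits threshold.** The model-based verdict requires the two
regions' fits not to differ significantly. All significance testing in this
package uses the single global threshold $\alpha = 0.001$, and the equality
clause uses the same threshold by default (`alpha_eq`, configurable). This
matters quantitatively: with 120 vs 150 channels the larger region's RDM is
estimated slightly more precisely, so its model fits run systematically
higher by about 0.008 — small, but with N = 20 and the low between-subject
variance of these simulations, a 0.05-level equality test rejects this
nuisance difference in roughly a quarter of groups, confounding the verdict
with a channel-count artifact the analysis is not about.

**1-model common model.** Experiments 2 and 3 use ROI 1's factor model
(position) as the common model, the convention under which the 1-model
results are reported.

**Random models.** `random_model()` builds the RDM of an
$n \times k$ Gaussian latent pattern matrix ($k = 30$ by default) rather
than filling entries i.i.d., so random models are always geometrically
valid RDMs. The similarity of two independent random models is unbiased
around zero with spread of about 0.09 — a property of the 120-dimensional
RDM space, essentially independent of $k$.

## What the generator does and does not emulate

The simulator reproduces the *informational* structure of a two-region
experiment: factorial condition structure, region-specific codes, additive
sensor noise, a shared input, and windowed, delayed information. It omits,
deliberately: hemodynamic or electrophysiological forward models, sensor
leakage and volume conduction, temporally autocorrelated noise,
between-subject variation in effect size, and trial-level structure
(patterns are condition means). Passing tests therefore demonstrate the
estimators' logic and their failure modes, not robustness to the nuisance
structure of recorded data.

## Known limitations

* With boxcar information windows, the incongruent 1-model estimate
  carries a small positive bias: ROI 1's positive fit bump and ROI 2's
  negative fit dip (its category-structured RDM correlates at about
  $-0.25 \times$ attenuation with the position model) are disjoint in time
  after the lag shift, and two disjoint deflections of opposite sign
  correlate positively through their means. At N = 20 this bias
  (about $+0.08$) is regularly group-significant even at $\alpha = 0.001$,
  so the "1-model RCA detects nothing in the incongruent case" pattern
  should not be expected from this design; the congruent 1-model estimate
  is strongly negative and never significant, as expected.
* The post-injection model-free RCA level depends on the common-to-private
  variance ratio and the mixing convention, as discussed above; comparisons
  against a target level should fix both.
* The equality-of-fits clause inherits the channel-count asymmetry noted
  above; designs intending exact exchangeability of the two regions' fits
  should use equal channel counts.

## Problem sizes used in the packaged checks

The acceptance script simulates 50 subjects at one time sample each
(seconds). The test suite's heaviest property check runs the three full
experiments (N = 20 subjects; 200 time samples for the time-resolved
scenarios) across 20 master seeds, around four minutes on one CPU; the
common-input sensitivity property runs the 20-subject analysis across 20
seeds in about two minutes.
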