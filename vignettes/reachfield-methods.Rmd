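---
title: "Methods: selectivity screening, response fields and cross-validated encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity screening, response fields and cross-validated encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachfield)
```

## The scientific problem

Neurons in sensory-motor planning areas (e.g. the medial intraparietal area,
MIP, and dorsal premotor cortex, PMd) modulate their firing while a reach is
being planned to a remembered target. A long-standing question is *what*
about the upcoming reach is encoded: its direction, its amplitude, both
independently, or the target's position in space as a whole. `reachfield`
implements the full analysis chain used to address this question with
center-out memory-reach data:

1. a **synthetic session generator** producing per-trial epoch firing rates
   from neurons with known ground-truth tuning,
2. a **selectivity screen** (task-relatedness filter, two-way fixed-effect
   ANOVA with interaction, direction-wise t-tests, shuffle nulls, binomial
   proportion tests),
3. **tuning geometry** (preferred direction, the angular offset
   $\Delta\mathrm{PD}$ between amplitude modulation and preferred direction,
   Rayleigh test, circular mean $\pm$ SE, amplitude-response curves),
4. **response-field characterization** (scattered linear interpolation onto
   an $11 \times 11$ grid over a 14 cm $\times$ 14 cm window, peak
   eccentricity, quartile field width, visual-angle conversion), and
5. **encoding-model comparison**: five parametric models fitted by
   constrained least squares and scored by split-half cross-validated
   consistency against the split-half noise ceiling, with pairwise
   signed-rank comparison across a population.

Because the original recordings are not redistributable, every claim the
test-suite makes is grounded in the synthetic generator, whose ground truth
is known exactly.

## Task geometry

Two target layouts are provided. *Task 1*: two amplitudes (defaults 5 and
10 cm) along four cardinal directions (0/90/180/270 degrees,
counterclockwise from screen-rightward). *Task 2*: three amplitude rings
(defaults 3, 5, 7 cm) of 16 equally spaced directions each; rings are
angularly staggered (default 7.5 degrees per ring) to emulate a layout that
fills a square touch screen rather than a perfectly radial one, and targets
may be marked omitted. Angles are degrees at every interface and radians
inside model evaluation. Cartesian conversions are exact
($x = r\cos\theta$, $y = r\sin\theta$, fixation at the origin).

Distances on the screen convert to visual angle via
$\deg(d) = \frac{180}{\pi}\,\mathrm{atan}(d/D)$ with screen distance
$D = 45$ cm by default; a linear small-angle variant is selectable. The two
agree to under 1% for $d/D < 0.15$. We make no attempt to reconcile the
source task's internally inconsistent cm-to-degree claims; both conventions
are exposed.

## The synthetic generator: a stated world

Each `ground_truth_neuron()` has a generating model (untuned, or one of the
five encoding models below), a baseline rate $b$ (default 5 Hz) and additive
per-epoch gains $g_e$ (default 40 Hz; the canonical *SNR span* used by the
population-level tests draws $g_e$ uniformly from $\{10, 20, 40\}$ Hz,
spanning weak to strong planning modulation). The expected rate at target
$\mathbf{x}$ in epoch $e$ is

$$\lambda_e(\mathbf{x}) = b + g_e \, f_{\mathrm{norm}}(\mathbf{x}),$$

where $f_{\mathrm{norm}}$ is the generating model's response mid-range
normalized over the configuration's targets — so the gain is the peak
modulation in Hz and rates are never negative. Untuned neurons have
$f_{\mathrm{norm}} \equiv 0$; the baseline epoch is untuned for every
neuron, which makes the task-relatedness filter's behaviour predictable.
Spike counts in each 500 ms epoch are Poisson,
$n \sim \mathrm{Pois}(\lambda/2)$, reported as rates $2n$ Hz; the Fano
factor of counts is therefore 1 by construction and is verified by test.
Trial counts default to the task medians (42 per target for Task 1, 10 for
Task 2). A memory-period duration, uniform on 1.1–1.7 s, is attached as
metadata only.

What the generator does **not** emulate: spike-time structure,
refractoriness, over-dispersion (real cortical counts often have Fano > 1),
slow gain drift, cross-neuron correlations, and epoch-to-epoch changes in
tuning shape (gains may differ by epoch but the spatial pattern is shared).
A green test therefore establishes correctness of the *analysis machinery*
under Poisson assumptions, not robustness to every property of cortical
data.

## Selectivity statistics

Epoch windows are all 500 ms: cue C = [0, 500] ms after cue onset, early
memory EM = [200, 700] ms after cue offset, late memory LM = [-700, -200] ms
before the go signal, movement RT/MT = [0, 500] ms after go. The baseline
window is not defined by the source description; we fix it as the 500 ms of
fixation immediately before cue onset, matching the other windows' length.

*Task-relatedness*: a neuron passes if some epoch differs from baseline at
$p < 0.05/4$ (t-test, Bonferroni over the four epochs) **and** some epoch
mean exceeds 1 Hz. The t-test is paired across trials by default (epoch
minus baseline of the same trial), which removes slow rate drift; the
unpaired variant is available since the source analysis does not specify
pairing.

*Two-way ANOVA*: fixed effects of direction and amplitude with interaction.
On balanced designs the sums of squares are computed in closed form (all SS
types coincide there); mildly unbalanced designs use type II via nested
residual comparisons — type II equals type I/III exactly when balanced and
is the robust choice for "approximately balanced" sessions. Zero-variance
degeneracies yield $p = 1$ (no evidence) or $p = 0$ (infinite $F$) with a
flag instead of an error, so population screens never abort.

*Bonferroni flags*: "amplitude-selective in any epoch" means the minimum of
the amplitude-main-effect and interaction p-values over the four epochs is
below $0.05/8$ (eight comparisons: 2 effect types × 4 epochs). The
"planning" variant restricts to the memory epochs EM and LM at $0.05/4$;
2 effects × 2 memory epochs is the only decomposition that yields exactly
four comparisons, and we log this as an interpretation rather than assert it
as the source's.

*Chance proportions* come from an exact one-tailed binomial test and from
re-running the screen on label-shuffled data (default 100 shuffles,
target labels permuted within neuron).

## Tuning geometry and circular statistics

The preferred direction (PD) is the sampled direction with maximal mean
rate, pooling amplitudes (ties broken toward the smallest angle, flagged).
$\Delta\mathrm{PD}$ is the wrapped difference, in $(-180, 180]$, between
the direction with the smallest amplitude-modulation p-value (or, in the
alternative mode, the circular mean of all significantly modulated
directions) and the PD; neurons with no direction significant at 0.05 are
excluded, not errored. The Rayleigh test uses
$Z = n\bar R^2$ and the standard series approximation
$p = e^{-Z}\left(1 + \frac{2Z - Z^2}{4n} -
\frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right)$, clamped to $[0, 1]$ and
validated against a Monte-Carlo null of $\bar R$ (permuting angle labels
leaves $\bar R$ invariant, so the meaningful brute-force null is uniform
resampling). The circular SE is the dispersion-based estimator
$\sqrt{\hat\delta/n}$ with $\hat\delta = (1 - \hat\rho_2) / (2\bar R^2)$
($\hat\rho_2$ = resultant length of the doubled angles); the source does not
name its estimator, so ours is documented rather than matched.

Amplitude-response curves (Task-2 layouts) read the mid-range-normalized
per-target means along the PD and along the sampled direction closest to
PD + 180 degrees (rings are staggered, so the exact opposite may not be
sampled), and report pooled Pearson correlations between amplitude and
normalized rate. Normalization is the same mid-range utility used
everywhere (`midrange_normalize()`), so "normalized firing rate" has a
single definition in the package.

## Response fields

Per-target mean rates are interpolated by a Delaunay triangulation of the
target scatter with barycentric (piecewise-linear) evaluation at the bin
centers of an $11 \times 11$ grid tiling the 14 cm × 14 cm window. The
triangulation is built once per configuration; interpolation is then a
fixed weight matrix, which is what makes ~10^6 split-half patterns cheap.
Two properties pin the implementation down independently of any library:
the interpolant is exact at the targets and exact for affine functions of
$(x, y)$. Amplitude rings are exactly cocircular — a degenerate case for
Delaunay — handled by an inclusive in-circumcircle predicate; any valid
triangulation yields the same knot/affine exactness. Bins outside the
convex hull take the nearest target's value and are flagged in a validity
mask; statistics use all 121 bins by default (`mask_only = TRUE` restricts
to the hull).

The grid convention: bins *tile* the window (bin side 14/11 cm), so the
uniform pattern's quartile area is the full window and its width is exactly
$\deg(14)$.

Peak eccentricity is the distance of the argmax bin center from the origin
(ties: smallest eccentricity, then smallest angle), converted to visual
degrees; field width is $\deg(\sqrt{A})$ where $A$ is the area of bins with
values at or above their own 75th percentile (linear-interpolation
percentile, ties included by $\geq$). Note a structural property of this
definition: because the threshold is a percentile of the bin values, about a
quarter of the bins is always selected, so the width statistic varies only
through ties and is largely insensitive to the true field size — consistent
with the narrow width ranges this measure produces in practice. Both
statistics are affine-invariant, hence identical on raw and normalized
patterns. A Gaussian display blur (σ = 0.5 bins, symmetric padding,
mass-preserving) is provided for figures only; quantification functions
refuse smoothed patterns unless explicitly overridden.

## Encoding models and fitting

The five candidate models map $\mathbf{x} = (x, y) = (\theta, r)$ to a
scalar response:

| # | form | parameters (box constraints) |
|---|------|------------------------------|
| 1 | $\cos(\theta - \theta_0)$ | $\theta_0 \in [-\pi, \pi]$ |
| 2 | $\cos(\theta - \theta_0)\,k r$ | $+\;k \in [-100, 100]$ |
| 3 | $e^{\sigma \cos(\theta - \theta_0)} / (2\pi I_0(\sigma))$ | $\sigma \in [0.01, \infty)$ |
| 4 | model 3 $\times\, k r$ | as above |
| 5 | $\exp\!\big(-\tfrac12 (\mathbf{x}-\boldsymbol\mu)^\top \Sigma^{-1} (\mathbf{x}-\boldsymbol\mu)\big)$ | $\mu_{x,y} \in [-20, 20]$, widths, $\rho$ |

Numerical choices worth stating:

* **Model 5 sign.** The position model is sometimes written without the
  negative exponent; as printed that diverges away from $\boldsymbol\mu$
  and cannot describe a field that "fires maximally at a location". We
  implement $\exp(-\frac12 q)$ and flag this prominently.
* $\Sigma = \begin{pmatrix} \sigma_x^2 & \rho\sigma_x\sigma_y \\
  \rho\sigma_x\sigma_y & \sigma_y^2 \end{pmatrix}$; since only squares of
  $\sigma_{x,y}$ enter, the nominal $[-5, 50]$ width bounds are implemented
  on $[10^{-3}, 50]$; $\rho$ is bounded to $[-0.99, 0.99]$ with a
  positive-definiteness check.
* $\sigma$'s upper bound $\infty$ is capped at $10^3$ for the optimizer; at
  that concentration the normalized pattern is numerically a delta on the
  grid. The Von Mises normalizer uses the exponentially scaled Bessel
  $I_0$, so no overflow occurs anywhere in the box.
* **Fitting** minimizes the SSE between the mid-range-normalized model
  pattern and the (normalized) data pattern over the grid bins — Pearson
  comparisons downstream are scale/offset-free by construction. The
  optimizer is a box-clamped Nelder-Mead (C++), objective tolerance
  $10^{-10}$ relative, multi-start: `n_restarts` bound-uniform draws
  (default 10) plus one data-driven start ($\theta_0$ at the pattern's
  angular argmax; $\boldsymbol\mu$ at its spatial argmax). Starts are drawn
  on the R side from a seeded stream, so fits are exactly reproducible, and
  the draws for $k$ restarts are a prefix of those for $k+1$, making the
  best objective provably non-increasing in the restart count. Noiseless
  self-recovery lands within 2 degrees ($\theta_0$) and 0.5 cm
  ($\boldsymbol\mu$).

## Split-half consistency and the noise ceiling

Per neuron, epoch and repeat (default 50 repeats): trials are split in two
halves *within each target* (stratified, so both halves cover all targets;
an odd count sends the extra trial to a random half). Each half gives a
normalized interpolated pattern (N1, N2); `internal = cor(N1, N2)` is the
noise ceiling. Each model is fitted on N1 and on N2; the model consistency
is the mean of `cor(N1, M2)` and `cor(N2, M1)` — each model is only ever
scored against the half it did not see, so extra parameters cannot win by
over-fitting. Targets with fewer than 2 trials are excluded (the
neuron-epoch is skipped if more than 20% are); constant half-patterns are
discarded and redrawn, and a neuron-epoch is unusable if more than half the
draws are discarded. Both raw cross-correlations are averaged (their mean is
reported; the alternative of pooling them as two samples changes nothing
material and is noted as an open choice).

**Noise ceiling caveats.** The split-half internal consistency is a
*downward-biased* ceiling estimate: a model fitted on one half is a
denoised version of it, so when the data are generated exactly by that
model family, its cross-validated consistency can sit reliably *above*
`internal` (we measure up to +0.08 at 10 Hz gain). The meaningful ceiling
property is therefore population-level — for each model, the mean
consistency over a mixed population does not exceed the mean internal
consistency (beyond 2 SE of the paired difference across neurons) — which
is also the comparison made in practice (per-model bars vs the ceiling
bar). The per-neuron inequality is *not* asserted; tests document the bias
instead. With real neurons, model mismatch dominates and consistencies fall
below the ceiling.

Pairwise model comparison uses two-tailed Wilcoxon signed-rank tests on the
paired per-neuron consistencies (p = 1 when all differences vanish;
at least 6 neurons required).

## Pipeline, seeds, and outputs

`run_pipeline()` executes simulate → selectivity → tuning → fields → models
from a single `run_config()`, writing tab-delimited tables, JSON summaries
and a manifest. Randomness uses a seed hierarchy (master → stage → neuron →
repeat) so that adding neurons never perturbs existing ones and identical
config + seed gives byte-identical outputs. `recovery_report()` scores a
simulated run against its ground truth: confusion matrix of generating vs
highest-consistency model, wrapped $\theta_0$ and Euclidean $\mu$ recovery
errors, and the selectivity screen's hit rates.

## Known limitations

* The quartile field-width statistic is structurally insensitive to the
  true field size (see above); it is implemented as defined, not improved.
* Poisson noise only; no over-dispersion knob.
* Cross-epoch dynamics of response fields are out of scope; epochs are
  analysed independently.
* Population proportions from the original recordings (e.g. the
  amplitude-selective percentages) are not reproducible without those
  recordings and are deliberately not targeted by any test.
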