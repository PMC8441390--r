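---
title: "Modelling near-perfect adaptation to optogenetic Notch input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling near-perfect adaptation to optogenetic Notch input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomotif)
```

## The scientific problem

When nuclear entry of the Notch intracellular domain (NICD) is switched on
optogenetically in a cellularising embryo, nascent transcription of the
target gene *sim* (visualised as MS2/MCP nuclear spots) rises within minutes
and then decays back towards baseline — even though nuclear NICD remains
high. This package provides the quantitative machinery to (i) extract
expression and translocation dynamics from the image data, (ii) reconstruct
the nuclear NICD input from a transport model, (iii) fit candidate
adaptation circuits to the expression dynamics, and (iv) predict which
molecular perturbations distinguish the candidates.

All times are minutes. Model concentrations and motif state variables are
non-dimensional, scaled so that pool totals and state capacities are 1.

## The import–export model

Four pools: cytoplasmic/nuclear (C/N) × fluorescent/bleached (F/B). Import
(`ki`), export (`ke`) and bleaching (`b`, light phases only) are first-order:

$$\dot C_F = k_e N_F - k_i C_F - b C_F, \qquad
  \dot N_F = k_i C_F - k_e N_F - b N_F,$$
$$\dot C_B = k_e N_B - k_i C_B + b C_F, \qquad
  \dot N_B = k_i C_B - k_e N_B + b N_F.$$

Bleached protein no longer fluoresces but keeps shuttling and signalling,
so the transcriptional input is $N(t) = N_F + N_B$ while the *measured*
quantity is the fluorescent ratio $N_F/(N_F+C_F)$.

Two structural facts make the system solvable in closed form, which
`simulate_import_export()` exploits segment by segment (light/dark
parameters switch at protocol boundaries, with exact state carry-over):

* the fluorescent pool $F = C_F + N_F$ decays exactly as $F_0 e^{-bt}$ and
  its nuclear fraction relaxes to $k_i/(k_i+k_e)$ at rate $k_i + k_e$;
* the total pool is conserved, and the total nuclear amount obeys the same
  relaxation independently of $b$.

There is consequently no integration error beyond floating point; the test
suite confirms agreement with an independent fixed-step RK4 integration to
better than $10^{-5}$ and mass conservation to $10^{-9}$ relative.

Because $b$ multiplies both fluorescent pools equally, the observed ratio is
*structurally independent of* $b$: the bleaching rate cannot be estimated
from ratio data. `fit_import_export()` therefore keeps $b$ fixed unless a
total-fluorescence series is supplied, in which case the normalised decay of
$C_F+N_F$ enters the loss and $b$ becomes identifiable. Light-phase fits
free $k_i$, $k_e$ and the initial fluorescent concentrations (bleached pools
start at 0); dark-phase fits free only $k_i$ and $k_e$, starting from the
end-of-light state with $b = 0$. Fits minimise the MSE between predicted and
measured nuclear/total ratios with bounded quasi-Newton optimisation from
seeded multi-starts (rates $[10^{-6}, 10]$ in log space, concentrations
$[0, 2]$); a constant ratio identifies only the quotient $k_i/(k_i+k_e)$,
which the tests assert rather than hide.

## Adaptation motifs

Three candidate circuits, each with an output-controlling activity and a
mechanism that shuts it down under sustained input:

* **negative feedback** — the output activates an inhibitor B of itself;
* **incoherent feedforward** — the input activates both the output and its
  inhibitor B;
* **state-dependent inactivation** — the active controller itself converts
  into a refractory state $A_{in}$, with no separate inhibitor species.

In the elementary (mass-action) family, e.g. feedback:
$\dot A = k_1\,\mathrm{In}\,(1-A) - k_2 B A - k_3 A$,
$\dot B = k_4 A (1-B) - k_5 B$; the feedforward variant drives B from the
input, and state-dependent inactivation reads
$\dot A_{on} = k_1\,\mathrm{In}\,(1-A_{on}-A_{in}) - k_2 A_{on} - k_3 A_{on}$,
$\dot A_{in} = k_2 A_{on} - k_4 A_{in}$. The Hill family raises every
non-decay interaction factor to a fitted exponent in $[0.25, 4]$. The full
equations are in `?motif_rhs`.

Numerical choices:

* integration by adaptive `lsoda` (deSolve) with compiled right-hand sides,
  `rtol = 1e-8`, `atol = 1e-10`; the input profile is linearly interpolated
  between its grid points (default grid 0.1 min);
* bases of fractional powers are clamped at 0 before exponentiation so that
  integrator overshoot past the unit box cannot produce NaNs;
* initial motif state is 0 (pre-stimulus, no expression); the output is $A$
  (or $A_{on}$), taken as proportional to the mRNA production rate.

The discriminating perturbation logic (`apply_perturbation()`): removing the
inhibitor ($k_4 = 0$) abolishes adaptation for feedback and feedforward but
is meaningless for state-dependent inactivation (an error, since the
controller itself inactivates); removing an attenuator of activation
($k_1 \to 10 k_1$) destroys adaptation for the inhibitor motifs yet
*strengthens* it for state-dependent inactivation; stabilising the active
state ($k_2 \to 0.1 k_2$) raises peak output for all three in the elementary
family, but in the Hill family only state-dependent inactivation responds
with a clear output increase. The acceptance suite asserts this grid with
margins (adaptation index below 0.1 / above 0.5; Hill peak gain above 1.2
for state-dependent inactivation versus below 1.1 for the others) chosen to
sit in the wide gap between the simulated regimes.

## Fitting conventions

Data (total spot intensity per frame) and model output live on arbitrary,
different scales. Both are brought to a common range by *fixed* linear
factors — data × 1/300, model output × 100 — before the pooled
mean-squared-error loss is computed; this is a numerical convenience that
does not affect parameters or dynamics. Rates are bounded to
$[10^{-4}, 100]$ and optimised in log10 space (six orders of magnitude);
Hill exponents start at 1 and are optimised linearly in $[0.25, 4]$.
`fit_motif()` runs a seeded deterministic global search: default rate
initials (activation near 1 min⁻¹, turnover slow — order-of-magnitude
conventions, not published values) plus log-uniform random restarts, each
refined by L-BFGS-B, followed by basin-hopping perturbations of the
incumbent. Any parameter landing on a bound is reported in `bound_hits` —
with the published parameters the inhibitor turnover rates sit at the lower
bound, reflecting that recovery of the adapted state is slow compared to the
observation window.

Because several parameter combinations produce indistinguishable output
traces (sloppiness), the honest contract of a fit is the reproduced *trace*,
not parameter equality. `recovery_study()` therefore reports the relative L2
error between fitted and generating output traces. For synthetic cohorts the
1/300 data factor is generalised to
`model_scale / (n_nuclei × intensity_scale)` — the same convention, tied to
the cohort's magnitude, reducing to exactly 1/300 at the default 100 nuclei
× 300 intensity units.

Study sizes: recovery runs fit a 40-minute continuous-activation window
sampled every 0.5 min (matching the 30-s acquisition interval of the
expression imaging), 100 nuclei per cohort. Noiseless fits use the full
global search; replicated noisy fits (20 per motif at 2% per-nucleus noise)
use a lighter two-start search, which the noiseless baseline shows is
sufficient once the data constrain the basin.

## Image quantification

**Spots.** Stacks are maximum-projected; adaptive background subtraction
removes a σ = 10 px Gaussian blur of the frame (reflect boundary handling,
so edges introduce no artificial gradients; negative values are preserved).
Detection is multi-scale Laplacian-of-Gaussian: scale-normalised responses
on a geometric σ-ladder, 3×3×scale local maxima above a threshold, greedy
suppression of overlapping detections (a weaker detection is dropped when
closer than `overlap × (r₁+r₂)`, r = σ√2). For a Gaussian spot of amplitude
*a* the matched-scale response is ≈ *a*/2, which anchors the threshold
choice; the detector's scale range, threshold and overlap fraction are
configuration values calibrated on the synthetic fixtures — no published
values exist for them. Spot intensity is the median within a square of edge
`round(3σ)` (forced odd, ≥ 3 px, clipped at borders; even-count medians use
the mean-of-two-middles convention). Coordinates are 0-based pixel-centre.

**Nuclei.** The counter channel is smoothed (σ = 2 px) and thresholded by
Otsu's method; the cytoplasm is the exact Euclidean dilation ring (radius
10 px) around the nuclei. Reporter means are taken per frame in each
compartment, and each track's minimum nuclear mean over time is subtracted
from both compartments as a background proxy. Two deliberate refinements:

* `quantify_nuclei()` erodes the nuclear mask by 2 px (configurable;
  0 reproduces the unrefined pipeline) before taking the nuclear mean.
  Thresholded masks carry a boundary ring of mixed nuclear/cytoplasmic
  pixels — Otsu lands below the edge midpoint on disk images — which
  otherwise biases the nuclear/total ratio by several percent. The
  cytoplasmic annulus is always built from the uneroded mask.
* Bleaching is fitted (log-linear least squares of $I_0 e^{-bt}$, exact for
  noiseless exponentials) in the 10–20 min window of continuous activation,
  where the on-state compartment composition is stationary. The recommended
  input is the *sum of the two compartment means*: it is proportional to the
  fluorescent pool $C_F + N_F$ and decays exactly exponentially, whereas the
  whole-frame mean confounds bleaching with composition drift whenever the
  compartment areas are unequal.

The bleaching-correction arithmetic (divide by $e^{-bt}$, i.e. add the
predicted bleached fraction back) cancels in the nuclear/total ratio, so the
choice between the divisive and additive readings is inconsequential for the
quantity the models are fitted to.

Dark-phase frames do not exist in pulsatile experiments (imaging light is
activating light), so time bases carry explicit gaps and nothing is
interpolated across them.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seeded (bit-reproducible) and carry their
ground truth:

* `render_spot_frames()` — isotropic 2-D Gaussian spots (the standard
  diffraction-limited approximation; the paper trail gives no forward model)
  on constant background with i.i.d. Gaussian pixel noise; centres placed by
  rejection sampling with a minimum separation and bounded retries.
* `render_nuclear_timelapse()` — nuclei as constant disks on a jittered
  hexagonal grid (guaranteeing non-overlap without a packing physics model);
  reporter intensities proportional to the simulated $N_F$/$C_F$. The
  default initial state is all-cytoplasmic ($N_F = 0$), the pre-activation
  condition; under it the minimum-background rule removes exactly the camera
  offset. If the true nuclear signal never approaches zero, the minimum-
  nuclear-mean background proxy over-subtracts — a limitation of the proxy
  itself, visible here because the ground truth is known.
* `simulate_expression_cohort()` — per-nucleus traces as onset-jittered,
  scaled motif output with additive truncated-at-zero Gaussian noise; pooled
  counts (trace above a detection threshold) and pooled total intensity
  mimic what automated spot detection reports.

Not emulated: PSF z-dependence and other optics, nuclear movement or
division, transcriptional bursting, spatial coupling between nuclei, and any
realistic (e.g. multiplicative or Poisson) intensity noise — the additive
Gaussian choice is a stand-in. Passing tests on these data therefore
validate the *computational* chain (detection, measurement, integration,
optimisation), not robustness to the full complexity of embryo imaging.

## Population statistics

Running means use a 1-min window and are emitted only where ≥ 9 observations
fall in the window; normal-theory 95% confidence intervals
(mean ± z·sd/√n) only where ≥ 5 samples exist at the time point; the
activation rate is the maximum of a second-order finite-difference gradient
(exact on linear ramps, one-sided at edges) within the 0–7 min window.

## Known limitations

* Dark-phase import is reported but effectively boundary-constrained: with
  export dominating in darkness, ratio endpoints barely constrain `ki`, and
  fits flag it in `bound_hits`.
* No spot tracking across frames, no 3-D detection, no nuclear tracking
  through division; per-track mode links connected components by nearest
  centroid and assumes approximately stationary nuclei.
* Motif fits are sloppy by construction; compare traces (or losses), never
  individual rate constants, across fits.
* The pipeline orchestrator (`run_pipeline()`) targets synthetic
  end-to-end runs and reproducibility audits; analyses of real stacks
  should call the quantification functions directly.
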