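---
title: "Models and methods behind forceramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forceramp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forceramp)
```

`forceramp` analyses constant-loading-rate ("force-ramp") pulling
experiments on a single folded nucleic-acid structure — here a human
telomeric G-quadruplex (GQ) tethered between two long dsDNA handles,
optionally bound to a pyridostatin (PDS) ligand and/or confined inside a
bowl-shaped DNA-origami nanocavity (NB). This vignette is the package's
account of the models it implements, the parameters that matter, the
numerical choices, and what its synthetic data can and cannot tell you
about real traces.

## 1. The pulling model

### Elasticity

The tether is an extensible worm-like chain. For relative extension
$z$, the Marko–Siggia interpolation gives

$$F(z) = \frac{kT}{P}\left[\frac{1}{4(1-z)^2} - \frac{1}{4} + z\right],$$

and with a stretch modulus $K$ the total extension is
$x/L = z_{\mathrm{MS}}(F) + F/K$. Defaults describe a 5040-bp handle
pair: contour length $L = 0.34\,\mathrm{nm/bp}\times 5040$, persistence
length $P = 50$ nm, $K = 1200$ pN. These are community-standard dsDNA
constants; the package exposes all of them in the configuration because
instrument-specific calibrations differ at the few-percent level. The
strand released on unfolding is an inextensible WLC with
$P_{ss} = 0.8$ nm and 0.44 nm/nt, and the folded structure contributes a
2.0 nm end-to-end distance, so a 21-nt core is expected to release
`expected_delta_L(21)` $= 7.24$ nm — consistent with the ~8 nm measured
release given the uncertainty in the ssDNA constants.

The inverse $z(F)$ has no closed form; it is evaluated on a dense
monotone grid ($\Delta z = 2.5\times 10^{-5}$, interpolation error below
0.05 nm at handle scale) rather than by per-sample root finding, which
keeps the simulator linear-time in trace length.

### Rupture kinetics

Unfolding is a single irreversible escape with Bell–Evans rate
$k(F) = k_0 e^{F x^\ddagger/kT}$. Under a ramp at $r$ pN/s this yields
an analytic rupture-force density and mode
$F^\ast = (kT/x^\ddagger)\ln(r x^\ddagger / k_0 kT)$, used three ways:
as the simulator's sampling law (inverse CDF, conditioned on survival to
the recorded ramp's start force), as the closed-form oracle in the test
suite, and as the inverse map `bell_k0_for_mode()` that turns target
population centres into kinetic parameters. The experiments being
emulated report population centres, not kinetics, so the default species
table places modes at 20, 30 and 47 pN (free GQ, confined GQ, and
ligand-bound confined GQ) with weights 0.48/0.26/0.26 — the measured
species inventory with a cavity-immobilized ligand — using
$x^\ddagger = 2$ nm, which gives the ~2.5 pN population widths seen in
rupture histograms. $\Delta L = 8$ nm for every folded species.

### How a rupture appears in a trace

The commanded load ramps linearly (5.5 pN/s, sampled at 1000 Hz over
10–30 pN, extended to 63 pN when high-force species are present). At the
rupture the tether's end-to-end extension is continuous, so the force
relaxes to the value $F'$ solving

$$x_{\mathrm{handle}}(F') + \Delta L\,\varphi_{ss}(F') =
  x_{\mathrm{handle}}(F_r),$$

then the ramp resumes. This renders both experimental signatures at
once: a sawtooth force drop (~2–4 pN for $\Delta L = 8$ nm, set by the
handle compliance) and an extension jump of $\Delta L\,\varphi_{ss}(F_r)$
between the folded and unfolded branches. The relax half-cycle follows
the unfolded branch down to a refolding force (default 5 pN, below the
recorded range — refolding is treated as certain between cycles, since
each recorded stretch starts folded). Measurement noise is additive
white Gaussian force noise, default sd 0.5 pN.

What the generator deliberately does **not** emulate: bead/trap
hydrodynamics and drift, coloured instrument noise, refolding kinetics
and unfolding intermediates, and any coupling between folding free
energy and the invented Bell–Evans kinetics. The last point matters for
interpretation: simulated hysteresis works are set by the ramp geometry
($W \approx \Delta L \int \varphi_{ss}\,dF$), so Jarzynski estimates on
simulated data validate the *estimator machinery*, not calorimetric
unfolding energies. Passing tests therefore demonstrate correct
recovery of rupture forces, populations, $\Delta L$ and work — not that
real traces are this clean.

## 2. Event extraction

**Detection.** A rupture is declared where the mean force over the 20
samples (20 ms) before a candidate point exceeds the mean over the 20
samples after it by at least `min_drop` = 1 pN while the commanded load
rises. The window matters: with 0.5 pN white noise and $\sim 10^4$
samples per trace, differencing 5-sample means (sd 0.32 pN) would
false-trigger constantly at a 1 pN threshold, whereas 20-sample means
put the threshold at $\sim 6.3\sigma$ (expected false positives
$\ll 1$ per thousand traces). Triggers closer than two windows are
merged. The rupture force is the linear-ramp extrapolation of the
pre-drop samples to the drop boundary, which is unbiased under white
force noise (noise-free recovery is exact to one ramp increment).

**Contour-length release.** Each branch is fit locally around the
rupture and evaluated at $F_r$; then
$\Delta L = \Delta x(F_r)/\varphi_{ss}(F_r)$. Two numerical choices are
load-bearing here. First, branch windows are selected by *sample index*
(±2 pN of commanded ramp, converted via the locally estimated ramp
increment), never by thresholding the measured force — conditioning on
a noisy response preferentially keeps favourable noise and biased
$\Delta L$ by ~1 nm in early implementations. Second, the branch is
evaluated by inverting a linear force-vs-index fit and reading a
quadratic extension-vs-index fit, because regressing extension directly
on a noisy force attenuates the slope (errors-in-variables), and linear
branch fits leave a curvature bias of ~0.2 nm at low forces. With these
choices the noise-free recovery is exact to <0.01 nm and at 0.5 pN
noise the median absolute error is ~0.13 nm (1.6 %).

**Work.** The unfolding work of a cycle is the area enclosed between
stretch and relax within the configured force window, computed as the
loop integral $\oint F\,dx$ along the two measured paths closed at the
low-force end (trapezoidal), converted at 1 pN nm = 0.143932 kcal/mol.
It is zero for reversible cycles by construction and positive for
dissipative ones up to noise.

## 3. Population deconvolution

Rupture forces are fit by maximum-likelihood Gaussian mixtures
(expectation–maximization, log-space responsibilities, variance floored
at $10^{-3}$ sample sd, 10 restarts from quantile-spread starts, best
log-likelihood kept, deterministic under a seed). The component count is
fixed by the experimental design — 2 without ligand, 3 with an
immobilized ligand, 4 in a titration — not chosen by information
criteria, because the species inventory is asserted by the assay.
Components are labelled by the force window containing their mean
(17–24, 24–32, 32–40, 44–63 pN); the upper edge of the last window is
the ramp turnaround, so a mean beyond it is `Unassigned`. When two
components land in one window the one nearer the window centre wins and
both are flagged. The 32–40 pN window is context-dependent: in free
ligand solution it is the solution-bound complex (GQ–PDS), while with a
cavity-immobilized ligand the same force range is occupied by the
unbound confined structure; `assign_species(context =
"immobilized_ligand")` applies and records that reinterpretation.
Percentages are rendered with halves rounded up, so rows sum to
100 ± 1.

### The proximity/confinement partition

With both binding partners anchored in the cavity, the high-force
population mixes two effects: rapid rebinding of the held-together pair
(proximity, centred ~47 pN) and the cavity's water-mediated
stabilization (nanoconfinement, ~54 pN). `partition_effects()` restricts
to 32–63 pN and deconvolves a two-component mixture with a **shared
component width**. The equal-variance constraint is not cosmetic: at
~2.3 sd separation the free-variance likelihood has a ridge that trades
weight against unequal widths, and the ML weight of a 0.78/0.22 truth
scatters with sd ≈ 0.13 (confirmed against an independent mixture
implementation); with a shared width the weight is identifiable and
recovers to ±0.05 at $n = 1000$. "Random deconvolution" is read as
bootstrap stabilization: 200 resamples are refit (warm-started from the
point fit) and the median weights reported with percentile intervals;
a switch exposes the alternative reading in which events are
stochastically assigned to components by responsibility. When the
two-component fit fails to beat a single Gaussian by a likelihood-ratio
margin of $\chi^2_{0.99}(2)$ the sample is unimodal at the available
resolution: the fit is flagged degenerate and the full weight collapses
onto the component nearest the grand mean rather than reporting an
arbitrary split.

## 4. Thermodynamics

Per-species works feed the Jarzynski estimator

$$\Delta G = -RT\,\ln\frac{1}{n}\sum_i e^{-W_i/RT},$$

evaluated with log-sum-exp (overflow-safe for $W \gg RT$), with
$R = 1.987\times10^{-3}$ kcal/(mol K) and default $T = 296.15$ K
(23 °C). Events are attributed to species by maximum mixture
responsibility; the weighted alternative is deliberately not the
default, keeping each estimate traceable to a concrete event subset.
The finite-sample estimator is biased, and the bias is reported next to
the value in two conventions: `bootstrap` reports the mean resampled
estimate minus the point estimate (positive when the estimator
overshoots), while `gaussian_correction` reports the additive large-$n$
correction $-RT\,\widehat{\mathrm{var}}(e^{-W/RT})/(2n\,\bar{X}^2)$
(negative for broad work distributions). For Gaussian works the
estimator converges to $\mu - \sigma^2/2RT$; at $\sigma = 2$ kcal/mol
and $n = 10^4$ its single-draw sampling sd is still ~0.2 kcal/mol, which
is why the test suite checks the estimator's mean over replicates
against the closed form rather than one draw.

The binding arithmetic is deliberately plain: the cycle
`hess_cycle_dG()` subtracts unfolding free energies,
`kd_from_dG()` exponentiates against the implicit 1 M standard state
(no cavity-volume correction is attempted — the resulting $K_d$ is a
lower-limit estimate), `apparent_kd()` converts the cavity's
stabilization of the fold into an equivalent ligand affinity, and
`affinity_fold_change()` reports the ratio and its orders of magnitude.
Fed the measured unfolding free energies of 12 kcal/mol (free GQ) and
27 kcal/mol (ligand-bound confined GQ), the chain gives 15 kcal/mol of
stabilization and a dissociation constant of
$8.5\times10^{-12}$–$1.01\times10^{-11}$ M across 296–298 K — note the
~19 % sensitivity of $K_d$ to two kelvin; the conventional "~10 pM"
figure corresponds to evaluating at 298 K. Against the 490 nM
dilute-solution affinity this is a ~49 000-fold, 4.7-orders-of-magnitude
enhancement.

## 5. Reproducibility and problem sizes

Every stochastic entry point takes a seed and restores the caller's RNG
state (`withr::with_seed`); `run_pipeline()` derives all stage seeds
from one global seed and writes a manifest with a config hash and
per-file checksums, so identical config + seed reproduce the JSON
reports byte for byte. The package's own validation uses problem sizes
a desk machine handles in minutes: 500 pulling cycles (~10⁶ samples) for
end-to-end recovery of the 48/26/26 inventory to ±5 points and the 8 nm
release to ±0.5 nm, 1000–2000 draws for distributional oracles, 10⁴
works for the Jarzynski closed form, and 200 bootstrap resamples for the
partition. At these sizes the residual end-to-end percentage error
(~2–4 points) is dominated by multinomial sampling of 500 cycles plus
the left-skew of Bell–Evans populations bleeding across Gaussian
component boundaries — a real effect that equally applies to
experimental histograms fit with symmetric components.

## 6. Known limitations

* Single-rupture unfolding only; intermediates on one stretch are
  detected as separate events and flagged, not modelled.
* The ssDNA constants behind the expected 7.24 nm release are
  field-standard stand-ins; labs calibrating their own ssDNA elasticity
  should override `ssdna_model()`.
* Simulated free energies are not calorimetric (Section 1); only their
  estimator properties transfer to real data.
* The apparent-$K_d$ and fold-change conventions assume both free
  energies were estimated at the same temperature; the functions check
  this when given `free_energy` objects but cannot when given bare
  numbers.
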