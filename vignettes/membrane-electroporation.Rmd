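---
title: "Modelling cell-size-dependent electroporation and membrane resealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell-size-dependent electroporation and membrane resealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nspef)
```

## The scientific problem

Nanosecond pulsed electric fields (nsPEFs) transiently permeabilize cell
membranes. Urothelial cancer cells take up far more membrane-impermeant dye
than normal urothelial cells after identical pulse exposure, swell more, and
lose more stiffness — and the dominant explanation is geometric: cancer cells
are larger, and the induced transmembrane potential scales with cell radius,
so bigger cells cross the electroporation threshold at lower external fields.
`nspef` implements the quantitative machinery behind that argument: the
threshold model, the resealing kinetics extracted from dye-uptake time
courses, morphometric and AFM-stiffness quantification, the associated
statistics, and synthetic-data generators that emulate each raw input so
every stage is testable end to end.

## The threshold model

For a spherical cell of radius $R$ in a uniform field $E$, the steady-state
induced transmembrane potential at the cathode-facing pole is
$\Delta V = \tfrac{3}{2} E R$. The external field required to induce a target
potential is therefore

$$E = \frac{2}{3}\,\frac{\Delta V}{R}.$$

Membrane charging is not instantaneous: during a pulse of duration $t$ the
potential builds as $\Delta V(t) = \Delta V_{\max}(1 - e^{-t/\tau_c})$ with a
charging constant $\tau_c \approx 2\ \mu\text{s}$ for mammalian cells. The
threshold field for a pulse of duration $t$ is the steady-state field divided
by this charging factor:

$$E_{thr}(R, t) = \frac{2}{3}\,\frac{\Delta V_{thr}}{R}\,
  \frac{1}{1 - e^{-t/\tau_c}},$$

with $\Delta V_{thr} = 0.2$ V as the conventional electroporation threshold.
Two consequences are load-bearing and tested: $E_{thr} \propto 1/R$, so a
20-µm cell needs exactly 1.5 times the field of a 30-µm cell at *any* pulse
duration; and $E_{thr}(t)$ converges to the steady-state value within 0.1%
once $t \gtrsim 14\,\tau_c$.

```{r threshold}
threshold_curve(c(20, 30), c(100e-9, 300e-9, 1e-6))
```

The angular dependence of the induced potential is not modelled (thresholds
refer to the pole, where it is maximal), and pore-dynamics models are out of
scope: the package computes the deterministic threshold criterion only.

### The electrode field

The experimental field is produced by two parallel 0.5-mm tungsten rods at
1.5 mm center spacing, driven here at 1 V and scaled linearly to the applied
voltage. We use the closed-form 2D solution for two infinite charged
cylinders: outside the conductors the field equals that of two line charges
at $x = \pm s$, $s = \sqrt{(d/2)^2 - a^2}$, with the charge density fixed by
the inter-electrode voltage through
$\lambda/(\pi\varepsilon) = U / \operatorname{acosh}(d/2a)$. This is a
deliberate idealisation of the physical contact geometry (the rods actually
meet the coverslip at 45°, a 3D configuration we do not attempt to solve);
it preserves the monotone decay of intensity with distance from the gap, is
exactly linear in the applied voltage, and is verifiable against an
independent numerical gradient of its potential to $10^{-9}$ relative
accuracy. The analytic model is *not* expected to reproduce the absolute
kV/cm labels attached to the imaging sub-regions in the original setup; the
sub-region machinery (`assign_subroi_fields()`, default 21×21 sampling grid
per sub-region, configurable) only requires the ordering and linear scaling,
which it has by construction.

## Resealing kinetics from dye uptake

After pulse delivery at $t_0$, dye uptake follows a single-exponential
saturation as membrane lesions reseal:

$$F(t) = A\,(1 - e^{-(t - t_0)/\tau}), \qquad t \ge t_0,$$

where $A$ is the extrapolated plateau and $\tau$ the resealing time
constant. `fit_uptake()` fixes $t_0$ at the recorded exposure time (pulse
delivery time is known; freeing it only adds degeneracy), subtracts the mean
pre-exposure baseline, and fits the post-exposure samples by least squares.

Numerically the model is linear in $A$ given $\tau$, so the amplitude is
profiled out in closed form and the fit reduces to a bounded one-dimensional
search over $\tau \in [1, 10^4]$ s: a 200-point logarithmic grid brackets
the optimum and `optimize()` refines it. This profiled search is
deterministic, needs no random restarts, and by construction never returns a
worse residual than a dense grid search over the same bounds (a property the
test suite asserts against a 2000-point grid oracle). The amplitude is
constrained non-negative; negative-trending traces are flagged
non-converged, and a trace that is identically zero after exposure converges
with $A = 0$ and $\tau$ marked unidentifiable. $R^2$ is computed on the
post-exposure samples as $1 - SS_{res}/SS_{tot}$. Negative
baseline-subtracted values are retained, not clipped, preserving noise
symmetry.

Group-level summaries (`fit_group_mean()`) fit the pointwise mean trace of
replicates on a common grid and report its $R^2$ alongside the individual
fits. Downstream comparisons use the trapezoidal AUC of the
baseline-subtracted trace and the uptake at a fixed evaluation time
(180 s for monolayers), both invariant to a common pre-exposure baseline.

Two acquisition cadences appear in the source protocols (3 s and 4 s
monolayer sampling); the package defaults to 3 s and exposes the interval as
a configuration knob, since nothing downstream depends on the choice.

## Swelling and stiffness after permeabilization

Permeabilized cells swell by colloid-osmotic influx. Spheroid swelling is
quantified on the projected 2D area as
$100 \times (a(t_{eval}) - \bar a_{pre})/\bar a_{pre}$, evaluated 10 min
post-exposure. The spheroid acquisitions are sampled every 10 s; exposure is
placed 30 s into the series so that at least three pre-exposure samples
define the baseline (the original timing of pulse delivery within the
spheroid acquisition is not precisely specified; this choice is recorded
here and used consistently by the generator and the analysis).

Stiffness is measured by AFM force mapping: 25 curves on a 5×5 grid per
spheroid per timepoint, each reduced to a Young's modulus by fitting the
spherical-indenter Hertz model

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R_{tip}}\;\delta^{3/2}$$

to the approach segment. `hertz_fit()` treats every sample position as a
candidate contact point; for each candidate the modulus is the closed-form
least-squares solution (the force is linear in $E$) and the full-curve
residual — zero force before contact, Hertzian after — selects the winner.
Evaluating the residual over the *whole* curve matters: restricting it to
the fitted range would let spurious early contact points hide the data.
The fitted indentation range is capped at $\delta \le R_{tip}$ (the sphere
approximation degrades beyond), but predictions are extended past the cap
for residual purposes. The Poisson ratio defaults to 0.5, the standard
incompressible-soft-tissue convention, since no measured value is
available. Per map, the representative modulus is the **median** of
converged fits (robust to occasional bad curves; the mean is available via
the `fun` argument, as both conventions appear in practice).

Post-exposure stiffness, normalized to baseline, decays as

$$y(t) = p + (1 - p)\,e^{-t/\tau_m},$$

with plateau fraction $p$ (stiffness retained at equilibrium). The fit
(`fit_stiffness_decay()`) again profiles the linear parameter and searches
$\tau_m$ in one dimension. For the cancer-spheroid (RT4-like) defaults the
parameters are fixed by two anchor losses: $p = 0.40$ with
$\tau_m = 4/\ln 6 \approx 2.23$ min places the 4-min loss at exactly 50%,
from which the 10-min loss evaluates to 59.3%. The normal-line (SV-HUC-1)
defaults solve the analogous two-point problem (26% and 29% losses), giving
$p \approx 0.709$, $\tau_m \approx 1.79$ min. Baseline moduli are
back-computed from the 10-min post-exposure values of 401.8 Pa and
1218.5 Pa, whose ratio of about 3 the noiseless pipeline reproduces
end to end.

## Morphometrics

Cell shape enters through the form factor $FF = 4\pi A/P^2$ (1 for a
circle, bounded by 1 for any simple closed curve) and through per-cell area
tables. The pipeline starts from measurement tables, not images — upstream
segmentation conventions travel with the table. Monolayer statistics treat
the ROI mean as the independent unit; tissue-microarray statistics average
cells per (array, tissue class) and weight arrays by their core counts, so
`tissue_group_means()` with equal weights reduces exactly to ordinary
means. The immunohistochemistry H-score is the weighted sum
$0\cdot\%_{neg} + 1\cdot\%_{weak} + 2\cdot\%_{mod} + 3\cdot\%_{strong} \in
[0, 300]$. Spheroid "mean radius" is defined as $\sqrt{A/\pi}$ of the
projection, the only definition available when just the projected area is
measured.

## Statistics

Group comparisons use Welch's one-way ANOVA (base R's
`oneway.test(var.equal = FALSE)` under the hood) followed by Dunnett's T3
post hoc test. T3 computes per-pair Welch $t$ statistics with
Welch–Satterthwaite degrees of freedom and adjusts via the studentized
maximum modulus (SMM) distribution with $m$ = number of comparisons; no
installed package provides T3, so the SMM tail probability
$P(M \le q) = E[(2\Phi(qS) - 1)^m]$, $S = \sqrt{\chi^2_\nu/\nu}$, is
evaluated by adaptive quadrature and cross-checked against Monte Carlo in
the tests. Tissue comparisons use a weighted one-way ANOVA
(`lm(weights = )`) with Tukey-adjusted pairwise comparisons of weighted
marginal means via `emmeans`. Correlation analyses report Pearson $r$,
$r^2$, the $t$-based two-sided $p$ with $n - 2$ df, and the OLS line.
Significance stars follow the 0.05/0.01/0.001/0.0001 convention.
Repeated-measures two-way ANOVA with sphericity corrections is deliberately
out of scope.

A note on the weighted ANOVA's df convention: doubling an observation's
weight reproduces the group means and all sums of squares of physically
duplicating the row, but the residual degrees of freedom count rows, so the
F statistics coincide only after aligning the df — the equivalence the test
suite checks at the sums-of-squares level.

## The synthetic-data generators

Each generator is the exact inverse of its analysis model at zero noise, so
zero-noise round trips recover parameters to numerical precision — the
strongest available correctness check, and the suite enforces it for all
four generators. Distributional choices: cell sizes, time constants and
plateaus are lognormal (positive, right-skewed biological quantities);
trace and deflection noise are additive Gaussian; map-level modulus noise is
multiplicative lognormal. Fixed seeds give byte-identical output, and the
generators restore the caller's RNG state.

Calibrated defaults (each verified by the tests that consume them):

* **Uptake groups.** Cancer-line time constants carry the reported values
  (T24: 130/84/86 s; UM-UC-3: 115/75/75 s at 0/2/5 mM Ca²⁺); plateau levels
  are set so group ratios at 180 s reproduce the reported fold changes
  (e.g. T24 : SV-HUC-1 = 6.1 at 5 mM). Normal-line time constants and all
  absolute fluorescence levels are not printed anywhere and are marked
  `source = "assumed"` in `uptake_group_defaults()`. Lower exposure levels
  scale plateaus by 1/1.5 and 1/3 with unchanged τ.
* **Noise levels.** Replicate-to-replicate CV is 15%. Per-point trace noise
  defaults to 2% of the plateau: at 5% the per-replicate fitted-τ spread
  becomes heavy-tailed (SEMs ≈ 25 s), which is incompatible with the
  resolved 130 vs 84 s contrast at high significance with n ≈ 19 — the
  spread of fitted time constants, not the raw pixel noise, is the
  observable the noise level must match.
* **Spheroid dataset.** Per-spheroid mean cell areas by type (values
  assumed; cancer types larger), with final fluorescence
  $F = \alpha + \beta A + \varepsilon$ and $\sigma_\varepsilon$ set
  analytically from the mixture variance of the size populations so the
  population correlation equals 0.36; the mean sample $r$ at $n = 45$ over
  100 seeds is required to land within 0.05 of the target. Swelling gains
  are set so the 10-min percent change matches each group target (12%,
  42%, 14–21%); the spheroid-level CV of that percentage is 5%, the spread
  consistent with adjacent groups (12% vs 14%) separating at n ≈ 10.
* **Morphometry.** Monolayer areas give the 1.8-fold cancer/normal ratio;
  TMA areas use the printed 111.8/90.7 µm² class means with per-array
  effects of 3% CV; perimeters are back-computed from sampled form factors,
  so the form-factor relation inverts exactly. 18 ROIs of 40–80 cells per
  line; 9 arrays carrying the printed 47/66/56 core totals.
* **Force maps.** Hertzian curves with $k = 0.04$ N/m, $R_{tip} = 1$ µm,
  $\nu = 0.5$, randomized contact points, 10% map-level modulus CV and 2 nm
  deflection noise by default; `noiseless = TRUE` zeroes every noise source.

What the generators do *not* emulate: spatial structure within images
(segmentation is out of scope), photobleaching, bi-exponential or
pore-population uptake mechanisms, Ca²⁺ reaction–diffusion, and viscoelastic
(time-dependent) indentation responses. Passing tests therefore demonstrate
that the analysis chain is correct and well-calibrated *for data generated
by its own model class with realistic noise* — not that the models are
adequate for any particular real dataset.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use the study-scale sizes
throughout: 18–20 replicate traces per monolayer group, 45 spheroids for the
correlation analysis (100 generator seeds when averaging the sample
correlation), 10 spheroids per swelling group, and 3 spheroids × 5
timepoints × 25 curves for the mechanics chain. These sizes match the
reported experimental n and keep the full suite comfortably fast. All
stochastic entry points take explicit seeds; `run_report()` writes a
manifest with a configuration hash so any output bundle can be regenerated
from (config, seed).

## Known limitations

The two-wire field is a 2D idealisation of a 3D contact geometry and is not
calibrated to absolute exposure labels. The threshold model is a
deterministic criterion on a spherical cell at its pole; real populations
mix shapes and orientations. The resealing τ is a phenomenological summary
of repair kinetics, not a mechanistic pore model. Hertz fits assume small
elastic indentation of a homogeneous half-space; spheroids are neither
homogeneous nor flat, so moduli are effective values, comparable within a
protocol rather than absolute. PDO-specific kinetic parameters are
generator assumptions, as no reference values are available for them.
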