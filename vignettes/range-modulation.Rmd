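---
title: "Modelling range modulation of proton spread-out Bragg peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling range modulation of proton spread-out Bragg peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4.5)
library(rangemod)
```

## The problem

A clinical proton beam deposits most of its dose in a sharp Bragg peak just
before the protons stop. Treatment plans spread this peak into a flat
high-dose plateau (a spread-out Bragg peak, SOBP) by stacking pristine peaks
of staggered range. The clinical attraction is the steep distal falloff: dose
essentially vanishes a few millimetres beyond the target. The complication is
biological: the relative biological effectiveness (RBE) of protons, taken as
a uniform 1.1 in clinical practice, rises over the last few millimetres of
each pristine peak, producing a biological hotspot at the distal edge and an
extension of the biologically effective range of roughly 1--2 mm. Because the
hotspot is hard to quantify *in vivo*, planners often refuse to stop a beam
inside a vulnerable structure, which sacrifices much of the sparing protons
could offer.

"Range modulation" confronts this directly: the planned dose of a beam is
split across two or three identical copies whose ranges differ by a few
millimetres. The summed delivery has a deliberately smeared distal falloff,
which lowers both the physical dose and the average RBE over the terminal
few millimetres, at the cost of a less sharp distal edge. This package is a
one-dimensional water-phantom simulator for studying exactly that trade.

## The pristine peak model

The physics literature does not prescribe a unique analytic pristine peak,
and nothing downstream depends on entrance-region detail, so the package
uses the minimal model with a realistic sharp distal falloff: a
Bragg--Kleeman stopping-power kernel with Gaussian range spread. The
straggling-free kernel for a proton of residual range $R$ is

$$ d_0(z; R) = (R - z)^{1/p - 1}, \qquad 0 \le z < R, $$

with power-law exponent $p = 1.77$ (the standard value for protons in
water). Individual protons stop at depths scattered around $R$, so the dose
is the kernel averaged over a normal distribution of stopping depths:

$$ D(z; R, \sigma) = \int_{R-6\sigma}^{R+6\sigma} d_0(z; r)\,
   \varphi(r; R, \sigma)\, dr . $$

The kernel's integrable singularity at $r = z$ is removed analytically by
the substitution $u = (r - z)^{1/p}$, which turns the integrand into a
smooth function ($D = p \int \varphi(z + u^p) \, du$) evaluated by 64-node
Gauss--Legendre quadrature. Doubling the node count changes the curve by
less than $10^{-4}$ relative, which is the package's convergence criterion;
the test suite asserts it. Each pristine curve is normalized to maximum 1,
so absolute dose lives entirely in the beam weights and all reported doses
are in arbitrary units (plateau prescription 100, so doses read as
percentages).

### The width parameter

Two effects set the width of a delivered pristine peak: intrinsic range
straggling, for which the package uses the standard scaling
$\sigma_s = 0.012\,R^{0.935}$ mm (about 1.3 mm at $R = 150$ mm), and the
energy spread of the delivery system. The two are combined in quadrature,

$$ \sigma(R) = \sqrt{\sigma_s(R)^2 + \sigma_E^2}, $$

with $\sigma_E = 2.4$ mm by default. The energy-spread term is essential,
not cosmetic: with pure straggling a peak is far narrower than the 6 mm
pull-back between pristine peaks of a uniform-scanning delivery system, and
no choice of weights can flatten the plateau (the ripple exceeds 30%). The
default $\sigma_E$ was fixed once, as a commissioning-style choice, so that
the canonical four-peak SOBP is clinically flat (about 1.6%
peak-to-trough-to-mean) while the distal 80--20 falloff (about 4 mm) and
the biologically effective range extension (about 1.8 mm, inside the
1--2 mm band expected from distal-edge RBE models) remain of clinical
magnitude. Peaks built with the rule remember it, so a range shift
recomputes $\sigma$ from the shifted range; an explicitly supplied
$\sigma$ is held fixed.

## Fitting the SOBP

`sobp()` places `n_peaks` peaks with the deepest at `distal_range` and each
subsequent peak pulled back by `spacing` (defaults: 4 peaks, 150 mm, 6 mm
-- the canonical beam used throughout), and solves non-negative weights
minimizing the squared deviation of the summed dose from the prescription
over the plateau grid points (Lawson--Hanson NNLS). The plateau is the
interval between the *straggled dose maxima* of the shallowest and deepest
peaks, shrunk by a 1 mm margin at each end. Defining the plateau from the
peak maxima rather than the nominal ranges matters: the straggled maximum
sits about 2.5 mm short of the nominal range, so an interval anchored at
`distal_range` would put its distal end on the falloff, where no weight
vector can hold the dose at prescription. Duplicate peaks make the design
singular; the solver collapses them, solves, and splits the group weight
equally, which is the minimum-Euclidean-norm minimizer and keeps the
solution deterministic.

```{r fit}
beam <- sobp()
beam
summary(beam)
```

```{r plot-sobp}
plot(beam, main = "Canonical 4-peak SOBP, physical and RBE-weighted dose")
```

## The distal-edge RBE model

Each pristine peak $k$ carries an analytic RBE profile: a hyperbolic
tangent centered on the depth $z_k$ of the straggled peak's dose maximum,

$$ \mathrm{RBE}_k(z) = b\left[1 + a\,\frac{1 + \tanh\!\big((z - z_k)/\lambda\big)}{2}\right], $$

with baseline $b = 1.1$, saturation $a = 0.35$ and characteristic length
$\lambda = 2$ mm. The proximal asymptote is exactly the uniform clinical
1.1; far beyond the peak the model saturates at a 35% excess. Two readings
of "saturating at 35%" were possible and the package had to pick one: the
excess is taken as *multiplicative* on the baseline (distal asymptote
$1.1 \times 1.35 = 1.485$), because that keeps "35%" interpretable as a
percent increase in biological effect; an additive asymptote of 1.45 is
available by setting `rbe_params(baseline = 1.1, saturation = 0.35/1.1)`.
Likewise the ramp is half-range ($0 \to a$, via $(1+\tanh)/2$) rather than
full-range ($-a \to +a$), because the plateau side is declared uniform.
The tanh argument is $(z - z_k)/\lambda$ with no extra factor of 2 -- the
simplest reading of a "characteristic length".

The RBE-weighted dose of a beam applies the model *per pristine peak
before summation*:

$$ D_\mathrm{bio}(z) = \sum_k w_k D_k(z)\, \mathrm{RBE}_k(z). $$

Because every component carries its own ramp, the RBE-weighted SOBP
ripples (about 6% for the canonical beam) even though the physical SOBP is
flat -- each pristine peak's distal edge is boosted where its neighbours
are not.

## Range-modulation schemes

`two_way_scheme(delta = 3)` splits the dose in half and pulls the second
half's range back 3 mm (half the 6 mm pristine-peak spacing);
`three_way_scheme(step = 2)` splits into thirds at pull-backs of 0, 2 and
4 mm, the variant used when a single beam carries a significant dose. The
sign convention is a design choice the source material leaves open: shifts
are applied *shallower* by default, because the clinical intent is to stop
short of -- never transmit through -- the organ at risk behind the target;
`direction = "extend"` is available for exploration. Weight fractions are
equal by default and must sum to one; `apply_scheme()` conserves total
weight exactly.

```{r modulation}
md2 <- modulated_dose(beam, two_way_scheme())
plot(beam$grid, beam$biological$values, type = "l", lwd = 2,
     xlim = c(110, 165), xlab = "Depth [mm w.e.]", ylab = "Relative dose [AU]",
     main = "RBE-weighted dose, unmodulated vs two-way modulated")
lines(beam$grid, md2$biological$values, lwd = 2, col = "steelblue")
abline(h = 100, lty = 3)
legend("topright", bty = "n", lwd = 2, col = c("black", "steelblue"),
       legend = c("unmodulated", "two-way (0 / -3 mm)"))
```

## Metrics and their conventions

All metrics live in `beam_metrics()`; the individual estimators are also
exported. The conventions, each of which the field's usage leaves open and
the package fixes once:

* **Flatness** is $100(\max - \min)/\mathrm{mean}$ over the plateau grid
  points -- scale-invariant, so it reads the same at any prescription.
* **"Range"** is the distal 90% crossing (R90) of the plateau reference
  level, the common clinical falloff reference, found by linear
  interpolation between bracketing grid points; R80 is available through
  the `fraction` argument.
* The **biological reference level** is $b \times$ (mean physical plateau
  dose), so the biologically effective range extension measures the distal
  RBE *ramp* and is exactly zero when the saturation is zero, rather than
  being inflated by the uniform 1.1 scaling.
* The **terminal window** realizing "the terminal few millimetres" is
  $\pm 5$ mm (configurable) around the evaluated delivery's *own* physical
  R90, with the reference level always taken from the unmodulated plateau.
  Centering the window on each delivery's own terminal region is the
  substantive choice: a pulled-back copy translates its RBE ramp shallower,
  so at any *fixed* depth the composed RBE ratio can only rise, and a
  window frozen at the unmodulated R90 would report modulation *raising*
  the terminal mean RBE. The mitigation claim is about the terminal
  millimetres of the delivery actually given, and under that reading the
  dose-weighted terminal mean RBE orders as expected: three-way < two-way
  < unmodulated (1.3046 < 1.3054 < 1.3223 for the canonical beam).
* The **distal hotspot ratio** is the peak RBE-weighted dose beyond the
  plateau, relative to the baseline-scaled plateau level.

```{r metrics}
compare_metrics(beam_metrics(beam), beam_metrics(beam, scheme = two_way_scheme()))
```

The comparison shows the trade explicitly: the hotspot ratio and terminal
mean RBE improve, while the physical plateau flatness and the falloff
sharpness worsen -- the deliberate compromise at the heart of the
technique.

## Numerical choices and degenerate inputs

* Depth grids are uniform, 0.1 mm by default (0.5 mm is the coarsest
  accepted), from the surface to `distal_range + 30` mm so the distal tail
  is fully covered; all lengths are mm water-equivalent.
* Peak maxima are located by argmax on a dedicated 0.01 mm grid around the
  nominal range, independent of the user's grid, so RBE centering does not
  wobble with grid resolution.
* A single-peak "SOBP" has no plateau interval; the weight is solved
  directly (prescription over the unit peak maximum) and plateau-based
  metrics fall back to the dose at the peak maximum as reference.
* `range_at()` signals a classed "range undefined" condition when a curve
  never crosses the threshold on its distal side; reports serialize it as
  the token `undefined`, never a number.
* The pipeline is fully deterministic: no randomness anywhere, so repeated
  runs are byte-identical.

## What the simulator does and does not show

The model is one-dimensional and analytic. It omits nuclear interaction
products, lateral scattering, tissue heterogeneity, and any dependence of
RBE on linear energy transfer, dose per fraction or tissue type -- the
distal-edge tanh model is an illustrative, fixed-saturation stand-in for
all of those. Consequently the package demonstrates the *structure* of
range modulation (how splitting ranges smears the falloff and dilutes the
terminal RBE, and by how much under the stated model), not patient-level
dosimetry; clinical planning quantities such as dose-volume histograms on
anatomy are out of scope. Within that scope every number the vignette
quotes is recomputed by the test suite or the bundled acceptance script.
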