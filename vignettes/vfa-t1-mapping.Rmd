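---
title: "Linear VFA T1 mapping with the half-angle tangent transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear VFA T1 mapping with the half-angle tangent transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfatau)
```

## The model

A spoiled gradient-echo sequence with repetition time TR, flip angle
$\alpha$ and perfect spoiling of transverse coherences reaches the
steady-state signal

$$S = A\,\frac{\sin\alpha\,(1-E_1)}{1-E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1},$$

with $A$ the fully relaxed 90° amplitude at the echo time.  Two exact
substitutions,

$$\tau = 2\tan(\alpha/2), \qquad
  \rho_1 = 2\tanh\!\left(\frac{TR}{2T_1}\right) = 2\,\frac{1-E_1}{1+E_1},$$

turn this into the rational function

$$S(\tau) = \frac{2A\rho_1\tau}{\tau^2 + 2\rho_1},$$

so that the coordinates $x = S\tau$, $y = S/\tau$ satisfy
$y = A - x/(2\rho_1)$ for ideal data.  The substitutions are bijections
from $\alpha \in (0^\circ, 180^\circ)$ and $TR/T_1 \in (0,\infty)$ onto
$(0,\infty)$ and $(0,2)$; both conform to their small arguments
($\alpha$ in radians, $TR/T_1$) with third-order error, which is what
licenses the familiar small-angle shortcuts of FLASH imaging.  The
signal maximum sits at $\tau_E = \sqrt{2\rho_1}$ (the Ernst angle,
$\cos\alpha_E = E_1$), where $y = A/2$: the Ernst point is always
halfway between the two intercepts of the line.

Everything in the package is phrased in these variables.  The estimator
is the ordinary least-squares line through $(x_i, y_i)$:
$\hat A$ is the intercept and $\hat\rho_1 = -1/(2b)$ the negative
half-reciprocal of the slope, transformed back to $T_1$ through the
inverse hyperbolic substitution.  The two-point case is the classic
dual-angle experiment in closed form.  For data pooled across several
short repetition times, $\rho_1 \approx TR/T_1$ makes
$x = S\tau/(2\,TR)$ a common abscissa and $T_1$ is read off directly as
the negative slope; the package warns once the fitted
$\max(TR)/T_1$ exceeds 0.2, where the quadratic error of the
approximation (relative error $(TR/T_1)^2/12$) passes roughly half a
percent.

### Numerical form of the classic equation

The classic and algebraic forms are the same function, and the package
keeps them numerically indistinguishable (a few ulp over the whole
domain) by evaluating the classic denominator as
$(1-E_1) + 2E_1\sin^2(\alpha/2)$ — a sum of positive terms — instead of
$1 - E_1\cos\alpha$, which loses up to three digits to cancellation at
small angles and long $E_1$.  The test suite asserts agreement within
8 ulp on a 500 × 500 grid.

## Noise propagation with correlated coordinates

Both plot coordinates carry the same measured signal, so their errors
are fully correlated with covariance exactly $\sigma_S^2$.  Propagating
through the line residual $F = y - (A - x/(2\rho_1))$ gives

$$\operatorname{var} F = \sigma_S^2\left[\frac{1}{\tau^2} +
  \frac{\tau^2}{4\rho_1^2} + \frac{1}{\rho_1}\right],$$

minimal at $\tau_E$ (value $2/\rho_1$) and divergent toward both
intercepts.  `residual_noise_scale()` returns the bracket;
`weight_function()` its reciprocal, the weights that cancel the
$\tau$-dependence in a weighted fit.  Because the weights need an a
priori $\rho_1$, `vfa_fit(weights = "optimal")` runs an unweighted pass
first and then iterates (at most 10 passes, relative $\rho_1$ change
below $10^{-6}$; on noiseless data the weights cannot move the exact
line, which the tests assert).

For protocol design the package propagates independent per-measurement
noise through the closed-form estimators: the partial derivatives
$\partial\hat\rho_1/\partial S_i$ and $\partial\hat A/\partial S_i$ are
evaluated analytically at the noiseless model point (the chain rule
runs through both coordinates, since $x_i$ and $y_i$ share $S_i$), and
a finite-difference mode serves as an internal cross-check.  A
Monte-Carlo check at $\sigma_S/A = 0.5\%$ on a mid-range tissue
($\rho_1 = 0.5$) reproduces the predicted variances within a few parts
per thousand.

**First-order caveat.**  The prediction is first-order.  The estimator
itself is a reciprocal of a regression slope, so it carries an
$O((\sigma_S/S)^2)$ bias (regression dilution plus ratio nonlinearity).
At the table level (ROI means, relative noise below a percent) this is
negligible; at the voxel level it matters — see the mapping section.

### Normalization of the variance table

Designs are compared on a unit-free scale: the variance of $\rho_1$
scaled by $(A/\sigma_S)^2$ and the variance of $A$ scaled by
$1/\sigma_S^2$, each multiplied by a calibration constant chosen so
that the optimized two-point relaxation design scores 4.000 and the
optimized two-point amplitude design 5.6133.  The calibration pins the
convention, not the physics: every other entry — 2.9313 for the
three-point T1 design, 2.0000/1.6532/1.3333 for four to six points,
2.8067 and 1.8711 for the replicated amplitude pairs — is a prediction
of the propagation machinery, and replication exactness
($m$-fold replication divides the variance by $m$) is tested
separately.

## Protocol optimization

`optimize_schedule()` minimizes the propagated variance over the $N$
normalized positions $u_i = \tau_i/\tau_E$ with a derivative-free
Nelder-Mead simplex in $\log u$, started from every sorted
combination (with repetition, all-equal excluded) of six log-spaced
levels spanning $u \in [0.1, 10]$, each run polished by a restart and
converged to a $10^{-12}$ relative objective tolerance.  The simplex
was chosen over gradient methods because the optima cluster replicated
points, where coordinate directions become degenerate.  Near-equal
minima (within $10^{-6}$ relative) are tie-broken toward the
lexicographically smallest sorted $u$; distinct local minima within 5%
of the best objective are reported as alternative branches, and for
even $N$ the replicated dual-angle scheme is always evaluated
alongside the global optimum (for the amplitude target the global
optimum clusters $N-1$ points low instead).

The structure that emerges: the T1-optimal positions are the
reciprocal pair $u = (\sqrt2 - 1, \sqrt2 + 1) = (0.4142, 2.4142)$ — the
85.4% and 14.7% amplitude levels — replicated for even $N$ with
variance exactly proportional to $1/N$; odd $N$ clusters points at two
slightly shifted positions.  The amplitude-optimal pair is
$(0.4903, 3.1461)$.  All positions are invariant to $A$, $\sigma_S$
and (as ratios to $\tau_E$) to $\rho_1$, which the tests verify.

`equidistant_schedule()` implements the complementary design
philosophy: levels $p_i = i/(N+1)$ spread evenly along the line, which
sacrifices variance but makes bias at either flip-angle extreme visible
against the consensus of the middle.  `realize_flip_angles()` converts
either schedule to degrees for a target (TR, T1), optionally rounding
to whole degrees (scanners often demand integers) and recomputing the
realized levels after the shift.

## Bias: transmit field and signal deviations

A multiplicative transmit-field factor $f$ scales the actual flip
angle.  In the small-angle regime ($\tau \approx \alpha$) fitting with
nominal angles returns $T_{1,app} = f^2 T_1$ and $A_{app} = f A$;
`correct_apparent_t1()` divides the map by $f^2$ post hoc, and
`fit_volume()` alternatively recomputes $\tau$ per voxel from
$f\alpha$ (exact mode).  The two routes agree within 1% for
$\alpha \le 15^\circ$, $f \in [0.8, 1.2]$.

`detect_signal_bias()` turns the linear display's diagnostic power into
a procedure: fit the included points, studentize the residuals with the
correlated-error scale above, and exclude one point per iteration until
nothing exceeds the threshold ($z = 3$ by default — a conventional
choice; the data do not fix it) or only three points remain.  Two
details matter:

* **The assessment fit is the weighted fit.**  Biased points live at
  the $\tau$ extremes, where they also have the largest leverage on an
  unweighted line; a coherent group of deviating high-angle points can
  capture the plain regression and push the residuals onto the clean
  middle.  The variance-cancelling weights peak at the Ernst point and
  anchor the line there.  The reported final fit is the plain
  unweighted regression on the retained points.
* **Significance and ranking are different questions.**  A relative
  signal deviation $\varepsilon$ shifts the residual by exactly
  $\varepsilon A$ — substituting $S(1/\tau + \tau/(2\rho_1)) = A$ —
  independent of $\tau$, while the noise scale varies strongly with
  $\tau$.  So the studentized residual decides *whether* a point is
  excluded, and the raw residual decides *which* candidate goes first.

When no noise level is given, $\sigma_S$ is estimated from the central
50% of the $\tau$ range (bias concentrates at the extremes) via a
Gaussian-consistent MAD of scale-corrected residuals; on numerically
noiseless clean data the estimate collapses and nothing is flagged.

## The synthetic-data module

The generators emulate the package's four reference conditions: a
uniform agar phantom (T1 = 2.41 s) acquired at TR = 6/12/24/48 ms with
flip-angle ranges matched to each Ernst angle (1° steps; 2° steps for
the 48 ms range — the ranges are fixed by the reference conditions, the
step is the package's choice); a MnCl2 phantom (T1 = 0.54 s, 13 angles
2-36° at TR = 7 ms) for spoiling studies; a three-compartment brain
(WM/GM/CSF T1 of 0.85/1.29/4.58 s, relative amplitudes 0.70/0.82/1.00 —
standard proton-density ratios, since the reference values specify only
T1) at the 16-angle 2-60°, TR = 11 ms in-vivo protocol.

Deviations are phenomenological: a multiplicative high-angle factor
with selectable sign, onset and optional linear ramp (imperfect
spoiling residuals vary in sign and onset with the RF phase increment,
so none of these is hard-coded), an additive low-angle offset, and
slice-profile integration (trapezoidal average of the Ernst signal over
a sampled profile of relative flip angles, at least 101 points), which
reproduces the known signature of 2D excitation: the signal maximum
shifts to higher nominal angles and the high-angle tail is positively
biased.  Noise is additive Gaussian or Rician
($\sqrt{(S+n_1)^2+n_2^2}$); the Rician mean offset follows the
expansion $\sigma^2/(2S)$, i.e. about 1% of $\sigma$ at SNR 50, which
the tests assert against simulation.  Every generator is pure given a
seed, restores the caller's RNG state, and reduces exactly to the
Ernst model when noise and deviations are off.

What the simulations do *not* contain: actual Bloch/EPG dynamics of RF
spoiling, k-space artifacts, motion, partial volume, or spatially
structured noise.  Passing tests therefore demonstrate correctness of
the estimators and procedures under the stated statistical model, not
robustness to everything a scanner can produce.

## Voxelwise mapping and problem sizes

`fit_volume()` evaluates the closed-form regression for all voxels in
one vectorized pass (64³ voxels × 16 angles fit comfortably in seconds
on one CPU), masks voxels whose mean signal falls below `mask_k` (=5)
times a background level taken from the lowest quintile of voxel
means, drops degenerate fits (non-negative slope, fewer than two
positive signals) with a count, and stores T1 in seconds with NA
outside the mask.

**Noise convention for volume simulations.**  Image noise in the
phantom tests is set relative to the measured tissue signal (1% of the
mean in-phantom signal, i.e. image SNR ≈ 100, typical of 3D FLASH).
Setting it relative to the fully relaxed amplitude $A$ would put
per-voxel signal SNR at 2-5 — short-TR signals are only a few percent
of $A$ — where the reciprocal-slope estimator is dominated by
regression dilution and no estimator of this family recovers
compartment medians to percent accuracy.  At image SNR 100 the
brain-phantom compartment medians recover to within 2% with the
2-18° angle subset.

Test problem sizes were chosen to exercise every code path at
comfortable runtimes: 16-20³ phantom grids, $10^4$-$10^5$ Monte-Carlo
replicates (vectorized), schedule optimization to $N = 6$.

## Known limitations

* The estimators assume magnitude signals with Gaussian noise;
  propagation formulas are first-order, and Rician noise enters only
  the simulator.
* `detect_signal_bias()` needs the clean points to outnumber (in
  weighted terms) the biased ones near the Ernst point; a protocol
  whose every sample is biased cannot be rescued, and the z = 3 default
  is a convention.
* B1 maps are inputs; the package neither acquires nor estimates them.
* No registration, motion correction or reconstruction: volumes are
  assumed aligned, and grid metadata is carried through untouched.
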