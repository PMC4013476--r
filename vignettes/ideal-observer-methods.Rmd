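---
title: "Ideal observer analysis of detection and free-localization tasks: models and methods"
author: "ioloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ideal observer analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

How efficiently does an observer use the information in a noisy image?
The classical yardstick is the *ideal observer* (IO): the decision rule
that attains the best possible performance given the exact statistical
model of the stimuli.  Measuring a human (or model) observer's contrast
threshold and dividing by the IO's threshold at matched performance gives
*efficiency*,
$$\eta = \left(\frac{C_{IO}}{C_{Obs}}\right)^2,$$
a number between 0 and 1 that controls for the task's intrinsic
difficulty.  `ioloc` implements this program for three visual tasks in
spatially correlated Gaussian noise:

* **cued detection** — yes/no presence judgment for a target at a known,
  central location;
* **free localization** — the target is always present somewhere in a
  search region and the response is a location, scored correct when it
  falls within an acceptance radius of the truth;
* **detect-and-localize (D&L)** — free localization with 50 %
  target-present trials and an explicit "absent" response governed by a
  criterion.

Because no human data ship with the package, a *synthetic linear
observer* with known, analytically tractable suboptimality stands in for
human subjects; every estimator in the pipeline is validated against
closed forms or exhaustive enumeration.

# Stimulus model

Stimuli are $N \times N$ gray-level images ($N = 256$ by default),
composed additively:
$$g = \bar b + n + c\,\bar b\, s_l,$$
with mean background $\bar b = 100$ gray levels (gl), a stationary
Gaussian noise field $n$, and a unit-peak Gaussian bump
$s(r) = \exp(-r^2/2\sigma^2)$, $\sigma = 3$ px, shifted to the target
location $l$.  **Target contrast** $c$ is peak amplitude over mean level;
this convention makes "20 % RMS contrast" noise correspond to pixel
variance $(0.2 \cdot 100)^2 = 400\ \mathrm{gl}^2$.

The noise has an isotropic power-law spectrum
$$S_\beta(f) = C_\beta / f^{\beta}, \qquad \beta \in \{0, 1, 2, 3\},$$
evaluated on the DFT grid in cycles/pixel, with the DC value set to the
first-harmonic value ($f = 1/N$) to avoid the singularity.  The package's
spectral scaling convention is that the grid mean of $S_\beta$ equals the
pixel variance; $C_\beta$ is fixed by that constraint, so the 20 % RMS
contrast holds *exactly* in expectation for every $\beta$.  Fields are
synthesized by filtering white Gaussian noise with $\sqrt{S_\beta}$ in
the frequency domain (a real white field is transformed, filtered, and
inverse-transformed; this is equivalent to Hermitian-symmetric frequency
sampling and is reproducible from a single integer seed).

Localization truth is uniform over the central $N/2 \times N/2$ search
region — one quarter of the image area; the wide border keeps the
circular (wrap-around) convolutions used throughout from coupling the
search region to the image edges.  Target locations are integer pixels
and embedding uses circular shifts, so stimuli are *exactly* linear in
contrast at a fixed seed — a property the tests exploit.

Display geometry enters only through the pixel angle,
$(180/\pi)\arctan(0.583\,\mathrm{mm}/640\,\mathrm{mm}) = 0.052^\circ$,
which converts pixel quantities to degrees (target FWHM
$2\sqrt{2\ln 2}\,\sigma = 0.37^\circ$; search width $6.7^\circ$;
acceptance radius $0.26^\circ$).  Images are kept in floating point; 8-bit
display quantization is a property of display hardware, not of the
decision theory, and is out of scope.

## White-to-pink processing

An image-processing variant filters $\beta = 0$ stimuli (after the target
is embedded) with an amplitude filter proportional to $1/f$, which turns
the white background into an exact $\beta = 2$ power law and reshapes the
target into a heavier-tailed profile.  Two readings of the filter's
strength are possible a priori (amplitude $S_2$ or $\sqrt{S_2}$); only
the $\sqrt{S_2} \propto 1/f$ amplitude yields a $\beta = 2$ *power*
spectrum from white noise, so that is what the package implements.  The
filter is normalized deterministically (mean squared gain 1) so the
background RMS contrast stays at 20 %; this renormalization only rescales
both observer and IO thresholds and therefore cancels in efficiency.

# Ideal observers

## Detection

With mean-subtracted images and noise covariance $\Sigma_\beta$, the IO
is the prewhitened matched filter $w = \Sigma_\beta^{-1} s$: respond
"present" iff $w^\top g > t_{crit}$.  Stationarity makes
$\Sigma_\beta^{-1}$ diagonal in the DFT basis, so the template's
frequency weights are $\hat s(f)/S_\beta(f)$ and the detectability per
unit contrast is
$$d'/c = \bar b \sqrt{s^\top \Sigma_\beta^{-1} s}
       = \bar b \sqrt{\textstyle\frac{1}{N^2}\sum_f |\hat s(f)|^2 / S_\beta(f)}.$$
The package fixes one DFT scaling convention (documented at
`buildTemplate()`) and uses it for templates, $d'$, whitening and the
localization exponent; any global rescaling cancels in all decisions and
in efficiency.  At the unbiased midpoint criterion, proportion correct is
$\Phi(d'/2)$ — the closed form the Monte-Carlo path is tested against.

## Free localization

With a uniform prior over locations, the posterior is
$p(l \mid g) \propto \exp(s_l^\top \Sigma_\beta^{-1} g)$ (the quadratic
term is location-independent under stationarity and circular shifts).
Because any response within the acceptance radius counts as correct, the
optimal rule integrates the posterior over the acceptance disk at each
candidate location and reports the maximizing pixel.  The convolutional
implementation: correlate the prewhitened template with the
mean-subtracted image, scale by the target amplitude, exponentiate, zero
outside the search region, normalize to unit sum, convolve with the
radius-5 disk (81 integer offsets with $\|d\| \le 5$; the radius test is
inclusive), and take the argmax over the region.

Numerical choices:

* the in-region maximum of the exponent is subtracted before
  exponentiation — exact for the normalized posterior and the only thing
  preventing overflow at realistic contrasts;
* exact ties at the argmax break to the first occurrence in row-major
  (reading) order, a measure-zero event made deterministic so the
  convolutional observer and the brute-force oracle can be required to
  agree *exactly*;
* tiny negative disk-convolution values from FFT round-off are clipped
  to zero.

A brute-force oracle (`bruteForceLocalize()`) recomputes the same
decision by explicit shifted-template inner products in the whitened
domain and direct disk summation; it is $O(N^4)$ and restricted to
$N \le 64$, existing purely as an independent check.

## Detect-and-localize

Identical machinery, with a threshold on the maximum disk score: below it
the observer responds "absent".  The threshold lives on the probability
scale of the disk score, in $[0, 1]$.

# Thresholds, criterion matching, efficiency

IO thresholds come from Monte-Carlo look-up tables: proportion correct at
contrasts in steps of 0.01 from 0 until PC exceeds 0.94, with 2000 fresh
stimuli per point (binomial s.e. < 1 % near the 80 % level).  One set of
noise fields is reused across the contrast grid (common random numbers):
each point's PC stays unbiased, the sweep becomes cheap — the identity
$\mathrm{corr}(w, n + a s_{l_0}) = \mathrm{corr}(w, n) + a\,
\mathrm{shift}(\mathrm{corr}(w, s), l_0)$ lets a trial's noise
correlation be computed once — and the PC curve is smooth in contrast.
Monte-Carlo PC curves are not exactly monotone, so inversion applies
isotonic regression and then interpolates linearly between the bracketing
grid points.

Observer thresholds come from maximum-likelihood cumulative-Gaussian fits
$p(c) = \text{floor} + (1 - \text{floor})\,\Phi((c - \mu)/\sigma)$ to
binomial counts, inverted at 80 % correct.  The chance floor is *fixed*,
not fitted: 0.5 for yes-no detection and the acceptance-disk /
search-area ratio ($81/128^2 \approx 0.5\,\%$) for free localization —
the floor is too small there for fitting it to matter.

Criterion matching:

* **detection** — the two-equation Gaussian system has a closed solution:
  $z(\mathrm{hit}) - z(\mathrm{fa}) = c_{IO} \cdot (d'/c)$ fixes the
  matched contrast and the criterion reproduces the false-alarm rate.
  Equal hit and false-alarm rates are accepted as the zero-contrast
  limit ($c_{IO} = 0$); rates below the diagonal admit no valid contrast
  and are an error.
* **D&L** — for a candidate contrast, the threshold that reproduces the
  false-positive rate is the empirical quantile of the absent-trial
  maximum scores, and the correct-D&L rate is then monotone in contrast,
  so a bisection over contrast (with common random numbers across
  candidates, making the solve deterministic given the seed) matches both
  rates.

Efficiency is the squared contrast ratio in all tasks, reported as a
fraction internally and as percent in displays.  Standard errors follow
the session convention: efficiency per session, then the standard error
across sessions; synthetic runs label sessions as blocks of 50 trials
(40 blocks at the 2000-trial design).

# Classification images

The whitened noise $q = \Sigma_\beta^{-1} n$ is the common currency.  For
detection the estimator is the signed sum of outcome-class means
$\bar q_{FP} - \bar q_{TN} + \bar q_{TP} - \bar q_{FN}$ (the unweighted
four-class form, not the class-size-weighted variant).  For localization
the package uses the response-aligned false-localization estimator: on
each incorrectly localized trial the whitened noise is circularly shifted
so the chosen pixel lands on the image center, and these fields are
averaged.  On such trials the response is driven entirely by the noise at
the selected location, which is why roughly the 20 % of trials that are
errors at PC = 80 % already give a strong estimate.  Circular shifts keep
the estimator unbiased under the wrap-around generation model; whitening
must use the same spectrum (and DC rule) as generation — a mismatch is an
error, not a warning.

For display and comparison: a 4th-order radial Butterworth low-pass
(cutoff 5.6 cyc/deg = 0.29 cyc/px) smooths the spatial estimate, and
radial frequency profiles apply a 4th-order Butterworth *spatial* window
(cutoff 1.05° = 20 px; order 4, matching the display filter, a
conventional choice where the window shape matters little) before the
Fourier transform, then
average the real part in annuli one DFT step wide (bin center = mean
radius of member frequencies) and normalize the peak weight to 1.  The
imaginary part, zero in expectation for symmetric templates, is attached
as a diagnostic.  The spatial window precedes the transform; the display
smoothing is cosmetic and never enters the profiles.

The analytic reference is the IO's own frequency weighting
$f^{\beta} \exp(-2\pi^2 \sigma^2 f^2)$, whose continuous peak sits at
$\sqrt{\beta}/(2\pi\sigma)$ — from 0 (white noise) to about 1.7 cyc/deg
at $\beta = 3$ under the default geometry (the continuous formula gives
1.76; discrete radial binning on the 256-grid reads 1.72).

# The synthetic observer

`ObserverModel` is a linear-template observer with four suboptimality
dials, each motivated by a mechanism commonly invoked for human
performance:

* **template mistuning** — low-frequency suppression
  $f^2/(f^2 + f_0^2)$, peak shifting $f^{\alpha}$, or a fixed
  $\beta$-tuned template used across conditions;
* **internal noise** — white noise added to the decision statistic
  (detection) or per pixel of the response map (localization), expressed
  in units of the template statistic's noise sd so settings transfer
  across conditions;
* **criterion jitter** — trial-to-trial Gaussian noise on the criterion,
  same relative units;
* **motor jitter** — isotropic integer-rounded Gaussian displacement of
  the localization response, clipped to the search region (pixels).

The synthetic localizer takes the argmax of the raw template response
map, *omitting* the acceptance-disk integration, as a principled
suboptimality a human plausibly shares; the flag `diskIntegration = TRUE`
restores the ideal computation, and the tests verify the omission costs
less than the Monte-Carlo resolution at the package's operating points.
Synthetic responses are integer pixels (human clicks may be sub-pixel;
the record schema would accommodate them, the generators never produce
them).

For detection the model's efficiency has the exact closed form
$$\eta^* = \frac{(w^\top s)^2}
  {\left(w^\top \Sigma w + \sigma^2_{int} + \sigma^2_{jit}\right)
   \; s^\top \Sigma^{-1} s},$$
which is the ground-truth oracle the measured-efficiency pipeline is
validated against.  No closed form exists for localization efficiency of
a suboptimal localizer, so there the tests check self-consistency (IO
self-efficiency = 1) and monotone degradation with template distortion
instead.

## What the generator emulates — and what it does not

The synthetic observer reproduces the *measurable signatures* of human
suboptimality — efficiency below 1 with known value, recoverable
mistuned templates, criterion-induced losses, motor-jitter-degraded
classification images — under exactly the stimulus statistics the
decision theory assumes.  It does not emulate learning or drift across
sessions, spatial inhomogeneity of attention, oblique/surround effects,
sub-pixel motor precision, or any deviation of real noise from the
stationary Gaussian model.  Passing tests therefore certify the
*estimators* (thresholds, efficiency, classification images) under the
stated model, not claims about human vision.

# Problem sizes and reproducibility

The full design size (256 px images, 2000 trials per LUT point, step
0.01) is used by the acceptance script, which recomputes the worked
threshold example (β = 1 free localization, 80 % correct near contrast
0.4) in a few minutes of CPU time.  The test suite exercises the same
code paths at reduced sizes chosen to keep each property statistically
decisive but cheap: 32–64 px images for exact-equivalence and
closed-form checks, 128 px for classification-image recovery (2000
trials per condition), with operating contrasts near each condition's
80 % point determined once by coarse LUT inversion at those geometries.
Every stochastic routine takes an integer seed, trial seeds derive from
it arithmetically, and identical inputs yield byte-identical CSV/JSON
outputs.

# Known limitations

* The stationary, circulant noise model is exact for these synthesized
  stimuli but only an approximation for natural or medical images the
  method is often aimed at.
* The response-aligned localization estimator carries a mild bias: at
  $\beta = 0$ it overweights low frequencies slightly and at
  $\beta = 3$ its recovered peak sits below the analytic one (the
  acceptance-disk maximization blurs response alignment by a few
  pixels); the recovery bound in the tests was set by simulation with
  this bias included.
* D&L criterion matching assumes the observed rate pair is attainable by
  the IO; infeasible pairs report the feasible frontier rather than a
  forced fit.
* Efficiency above 1 can occur by Monte-Carlo fluctuation when an
  observer is near-ideal; estimates carry session-based or delta-method
  standard errors for exactly this reason.
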