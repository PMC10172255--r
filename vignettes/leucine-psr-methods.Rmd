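---
title: "Quantifying cerebral protein synthesis rate with [11C]leucine PET: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral protein synthesis rate with [11C]leucine PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leupet)
```

## The kinetic model

Carboxyl-labelled [11C]leucine is well suited to measuring cerebral protein
synthesis because its label leaves the brain almost exclusively as CO2,
which is low and near equilibrium with blood over a 60-min scan. `leupet`
implements the simplified irreversible two-tissue compartment model for its
brain kinetics: plasma free tracer $C_p$ exchanges with a tissue precursor
pool $C_f$ and is trapped into protein $C_b$,

$$\frac{dC_f}{dt} = K_1 C_p - (k_2 + k_3)\,C_f, \qquad
  \frac{dC_b}{dt} = k_3 C_f, \qquad C_T = C_f + C_b,$$

with $K_1$ (ml·ml$^{-1}$·min$^{-1}$) the blood-to-brain transport rate
across the LAT1 carrier, $k_2$ (min$^{-1}$) the efflux rate, and $k_3$
(min$^{-1}$) the rate of incorporation into protein. Recycling of label
out of protein ($k_{rec}$) is fixed at zero: labelled protein does not
release measurable tracer within 60 min.

Three derived quantities carry the physiology:

* $\lambda = k_2 / (k_2 + k_3)$ — the fraction of the tissue precursor
  pool fed from plasma rather than from proteolysis. It corrects the rate
  estimate for unlabelled leucine recycled from protein breakdown, which
  dilutes the precursor pool that the tracer reports on. $\lambda \in
  (0, 1]$ always.
* $K_{cplx} = K_1 k_3 / (k_2 + k_3)$ (min$^{-1}$) — the unidirectional
  (trapping) uptake rate of plasma leucine; $0 \le K_{cplx} \le K_1$.
* $\mathrm{PSR} = K_{cplx} \cdot [\mathrm{leu}] / \lambda$
  (nmol·ml$^{-1}$·min$^{-1}$), with $[\mathrm{leu}]$ the unlabelled
  arterial plasma leucine concentration in nmol/ml.

A useful algebraic identity follows immediately:
$\mathrm{PSR} = K_1 k_3 [\mathrm{leu}] / k_2$, i.e. PSR is exactly linear
in $k_3$. The synthetic-study generator uses this to set a target true PSR
by scaling $k_3$ (`k3_multiplier_for_psr()`).

## Exact forward solution

For a piecewise-linear input function the model has the closed form

$$C_T(t) = K_{cplx}\int_0^t C_p
  + \frac{K_1 k_2}{k_2+k_3}\int_0^t e^{-(k_2+k_3)(t-s)}\,C_p(s)\,ds ,$$

and `solve_model()` integrates each linear segment of $C_p$ analytically
rather than calling a generic ODE solver. This removes all step-size
sensitivity: the solution is exact (to floating point) for the
piecewise-linear input actually supplied, which in turn lets the test
suite use tight oracles (noiseless parameter recovery to 1e-3, closed-form
step-input checks to 1e-12). Two numerical details matter:

* the per-segment kernels $(1-e^{-b})/a$ and $(1-(1+b)e^{-b})/a^2$ are
  computed with `expm1()` and, for $b = a\,\Delta t < 10^{-4}$, a series
  expansion, so nearly-reversible kinetics do not lose precision to
  cancellation;
* the exponential recurrence across segments is evaluated as a rescaled
  cumulative sum in blocks whose exponent span is bounded, so fast
  kinetics on long segments cannot overflow.

Frame means used in fitting are also analytic: integrating the
convolution ODE once more gives the exact frame integral of $C_T$, so the
fitted model and the noiseless generator output agree to machine
precision with no fine-grid averaging step.

## Fitting

`fit_rate_constants()` minimizes the weighted residual sum of squares
between measured frame values and exact model frame means, by
Levenberg–Marquardt with box bounds ($K_1 \in [10^{-5}, 2]$, $k_2, k_3
\in [10^{-5}, 5]$), from a deterministic $3\times3\times3$ log-spaced
multistart grid strictly inside the bounds. The best final WRSS wins;
exact ties break to the smallest $K_1$. Convergence uses a relative
parameter tolerance of $10^{-8}$ with at most 500 iterations per start,
and a fit that converges from no start is returned flagged, never
silently. The reference implementation this workflow descends from does
not publish its weighting, bounds or optimizer, so all three are exposed
as explicit configuration rather than presented as "the" method.

The default weights are $w_i = \Delta t_i\,e^{-\lambda_{phys} t_i}$
(frame duration times the carbon-11 physical-decay factor at the frame
mid-time, $\lambda_{phys} = \ln 2 / 20.364$ min$^{-1}$), which
approximates the variance of uncorrected counts; uniform weighting is
selectable. An optional fractional blood-volume term $V_b\,C_{wb}$ is
available behind a flag for sensitivity analysis and is off by default
(the adopted model has none).

At very low trapping (anisomycin-suppressed $k_3$, an order of magnitude
below baseline) the per-subject estimate of $k_3$ becomes strongly
right-censored by identifiability: for some noise realizations the global
WRSS minimum genuinely sits at $k_3 \approx 0$. This is a property of
weighted least squares under the counting-noise model, not an optimizer
artefact (profiling WRSS in $k_3$ confirms the minimum), and it makes
low-PSR group means mildly left-skewed. Regularized or Bayesian variants
that would shrink this tail are deliberately out of scope.

## Patlak cross-check

For an irreversibly trapped tracer, $C_T(t)/C_p(t)$ plotted against the
normalized time $\int_0^t C_p / C_p(t)$ becomes linear with slope
$K_{cplx}$ once the free pool has equilibrated. `patlak_slope()` is kept
as a deliberately independent estimator (ordinary least squares on the
graphical coordinates; no shared code path with the compartmental fit) to
cross-check $K_{cplx}$. Both coordinates are frame-averaged to match the
frame-mean tissue data. The linear window must postdate equilibration,
which takes roughly $3/(k_2+k_3)$: the default `t_start = 20` min suits
typical rat leucine kinetics ($k_2+k_3 \approx 0.15$ min$^{-1}$), while
the validation suite uses 40 min when sweeping parameter combinations
down to $k_2+k_3 = 0.07$ min$^{-1}$, where the slope error stays ~1%.

## Blood pipeline conventions

The input function is plasma **free** (acid-soluble, not
protein-incorporated) tracer. From raw measurements the pipeline applies,
in order: decay correction of the online whole-blood detector curve to
injection (half-life 20.364 min); cross-calibration of the detector's
arbitrary gain against the gamma-counted discrete samples (mean of
sample/online ratios at the sample times); rigid delay alignment of the
online curve by matching its 10%-of-peak rise — located by inverse linear
interpolation, i.e. the threshold-crossing event an acquisition console
logs — to the recorded injection marker; conversion to plasma free
tracer by the cohort-mean plasma/whole-blood ratio and free fraction; and
resampling to the canonical analysis grid. Conventions worth making
explicit:

* **Ratios as constants.** The plasma/whole-blood ratio and free fraction
  enter as cohort averages, matching how a population protocol uses them;
  a time-varying variant (linear between the seven sample times, constant
  beyond) is available behind a flag for sensitivity checks.
* **No dispersion correction.** Only delay alignment of the shunt curve
  is applied; dispersion along the line is a documented limitation.
* **Sample exclusion is loud.** Samples with non-positive activity are
  dropped with a warning, never silently.

## Population-based input function

`build_pbif()` resamples each donor arterial input function to a
canonical grid (0.05-min spacing to 2 min, where the bolus peaks, then
0.5-min spacing to 60 min), normalizes each donor to unit 0–60 min area,
averages pointwise and renormalizes. Area normalization makes the
template invariant to donor gain and injected dose (dose-per-gram
normalization is selectable but depends on syringe-residual bookkeeping).
`scale_pbif()` multiplies the template by
$S = \mathrm{AUC}_{[10,60]}(\mathrm{IDIF} \cdot r_{p/wb} \cdot
f_{free}) / \mathrm{AUC}_{[10,60]}(\mathrm{template})$, where the IDIF is
the image-derived left-ventricle whole-blood curve. The late 10–60 min
window is used rather than peak matching because the early peak is
sensitive to left-ventricle spill-in, reconstruction and bolus shape,
whereas the late area is exactly the quantity the trapping estimate
integrates; the window is configurable.

## Image quantification

ROI curves are per-frame voxel means inside a mask; voxel units are
assumed Bq/ml with 1 cm³ ≡ 1 ml. SUV follows
$\mathrm{SUV} = \mathrm{activity}\,(\mathrm{Bq\,cm^{-3}}) \times 10^{-6}
\times \mathrm{BW(g)} / \mathrm{ID(MBq)}$, dimensionless under the
1 g ≡ 1 ml tissue convention, and SUV images are assumed decay-corrected
to injection (a flag records the assumption). Summed images integrate
frames whose mid-time falls in the window (mid-time assignment, not
overlap fractions — simple and robust to schedule changes), weighting
each frame by its duration.

## The synthetic-study generator

`cohort_spec()` + `generate_subject()` emulate a bolus-injection rat
study: a 60-min acquisition (default schedule 12×10 s, 6×30 s, 5×60 s,
10×300 s), a tri-exponential bolus input with appearance time τ = 0.25
min peaking ~0.4 min later at ~120 kBq/ml, discrete arterial samples at
2, 5, 10, 20, 30, 40 and 60 min, an online detector curve with arbitrary
gain, transport delay and 2% multiplicative noise, gamma-counting and
assay noise of 1%, an eight-analyte amino-acid panel (arterial leucine
228 ± 15 nmol/ml, the mean of the two published arterial group means;
venous offset −27%), plasma/whole-blood ratio 1.2 and free fraction 0.8,
and regional TACs with additive Gaussian noise of standard deviation
$\sigma\sqrt{C_T/\Delta t}$ (the counting-statistics shape; σ = 10 by
default, giving ~4% noise on late 5-min baseline frames; Poisson
resampling on the implied counts scale is selectable). Three default
regions span fast/slow efflux and high/low trapping at physiological
transport rates: frontoparietal cortex (0.10, 0.20, 0.05), hippocampus
(0.05, 0.10, 0.05) and thalamus (0.05, 0.05, 0.02); an anisomycin arm
multiplies $k_3$ by 0.14, i.e. ~86% PSR inhibition, inside the observed
77–89% range for that inhibitor dose. All randomness flows from one
master seed through a documented per-subject splitting scheme
(`subject seed = master·10007 + index·7919 + arm offset`, mod $2^{31}-1$),
so studies reproduce bit-identically and generation never perturbs the
caller's RNG stream.

What the generator does *not* emulate: scanner physics (scatter,
attenuation, partial volume, reconstruction correlations), dispersion of
the shunt line, metabolite kinetics in blood, or biological covariance
between rate constants and blood chemistry. Passing recovery tests on
this generator therefore demonstrates correctness of the estimation
chain under the stated statistical model, not robustness to every
real-data artefact.

The miniature dynamic phantom (`generate_phantom()`) places the
whole-blood curve in a left-ventricle block and each region's TAC in a
tissue block of a ≤32³ voxel 4D volume, so the image-quantification path
(ROI extraction, IDIF, SUV, summed images) is exercised end to end,
including through NIfTI files.

## Validation design and problem sizes

The test-suite checks are sized so the whole suite runs in minutes on one
core while keeping the Monte-Carlo error of each check well below its
tolerance: noiseless recovery and the Patlak cross-check sweep a 27-point
grid ($K_1 \in \{0.02, 0.05, 0.1\}$, $k_2 \in \{0.05, 0.1, 0.2\}$,
$k_3 \in \{0.02, 0.05, 0.1\}$); noisy parameter recovery uses 50 seeded
subjects per region (median PSR within 5% of truth) fitted against their
true input, isolating the estimator; the population-input-function
validation uses a 12-subject cohort with ±15% bolus amplitude jitter and
mild (3%) shape jitter, comparing PSR from the scaled template against
each subject's individual input; and group-mean recovery runs the full
blood-to-PSR pipeline on 20-subject cohorts whose generator truth is set
to published hippocampal group means. Group means over 20 subjects at
the strongly inhibited (low-signal) operating point carry a seed-to-seed
standard error near 5% — a consequence of the $k_3$ identifiability tail
discussed above — so recovery there is validated at the 10% level.

## Known limitations

* No dispersion correction of the online blood curve.
* Cohort-constant correction ratios by default (flag for time-varying).
* No partial-volume or spill-over correction of the left-ventricle IDIF.
* Per-subject PSR at strongly inhibited trapping is left-skewed by the
  $k_3 \ge 0$ boundary; group medians are more stable than means there.
* The inferential statistics of a study (ANOVA, mixed models) are out of
  scope by design: the package emits tidy tables for any standard
  statistics environment.
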