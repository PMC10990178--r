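---
title: "Methods: spring-mass gait variables and two-group repeated-measures comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spring-mass gait variables and two-group repeated-measures comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

Photocell systems (e.g. Optojump-type bars along a runway) measure two
quantities per step at millisecond resolution: ground contact time
$t_c$ and flight time $t_f$. Everything this package derives comes from
those two numbers plus body mass $m$, leg length $L$ and running speed
$s$.

Temporal variables are definitional:

$$\mathrm{SF} = \frac{1}{t_c + t_f}, \qquad
  t_s = 2t_f + t_c, \qquad
  \mathrm{DF} = \frac{t_c}{t_c + t_s} = \frac{t_c}{2(t_c + t_f)}.$$

The duty factor satisfies $0 < \mathrm{DF} \le 0.5$, with equality exactly
at zero flight time (the walking boundary). The identity
$\mathrm{DF} = t_c \cdot \mathrm{SF}/2$ is asserted in the test suite at
machine precision.

The spring-mass quantities use the sine-wave approximation of the stance
vertical ground reaction force: stance force is modelled as a half
sine-wave whose impulse must balance body weight over the step, giving

$$F_{max} = m g \frac{\pi}{2}\left(\frac{t_f}{t_c} + 1\right),$$

the centre-of-mass vertical excursion during stance

$$\Delta z = \frac{F_{max}\,t_c^2}{m\pi^2} - \frac{g\,t_c^2}{8},$$

the maximal leg-spring compression combining forward-geometry shortening
with $\Delta z$

$$\Delta L = L - \sqrt{L^2 - \left(\frac{s\,t_c}{2}\right)^2} + \Delta z,$$

and leg stiffness $k_{leg} = F_{max}/\Delta L$. Note that $\Delta z$ and
$\Delta L$ are mass-free after substituting $F_{max}$; mass enters only
$F_{max}$ and $k_{leg}$. The model's domain requires $s t_c / 2 < L$;
violations raise a model-domain error rather than producing complex
numbers.

### Assumptions worth stating

* The half-sine force shape is an approximation that is good for rearfoot
  and midfoot running at endurance speeds; it degrades for impulsive
  (sprint) gaits.
* Leg length is estimated as $0.53 \times$ body height unless a measured
  value is supplied (`leg_len` overrides everywhere).
* $g = 9.81\ \mathrm{m/s^2}$ by convention, configurable in
  `model_config()`.
* Internally everything is SI (s, m, N, N/m); milliseconds, centimetres
  and kN/m appear only at the I/O boundary, matching how the field reports
  these quantities.

## Trial processing

A trial is accepted when the photocell-measured speed is within ±5% of
the requested speed. The boundary is treated as *inclusive* — "within"
reads most conservatively as $\le$ — and the comparison carries a $10^{-9}$
relative guard so that decimal inputs such as 3.465 vs 3.3 m/s behave as
the arithmetic intends. Accepted trials are aggregated by the arithmetic
mean of $t_c$ and $t_f$ over the timed 20-m segment; aggregation is
permutation-invariant by construction.

Cohort assembly enforces complete cases for the repeated-measures
analysis: a participant missing any protocol speed is flagged and kept for
descriptives but excluded from the ANOVA. Duplicate participant × speed
records and unknown participant ids are data-integrity errors, not
warnings.

## The statistical workflow

For participant characteristics, each axis's two groups are compared with
a one-way ANOVA when the variable passes the normality check at
$\alpha$, and with Kruskal-Wallis (the "non-parametric ANOVA") otherwise.
Normality uses a composite-null Kolmogorov-Smirnov test: because the
normal parameters are estimated from the same sample, the plain KS null
distribution is wrong (anticonservative), so the null distribution of the
statistic is obtained by parametric bootstrap with parameters re-estimated
in every replicate — operationally the Lilliefors correction. The
bootstrap (B = 2000) runs on an internal fixed stream and restores the
caller's RNG state, so it is deterministic and seed-transparent. The plain
KS variant remains available via `stats_config(normality = "ks")`.
Homogeneity uses Levene's test (mean-centred by default; median-centred
Brown-Forsythe via config).

The central analysis is a mixed (split-plot) ANOVA: one two-level
between-subjects factor (a personality axis) crossed with the three-level
within-subjects speed factor. The implementation works on the wide
participant × speed matrix:

* the between effect is the one-way ANOVA on subject means (scaled by the
  number of within levels), which for a single between factor is the same
  under any sums-of-squares type;
* the within effects are computed from orthonormalised within-subject
  contrasts with sum-to-zero group coding, which yields Type III sums of
  squares for the speed main effect and interaction — the standard choice
  when the between factor is unbalanced (47 vs 33);
* Mauchly's test runs on the pooled within-group covariance of the
  contrast scores; when it rejects at $\alpha$, Greenhouse-Geisser
  $\varepsilon$ multiplies the within degrees of freedom. With only two
  within levels $\varepsilon \equiv 1$ and the test is vacuous, which the
  code short-circuits.

"Mauchly's correction" in common usage conflates a test with a
correction; the package reads it as *Mauchly's test gating a
Greenhouse-Geisser correction*, the standard pairing.

Post-hoc contrasts are per-speed two-sample comparisons with
pooled-variance t intervals (Welch selectable), Holm-adjusted across the
three speeds. Holm is implemented as the textbook step-down procedure with
running-maximum monotonicity and capping at 1; the unit tests check it
against an independent reference and verify order invariance.

### Effect-size conventions

Cohen's d always uses the pooled SD and no small-sample (Hedges)
correction; the one exactly recomputable reference value (−0.66 for the
thinking/feeling height cells) validates precisely this convention
(Hedges would give −0.65). Two orientations coexist in the field's
reporting and both appear here deliberately: `cohens_d()` returns
second-listed minus first-listed (the characteristics-table convention),
while `posthoc_pairwise()` reports d with the same orientation as its
$\Delta$ = first-listed minus second-listed (the results-text convention),
so a contrast row is internally consistent. Magnitudes classify as
trivial/small/moderate/large at 0.2/0.5/0.8.

## The synthetic cohort

The generator emulates the cohort the analysis was designed for: 47
"sensing" vs 33 "intuition" runners, three speeds, within-subject
correlation across speeds. Group timing means are not free parameters:
they are obtained by *inverting* the forward model against the built-in
reference group summaries (per-group, per-speed mean $F_{max}$ and
$\Delta L$) at the group-mean mass and leg length. The inverse is
closed-form in the flight-to-contact ratio and a bisection in $t_c$ on
the monotone $\Delta L(t_c)$ branch (tolerance $10^{-10}$ m; bisection
rather than Newton because convergence on the bracketed monotone branch is
guaranteed). A sanity gate requires the implied step frequency to be
within ±0.15 Hz of the reference SF cell.

Noise choices, made once:

* between-participant timing SDs 0.015 s for both $t_c$ and $t_f$ — a
  calibration (not a published value) chosen so that the derived-variable
  dispersions land near the reference SDs, which the test suite verifies;
* cross-speed correlation $\rho = 0.8$ — repeated gait measures within a
  runner are highly consistent, and the within-subject design is only
  meaningful with substantial correlation;
* step-to-step noise 0.003 s (≈ the photocell system's reported
  coefficient of variation) when emitting per-step records;
* measured trial speeds jitter around the requested speed truncated to the
  acceptance tolerance, so emitted trials are all accepted — rejection
  behaviour is tested separately with explicit fixtures;
* the other three personality axes are labelled independently of the
  timing process at the reference prevalences, encoding the null finding
  on those axes.

`null_effect = TRUE` gives both groups identical (averaged) targets and
anthropometrics: the null world used to calibrate the type-I error of the
full pipeline. `anthro_sd_scale = 0` additionally freezes anthropometrics
for degenerate-noise identity checks, because $F_{max}$ and $k_{leg}$
depend on participant mass, and the zero-noise cohort is required to sit
exactly on its generating ground truth.

### What a green test does and does not establish

The generator reproduces group means, realistic dispersions, cross-speed
correlation and the documented speed trends. It does not model
step-to-step long-range dependence, foot-strike geometry, fatigue drift
within a session, or any mechanistic link between personality labels and
mechanics — labels other than the sensing/intuition split are noise by
construction. Green statistical tests therefore establish that the
*pipeline* is calibrated (correct type-I error, correct directionality
under the stated effects), not that the scientific association itself is
reproduced from raw data, which are not public.

One known bias is documented rather than hidden: cohort-mean $k_{leg}$ is
a mean of per-participant ratios and is convex in $\Delta L$, so its
expectation sits slightly above the ratio-of-means calibration target
(visible in the intuition group at 5.0 m/s, ≈ +0.25 kN/m). The
Monte-Carlo consistency test checks cohort means against an independently
coded expectation of the generative law rather than pretending the bias
away.

A second honest limitation: with the reference-calibrated effect sizes
($d \approx 0.55$ for $\Delta L$, $\approx 0.68$ for $k_{leg}$) at
n = 47/33, joint detection of all five sensing-intuition effects at
$\alpha = 0.05$ happens in roughly three of five seeds, not ≥ 90% — the
underlying contrasts were only marginally significant once, and the
acceptance suite reports this calibration fact as a failing criterion
rather than shrinking the noise to force a pass.

## Numerical and degenerate-input choices

* $t_f = 0$ is admitted (DF = 0.5 boundary) although real runners always
  have positive flight time.
* `invert_timings()` accepts a peak-force target exactly at the
  $m g \pi/2$ floor (it maps to $t_f = 0$); targets below it are invalid.
* Zero pooled SD raises an undefined-effect error instead of returning
  ±Inf.
* The ±5% acceptance boundary is inclusive with a $10^{-9}$ relative
  floating-point guard.
* All simulation draws are redrawn (never clipped) when they violate the
  model domain; the redraw rate is reported and a rate above 1% triggers a
  configuration warning.
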