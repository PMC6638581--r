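---
title: "Assessing ultrasound image-acquisition competence from clinical measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ultrasound image-acquisition competence from clinical measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoskill)
library(dplyr)
```

## The problem

Point-of-care ultrasound measurements are strongly operator-dependent: the
same patient, imaged minutes apart by two operators, can yield systematically
different vein diameters. When an instructor and trainees acquire images of
the same patients contemporaneously — in random order, blinded readings —
the instructor's images can serve as a momentary reference standard, and the
clinical measurements themselves become the competence assessment. sonoskill
implements that assessment for four central-vein diameters used as
surrogates of central venous pressure: inferior vena cava maximum and
minimum (IVC_MAX, IVC_MIN) and right internal jugular mediolateral and
anteroposterior (RIJ_ML, RIJ_AP).

Two kinds of trainee acquisition error are distinguished:

* **systematic error** — a consistent shift (mm) of diameters measured from
  a trainee's images relative to the instructor's, pointing at a stable
  technique fault (e.g. compressing the vein with the transducer);
* **sporadic error** — excess image-to-image variability (mm²) beyond the
  instructor's, pointing at inconsistent technique.

## The model

Each blinded reading is one row of a long-format table: patient, image,
acquiring operator, diameter type, reader, repeat, value in mm. For each
diameter type a three-level Bayesian mixed-effects model is fitted to the
readings $y_{ijk}$ (reading $k$, image $j$, patient $i$):

$$y_{ijk} = \mu + \beta_{op(j)} + u_i + v_j + e_{ijk}$$

* $\mu$: instructor-adjusted mean diameter (the instructor is the
  reference: $\beta_{\text{instructor}} \equiv 0$);
* $\beta_t$: one fixed effect per trainee — the systematic acquisition
  error, directly the instructor-referenced contrast in mm (no centering of
  the trainee indicators);
* $u_i \sim N(0, \sigma_u^2)$: patient random intercepts;
* $v_j \sim N(0, \sigma_{v,op(j)}^2)$: image-level random effects with an
  **operator-specific** variance (random coefficients) — each operator's
  image variance is informed by that operator's images only. The trainee's
  $\sigma_{v,t}^2$ is the sporadic error;
* $e_{ijk} \sim N(0, \sigma_e^2)$: reading residual, common to all
  operators because readings are blinded to the acquirer.

Readers are recorded in the data but not modelled: blinded interpretation
is assumed independent of who acquired the image, and repeated readings are
treated as exchangeable. The simulator can inject a shared reader effect
(`sigma_reader`) to probe the robustness of that assumption, but the model
itself never includes one, nor an image-by-reader interaction.

### Estimation

Maximum likelihood commonly fails to converge for three-level models at
this size, so estimation is by Gibbs sampling with diffuse priors: improper
flat priors on $\mu$ and each $\beta_t$, inverse-gamma(0.001, 0.001) on
every variance component (a conventional diffuse default; both
hyperparameters are configurable). All full conditionals are conjugate. The
sampler (in C++) is partially collapsed: $(\mu, \beta)$ are drawn from
their exact generalized-least-squares posterior given only the variance
components — patient and image effects integrated out via a per-patient
Sherman–Morrison identity — then patient means, image means, and variances
follow in a fixed order. Collapsing makes the fixed effects mix essentially
independently, so the practical mixing limit is the image-level variances,
which are weakly identified when each operator contributes one image per
patient (their information comes from between-operator contrasts within
patients).

Defaults are 2 chains of 11,000 iterations, 1,000 burn-in, no thinning.
Point estimates are posterior medians (less biased than means for variance
components); intervals are type-7 quantiles (linear interpolation between
order statistics) everywhere: central two-sided for means and contrasts,
one-sided upper for variances. Convergence is monitored with split-chain
R-hat and effective sample size; a fit is flagged — an R warning plus a
`flagged` column in `$diagnostics`, never silently — when R-hat exceeds
1.05 or ESS falls below 400 for a reported quantity. With the default
chain settings the sporadic-variance components of a study-sized dataset
occasionally trip the ESS threshold; the flag is informative, not fatal,
and longer chains resolve it.

Patients and images are indexed by sorted identifier before sampling, so
row order of the input never changes a result; with a fixed seed, refits
are bit-identical.

### Verdicts

Zones are plug-in statistics of the observed instructor data (not posterior
functionals), so they stay fixed while trainee posteriors vary:

* **Equivalence zone** (systematic, mm): $\pm$ half the sample SD of
  per-patient instructor means. Per-patient averaging comes first because
  most patients contribute a single instructor image and the margin should
  reflect between-patient spread. Half an SD is the classical threshold at
  which a shift misclassifies about 1 in 15 measurements against a
  mean ± 2 SD reference range ($P(Z > 1.5) = 0.0668$,
  `reference_rule_check()`).
* **Noninferiority zone** (sporadic, mm²): $[0,\; \hat\sigma_{v,\text{instr}}^2
  + \text{margin}]$ with margin a quarter of the pooled sample variance of
  all instructor readings. The trainee's *excess* image-level variance must
  therefore stay under a quarter of the instructor's overall measurement
  variance; the zone is one-sided because a variance can only be too large.

Each trainee × diameter gets a traffic-light verdict per error type:
**green** if the 90% interval lies entirely within the zone, **red** if the
point estimate itself is outside, **yellow** otherwise. Interval endpoints
exactly on a margin count as inside: the thresholds are "less than"
criteria, ties are measure-zero, and resolving them leniently favours the
trainee. The three clauses are mutually exclusive and exhaustive whenever
the point estimate lies inside its own interval, which posterior medians
and central quantiles guarantee.

The consistency ICC,
$\sigma_u^2 / (\sigma_u^2 + \sigma_{v,\text{instr}}^2 + \sigma_e^2)$
per draw, summarises how much of the total measurement variance is
attributable to real between-patient differences when the instructor
acquires the images; "consistency" because the model has already adjusted
for trainee fixed effects.

Non-green verdicts are mapped back to a static catalogue of
instructor-observable technique deficiencies (`candidate_deficiencies()`),
keyed by error class and affected diameters — e.g. a systematic
anteroposterior error suggests transducer over-pressure or incomplete
recovery after a confirmatory compression. The lookup guides remediation;
it does not diagnose.

## The synthetic-data generator

No measurement data were published with the study design this package
implements, so the generator is a first-class module: it draws datasets
from exactly the additive-normal hierarchy above (`simulate_measurements()`),
echoes its true parameters for recovery tests, and writes the standard CSV.
`default_study_config()` encodes the study conditions:

* 21 patients; one instructor plus trainees A and B; one image per
  operator per patient per diameter, each dropped independently with
  probability 0.3 (the study retained 39 of a possible 63 IVC and 48 of 63
  RIJ images; the missingness mechanism was not reported, so dropout is
  completely at random at the image level);
* 3 blinded readers × 3 repeats = 9 readings per image;
* per-diameter means 16.2, 10.3, 14.4, 11.6 mm (the published
  instructor-adjusted means);
* variance components solved from three anchors per diameter: the
  published consistency ICCs (0.88, 0.69, 0.83, 0.63), a per-patient
  instructor-mean SD of 6 mm for IVC_MAX and RIJ_AP (the published ±3 mm
  anteroposterior equivalence margin implies SD 6; a 6 mm population SD for
  IVC maxima is also the standard figure) and 4 mm for the two
  mid-variability diameters, and an image fraction of 1/3 — i.e. one third
  of the within-patient variance sits at the image (acquisition) level, two
  thirds in reading. The split is anchored to the published width of the
  one printed trainee contrast interval (90% CI 2.3–5.4 mm for the
  anteroposterior contrast, halfwidth ≈ 1.55 mm), which a
  nearly-all-acquisition split would contradict. Reading noise this size is
  plausible for cine-loop measurements, where readers re-select the frame
  before placing calipers;
* trainee A: systematic biases −1.8 (IVC_MAX) and −3.8 mm (RIJ_AP) as
  published, −1.5 and −2.5 mm for the two unprinted diameters (chosen to
  reproduce the published "no diameter equivalent" pattern), and inflated
  image-level variances (18, 12, 4, 12 mm²) that put the IVC point
  estimates outside the noninferiority zones and the RIJ intervals (but
  not points) outside, as in the published sporadic-error pattern;
  trainee B: identical to the instructor.

Randomness is split hierarchically — one substream per (patient, diameter),
substream seeds drawn up front from the master seed — so enlarging a study
never perturbs earlier patients' draws, and missingness is applied after
all values are drawn, so changing the dropout probability only changes
which rows are kept. Readings are floored at 0.1 mm: a diameter is
physically positive, and the additive-normal tail below zero would
otherwise violate the data model's positivity invariant. The floor is
negligible for the instructor and an unbiased trainee, but for a trainee
simulated with a large downward bias on the smallest, most variable
diameter (RIJ anteroposterior, mean 11.6 mm with a heavily biased trainee
mean near 7.8 mm) it truncates an appreciable share of readings and pulls
the recovered contrast toward zero by a few tenths of a millimetre — a
distortion inherent to imposing positivity on a purely additive-normal
generator, and a reminder that real diameter distributions are
right-skewed rather than normal near zero.

What the generator does *not* emulate: multiplicative (size-dependent)
acquisition errors, correlation between the four diameters (each is
simulated and modelled independently, as in the source analysis),
respiratory-cycle dynamics, informative missingness, and reader drift.
Passing recovery and calibration tests on these simulations therefore
shows the estimator and verdict machinery are correct under the stated
model, not that the model captures every feature of real ultrasound
measurements.

## Worked example

```{r example, eval = FALSE}
cfg <- default_study_config(seed = 42)
dat <- simulate_measurements(cfg)
count_summary(dat)

assessment <- assess_acquisition(dat, n_iter = 4000, burn_in = 500,
                                 seed = 42)
assessment$verdicts
assessment$icc
autoplot(assessment, type = "systematic")
render_report(assessment) |> cat(sep = "\n")
```

The same pipeline is available from a shell via the CLI script installed at
`system.file("cli", "sonoskill.R", package = "sonoskill")` with subcommands
`simulate`, `assess`, `report`.

## Numerical choices and edge cases

* Quantiles: type 7 everywhere, stated once, used everywhere.
* Rounding of reported summary means (images per patient): one decimal,
  half away from zero.
* Degenerate inputs: header-only files, non-positive values, duplicate
  reading keys, and images spanning two patients or two acquirers are load
  or validation errors; fewer than 12 distinct patients (the minimum for
  unbiased variance estimation in this design) and empty operator-by-patient
  cells are warnings, because unbalanced data are expected and handled.
* A trainee (or the instructor) with no images for a diameter is a fit
  error naming the operator.
* With `fix_variances`, the variance updates are skipped and the
  fixed-effect draws come from the exact conjugate normal posterior — the
  hook used by the closed-form oracle tests.
* Problem sizes in the test suite are chosen to keep the full run around
  half a minute: replicate counts of 20–100 with chains of 1,200–6,000
  iterations, which the collapsed sampler's near-iid fixed-effect draws
  make sufficient.

## Known limitations

* The instructor is assumed error-free; a deficiency shared by instructor
  and trainee is invisible to the method.
* Image-level variances are weakly identified at one image per operator
  per patient; their posteriors are wide at study size, which the verdicts
  inherit (sporadic verdicts need grossly inflated variances to go red).
* The inverse-gamma(0.001, 0.001) default is conventional, not
  uninformative in any strict sense, and matters most for small variance
  components; the hyperparameters are exposed for sensitivity analysis.
* The exact prior and parameterization used by the original MLwiN analysis
  are unknown; numerical equality with the published estimates is neither
  attainable (the data were not deposited) nor claimed.
* The misclassification helper implements its explicit definition,
  $P(\text{cutoff} < X \le \text{cutoff} + \text{bias})$; for the
  published example (mean 22 mm, SD 6 mm, cutoff 20 mm, bias 1.8 mm) it
  gives 11.7%, which the source rounds to 10% by an unstated path.
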