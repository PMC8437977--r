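---
title: "Modelling pericardial effusion risk from heart dose: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pericardial effusion risk from heart dose: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcppce)
```

## The problem

Pericardial effusion (PCE) is the most frequent late cardiac toxicity of
thoracic radiotherapy. In oesophageal cancer treated with definitive
chemoradiotherapy the heart commonly sits partly inside the treated
volume, and the clinical question is how the *distribution* of dose over
the heart translates into complication risk — and in particular whether
the mean heart dose (MHD), the simplest summary a planning system
reports, predicts PCE as well as models that weight hot subvolumes
differently. The package implements that comparison for two endpoints
analysed separately: any-grade PCE (A-PCE, common, roughly 4 in 10
patients at these dose levels) and symptomatic PCE (S-PCE, CTCAE grade 3
or above, roughly 1 in 13).

## Dose representation

A DVH here is a differential histogram: uniformly spaced dose bins
(midpoint convention) carrying fractional volumes that sum to one. The
bin width defaults to 0.1 Gy, the granularity treatment planning systems
typically export. Whether exported DVH doses refer to bin edges or
midpoints is rarely documented by vendors; midpoints are the less biased
default and the reader converts cumulative input (dose at bin edges,
volume receiving at least that dose) by adjacent differencing. All
volumes are fractions of structure volume; absolute volumes are
normalised on construction, and normalisation is idempotent so re-reading
a written file is safe.

The generalised equivalent uniform dose collapses a DVH to a scalar,

$$\mathrm{gEUD} = \Big(\sum_i v_i D_i^{1/n}\Big)^{n},$$

a power mean with exponent $1/n$. Zero-dose bins are excluded from the
power sum (their contribution is zero for any $1/n > 0$), and the sum is
evaluated on the log scale so small $n$ (exponents up to 20 at the lower
bound $n = 0.05$) stays numerically stable. $n = 1$ gives the mean dose
exactly; the package relies on that identity to fit the MHD-based model
without DVHs at all.

## Dose-response models

Two forward families are supported:

* **Probit (LKB form)**: $\mathrm{NTCP} = \Phi\!\big((D - TD_{50}) /
  (m \cdot TD_{50})\big)$ with $D$ the gEUD at volume-effect exponent
  $n$. $m$ (dimensionless, typical range 0.1–1) sets the steepness;
  $TD_{50}$ (Gy) is the uniform whole-organ dose at 50% risk. The
  MHD-based model is the $n = 1$ special case.
* **Logistic**: inverse logit of an intercept plus named per-feature
  coefficients, which is the natural home for clinical covariates
  (hypertension enters the symptomatic-endpoint model this way). Odds
  ratios are `exp(coefficient)`.

Tolerance doses invert the curves in closed form:
$TD_x = TD_{50}(1 + m\,\Phi^{-1}(x))$ for the probit models and
$(\mathrm{logit}(x) - \mathrm{intercept} - \mathrm{offset}) /
\beta_{\mathrm{dose}}$ for the logistic ones. A solution at non-positive
dose means the curve never falls to that risk level on the physical dose
axis — a real feature of shallow any-grade curves, whose modelled risk at
0 Gy already exceeds 5% — and is returned as `NA`, rendered as a dash in
tables. For a multivariable logistic model the tolerance dose depends on
the covariate profile; no default profile is assumed and the caller must
supply one, because any implicit choice (all-zero covariates,
prevalence-weighted, ...) silently changes the answer. Relatedly, the
sign convention of a binary covariate is the caller's: a negative
hypertension coefficient under one coding is a positive one under the
complementary coding, and the package does not guess which was intended.

Reported tables round NTCP to 2 decimals and TD to 1, the convention of
published summaries; the underlying objects keep full precision.

## Maximum-likelihood fitting

Both fitters maximise the binomial log-likelihood
$\sum_i y_i \log p_i + (1 - y_i)\log(1 - p_i)$, with probabilities
clipped at $10^{-12}$ so extreme parameter proposals keep a finite
objective. Fits require at least one event and one non-event.

The LKB fit optimises $(n, m, TD_{50})$ — or $(m, TD_{50})$ with $n$
fixed — on the log scale, which enforces positivity without constraint
machinery. The optimiser is a coarse log-spaced grid multi-start (the
three best grid points seed independent runs) followed by projected
gradient ascent with a backtracking Armijo line search and
Barzilai–Borwein spectral step lengths; the spectral step matters because
$m$ and $TD_{50}$ are strongly correlated near the optimum and plain
fixed-step ascent crawls along the ridge. Convergence is declared when
the projected-gradient max-norm falls below $10^{-6}$ (central
differences, $h = 10^{-6}$); if the iteration budget (500 per start) is
exhausted first the best iterate is returned and flagged. Default bounds
$n \in [0.05, 2]$, $m \in [0.05, 2]$, $TD_{50} \in [5, 120]$ Gy bracket
the pericardium estimates published across the literature with a wide
margin. Because gEUD depends on the parameters only through $n$, the
per-patient gEUD vector is cached per distinct $n$ and computed for the
whole cohort at once from a stacked bin representation, which is what
makes replicate fitting affordable. Under uniform dose every $n$ yields
the same gEUD; the fit then reports a near-zero $n$-gradient rather than
failing, which is the honest description of an unidentifiable parameter.

Logistic models are fitted by iteratively reweighted least squares via
`stats::glm`; the package adds the contract: constant features are
rejected, and diverging coefficients (|log-odds| > 15 or IRLS
non-convergence) raise a perfect-separation error rather than returning
meaningless estimates. Forward stepwise selection starts from the
intercept-only model and adds, at each step, the candidate with the
largest likelihood-ratio improvement whose LRT p-value (chi-square, 1 df
per added parameter) is below 0.05 two-sided, stopping when none
qualifies; deviance ties break lexicographically so selection is
deterministic. Candidates are expected to come from the univariate screen
(single-predictor Wald p < 0.10) with collinear groups (pairwise Pearson
$R^2 > 0.70$, clustered by transitive closure) reduced to one
representative — in the pipeline, the member with the best univariate
AUC, mirroring how one representative dose metric is chosen from a block
of highly correlated cardiac dose-volume parameters.

## Validation

AUC is the Mann–Whitney statistic with midrank tie handling; its 95%
interval is a stratified bootstrap percentile interval (2000 resamples),
chosen to stay inside the same bootstrap machinery as the optimism
correction since the analytic-vs-bootstrap choice is rarely reported.
Optimism correction follows TRIPOD: refit the modelling recipe on each of
B = 1000 resamples drawn with replacement at cohort size
(unstratified), score the refit on its own resample and on the original
cohort, and subtract the mean difference from the apparent AUC.
Single-class resamples are redrawn and counted. The correction is
invariant to monotone rescaling of scores, since only ranks enter.

The Hosmer–Lemeshow statistic sums $(O - E)^2 / E$ over both outcome
cells of risk-ordered groups (default $g = 10$; identical predictions
stay together, so few distinct risk levels yield fewer groups; a group
with an empty expected cell is merged with its neighbour). The reference
distribution defaults to $\chi^2_{g-2}$, the convention when the
predictions were fitted to the same data; `df` is exposed because the
convention is not universal — published statistics are sometimes only
consistent with $df = g$ — and because the calibrated-null simulation in
the test suite, where the probabilities are known rather than estimated,
requires $df = g$ for a uniform p-value. Model-vs-model agreement is
ordinary least squares of one model's predictions on the other's with
the coefficient of determination $R^2 = 1 - \sum(y_i - f_i)^2 /
\sum(y_i - \bar y)^2$.

## The synthetic cohort generator

No patient data ship with the package; the generator reproduces the
statistical structure the analysis needs, with defaults frozen to the
cohort being emulated: 229 patients, MHD median 32.2 Gy on support
0.46–56.9 Gy, hypertension prevalence 30.1%, outcomes drawn as
independent Bernoulli events from declared truth models (defaults: the
MHD logistic model, intercept −2.513 and 0.073 per Gy, for the any-grade
endpoint; the MHD probit model $m = 0.26$, $TD_{50} = 56.5$ Gy for the
symptomatic one).

The MHD marginal is a two-component truncated log-normal mixture: a
dominant component around the median (sdlog 0.25, location solved
numerically so the mixture median equals 32.2 Gy) and a 20%
heart-sparing component (median 5 Gy, sdlog 1.0) representing tumours
high in the thorax that leave the heart largely out of field — which is
how sub-Gy mean heart doses coexist with a 32 Gy median. A single
truncated log-normal pinned at the printed median was tried first and
rejected: whatever its spread, it concentrates too much mass near the
median and over-predicts both endpoint incidences under the default
truth models, whereas the mixture reproduces median, range and both
incidences together. Hypertension is drawn independently of MHD by
default; the joint distribution in the real cohort is unknown, the
independence assumption is recorded in the cohort's attributes, and a
dependence knob exists for sensitivity analyses.

Per-patient DVHs use a logistic cumulative fall-off around the target
dose (scale 8 Gy by default, jittered ±30% across patients), truncated
at a 66 Gy prescription-level cap and rescaled on the dose axis so the
mean dose matches the drawn MHD exactly; a target that would need doses
beyond 80 Gy is a generation error. Zero heterogeneity produces
uniform-dose organs, the degenerate case in which the volume-effect
exponent is unidentifiable. What the generator does **not** emulate:
anatomical dose painting, cardiac substructure doses, longitudinal
follow-up, or any correlation between DVH shape and clinical covariates.
Passing tests therefore demonstrate that the estimators recover known
truths under plausible dose distributions — not that the published
parameter values are correct for real patients, which would require the
original DVHs.

## Problem sizes and tolerances in the test suite

Simulation sizes were chosen so each check has comfortable power while
the whole suite stays quick: parameter recovery uses 1000-patient
cohorts (50 replicates for the $TD_{50}$ bias bound of 5%, which is
several times the Monte-Carlo standard error) and 500-patient DVH
cohorts for the free-$n$ fit; the optimiser is audited against a dense
21×21×24 parameter grid (no grid point may beat it by more than 0.01
nats); AUC is checked exactly against pair counting on cohorts of up to
50 patients; optimism behaviour uses the classic overfitting design
(9 noise features on 60 patients) against a well-specified
single-predictor model at 1000; calibration uniformity uses 200
replicates of a known-probability null. The end-to-end pipeline runs the
full 229-patient configuration with B = 200 bootstrap resamples.

## Known limitations

* No fractionation correction (EQD2/BED): the emulated cohort is
  conventionally fractionated and none is applied.
* LKB parameter uncertainty (profile-likelihood or bootstrap CIs for
  $n$, $m$, $TD_{50}$) is not computed.
* The DICOM-RT pathway is out of scope; dose input is the DVH
  interchange CSV.
* The generator's independence assumptions above; endpoints are drawn
  independently unless the subset mode is enabled.
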