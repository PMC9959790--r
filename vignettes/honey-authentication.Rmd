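---
title: "Quantitative NMR honey profiling and origin discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative NMR honey profiling and origin discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeynmr)
```

`honeynmr` turns processed 1D ¹H NMR spectra of dissolved honey into a
33-component concentration table and discriminates a binary geographic
origin class from it. This vignette is the package's account of the
science: the models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## 1. The quantitation model

NMR is uniformly molar: the integrated area of a resonance is
proportional to the molar concentration of the species times the number
of protons producing it, with one proportionality constant for the whole
spectrum. With TMSP (sodium trimethylsilylpropionate-d4, nine equivalent
methyl protons at 0.0 ppm) present at a known concentration
$C_{\mathrm{TMSP}}$, the concentration of analyte $a$ follows from a
ratio of proton-normalised areas:

$$
C_a \;=\; \frac{A_a / N_a}{A_{\mathrm{TMSP}} / 9}\; C_{\mathrm{TMSP}}\; s_a ,
$$

where $A_a$ is the summed point intensity over the analyte's integration
region(s), $N_a$ the effective proton count of those regions, and $s_a$
a back-calculation factor for analytes quantified from only part of
their molecular population.

Three features deserve comment.

* **Integration is a plain inclusive point sum.** `integrate_region()`
  sums intensities at grid points with
  $\mathrm{ppm}_{\min} \le \delta \le \mathrm{ppm}_{\max}$, endpoints
  inclusive. No baseline fitting and no deconvolution are applied — the
  input is assumed to be a fully processed absorption spectrum (phased,
  baseline-corrected). Endpoint inclusion matters at coarse digital
  resolution and is therefore documented and tested.

* **Anomeric back-calculation.** Reducing sugars equilibrate between α
  and β anomers; when only the H-1α resonance is clean enough to
  integrate (the minor sugars, 5.15–5.55 ppm), the region represents only
  the α fraction and $s_a = 1/f_\alpha > 1$ recovers the total. The α/β
  ratios shipped with the default panel are synthetic placeholders (see
  §5); sucrose (non-reducing) and trehalose (symmetric) need no
  correction.

* **Fructose tautomer summation.** Solution fructose distributes over
  β-pyranose (68.2 %), β-furanose (22.3 %), α-furanose (6.3 %) and
  α-pyranose + open keto (≈3.2 %). The three integrated regions
  (4.098–4.130, 4.013–4.050, 3.985–4.013 ppm) collect different protons
  of different tautomers, so their proton-equivalent weights are
  fraction-weighted sums: $2f_{\beta f}+f_{\alpha f} = 0.509$,
  $2f_{\beta p} = 1.364$ and $f_{\beta p}+f_{\alpha f} = 0.745$,
  totalling $N_{\mathrm{fru}} = 2.618$. A nominal description of the
  same regions as "counting for 2 protons" is arithmetically
  inconsistent with the tautomer assignments; the package derives
  $N_{\mathrm{fru}}$ from the panel's fractions by default and offers
  `default_panel(fructose_protons = "nominal")` to force 2.0, keeping
  any downstream analysis self-consistent either way.

Units: molar concentrations convert to mass fractions through the sample
preparation, $\mathrm{mg/kg} = C\,[\mathrm{mM}] \times M\,[\mathrm{g/mol}]
\times V\,[\mathrm{mL}] / (m\,[\mathrm{mg}]\times 10^{-3})$ — a factor
of $20 M$ at the default 50 mg in 1 mL — and g/100 g is mg/kg divided by
$10^4$ (used for glucose and fructose only). The default
$C_{\mathrm{TMSP}} = 0.966$ mM is the externally verified mean of the
preparation; the nominal 1.00 mM is available via
`default_panel(is_concentration_mM = 1.00)`.

**Limits of quantification.** The molar LOQ is anchored to a one-proton
singlet at signal-to-noise 10:1 (0.01 mM on a 700 MHz cryoprobe
instrument), worsened by signal multiplicity and improved by the number
of protons in the region, then converted to mg/kg (`loq_mgkg()`).
Multiplicity penalties in the shipped panel are coarse synthetic
defaults (1 for singlets, the line count for simple multiplets); the
proline value is pinned at 230 mg/kg. LOQ flags annotate rather than
censor: flagged values stay in the concentration matrix.

## 2. The synthetic-data generator

The survey data behind this methodology (424 honey samples) are not
publicly deposited, so the package ships a generator with two parts.

**Mixture spectra** (`simulate_spectrum()`): one Lorentzian singlet per
integration region, centred in the region, with the line's summed
in-region intensity calibrated to $C_a N_a / s_a \times K$ for a single
global constant $K$ shared with the TMSP peak. Defaults: 1.0 Hz
linewidth at 700.15 MHz, $2^{15}$ points over −0.5…9.5 ppm, optional
Gaussian noise expressed as a fraction of the TMSP apex, optional
polynomial baseline, optional rigid mis-referencing for testing
`reference_spectrum()`.

Two numerical choices matter:

* *Tail truncation.* Each line's support is limited to ±0.05 ppm around
  its centre (`tail_limit_ppm`). Pure Lorentzian tails fall off only
  quadratically, so the ~100 mM sugar resonances would otherwise leak
  percent-level area into trace-analyte regions several tenths of a ppm
  away — a long-range baseline contribution that real processing removes
  with regional polynomial baseline correction before integration. The
  simulator emits spectra as they look *after* that correction; setting
  `tail_limit_ppm = Inf` restores pure Lorentzians if the user wants to
  study the leakage itself.
* *Union calibration for multi-region analytes.* The three fructose
  regions share an edge, so their lines cross-spill; the combined
  profile is rescaled so the union of the analyte's regions carries
  exactly the target total area, which is the quantity quantitation
  sums.

With these choices the noiseless round trip (simulate → quantify) closes
to machine precision for all 33 analytes, so the 0.5 % acceptance margin
is spent entirely on genuine perturbations (noise, mis-referencing), not
on simulator artefacts.

**Concentration cohorts** (`simulate_cohort()`): a 424 × 33 matrix with
105 positive (single-origin, "Canadian") and 319 negative samples by
default. Per-analyte values are lognormal (honey analytes are positive
and right-skewed; a truncated-normal alternative exists for sensitivity
checks), with arithmetic means following a built-in effect table and an
optional Gaussian-copula correlation structure. The effect table is a
set of *synthetic design constants*, not measurements; it encodes the
qualitative marker structure reported for Canadian honey:

* trigonelline: positive-class mean 4.4× the negative (35.2 vs 8 mg/kg),
  dispersed so that ~95 % of positive samples exceed 20 mg/kg;
* proline elevated (1.8×, 504 vs 280 mg/kg);
* ethanol at 0.25×, and succinate, MGDH, MGMH, leptosperin, HPLA,
  1,3-butanediol, lactate, alanine and phenylalanine all below 0.5×;
* bulk sugars nearly class-neutral (folds 0.85–1.04) so that, as in real
  honey, the dominant variance direction is composition, not origin;
* trehalose and isoleucine exactly class-neutral, giving the volcano
  plot its expected pair of non-significant metabolites.

Two deliberate design features: the positive class receives 0.7× the
negative pool's coefficients of variation (a single geographic origin is
more compositionally homogeneous than a pool of ~50 countries — the
feature that makes one-class modelling of it sensible at all), and the
three intended markers (trigonelline, proline, ethanol) carry markedly
better signal-to-noise than the remaining class-different analytes, so
that variable selection has a well-defined planted answer.

What the generator does **not** emulate: analyte–analyte correlations
(default correlation is identity), floral substructure, replicate
acquisition noise within the cohort, instrument drift, and any real
concentration scales beyond plausible orders of magnitude. Passing tests
on this cohort therefore demonstrate correctness and qualitative
behaviour of the algorithms, not expected performance on real survey
data.

## 3. Chemometrics

**Scaling.** All multivariate methods divide columns by their $(n-1)$
standard deviations. PCA defaults to *uncentred* sd-scaling: on
all-positive concentration data the first component then absorbs the
common compositional offset, which reproduces the characteristic pattern
of honey data where PC1 explains >90 % of total sum of squares while
carrying no class information. PLS-DA and SIMCA default to full
autoscaling (centre + scale), the standard practice for discriminant
models. Both choices are arguments, never hidden.

**PLS-DA** (`pls_da()`). Single-response PLS by NIPALS; with one
response the weight update is closed-form ($w \propto X^\top y$ of the
deflated data), so the fit is deterministic — no random initialisation.
Scores, loadings and the regression vector for every component count are
stored, so `predict(fit, X, ncomp = a)` is cheap for all $a$. At full
rank the fit equals ordinary least squares, which the tests exploit as
an oracle. Classification thresholds the continuous estimate at 0.4
(ties called positive — documented and immaterial for continuous
estimates); 0.4 rather than 0.5 reflects the imbalanced positive class
pulling fitted positives below 1.

**Cross-validation** (`cv_pls()`). Contiguous blocks in stored row
order (seven by default; sizes differ by at most one, larger blocks
first). RMSECV per component count pools the held-out squared errors;
the chosen size is the argmin, smallest count on ties (parsimony). Q²
is $1-\mathrm{PRESS}/\mathrm{TSS}$ with TSS about the training mean of
$y$. Because block membership follows row order, shuffling rows is the
caller's decision — the acceptance analyses draw random train/validation
splits first, which also randomises blocks.

**SIMCA** (`simca()`). Class-local autoscaling, PCA of the class,
and two statistics per sample: leverage
$h_i = 1/n + \sum_k t_{ik}^2/(t_k^\top t_k)$ in the retained score
space, and the orthogonal residual $Q_i$. Critical limits: leverage from
the prediction-form F limit on $(k,\,n-k)$ degrees of freedom, $Q$ from
the Jackson–Mudholkar approximation on the discarded eigenvalues. The
acceptance region is rectangular (both limits must pass); since the two
statistics are independent for Gaussian data, each limit is taken at the
Šidák-adjusted level $1-(1-\alpha)^{1/2}$ so the *joint* in-class
acceptance is $\approx 1-\alpha$ (95 % by default) — Monte-Carlo
verified in the tests. A combined elliptical rule
$\sqrt{(Q/Q_c)^2+(h/h_c)^2} \le 1$ is available via `limit_rule`.

Component count: `simca_cv_press()` uses *element-wise* PRESS — each
variable of a held-out sample is predicted from its other variables
through the training loadings. A naive projection residual decreases
monotonically in $k$ by construction and cannot locate an optimum;
element-wise PRESS turns back up when components begin fitting noise and
recovers planted ranks exactly in the tests. When an out-of-class set is
supplied, the alternative criterion maximising the geometric mean of
cross-validated sensitivity and specificity is reported alongside.

On strongly skewed (lognormal) classes the Gaussian-theory limits
under-cover somewhat — heavy upper tails inflate $Q$ beyond the
Jackson–Mudholkar quantile. This is a faithful property of the method,
not a defect of the implementation; the coverage guarantee is exact in
the Gaussian Monte-Carlo check and approximate on the synthetic cohort.

**Replacement method** (`rm_select()`). Local search for the
$d$-variable subset minimising RMSECV: from a random start subset, each
slot in turn is offered every non-member and the best strictly-improving
swap is kept; sweeps repeat until stable. A $d$-variable model admits
$d$ paths (sweep orders rotated by starting slot) and the search runs
from several random starts; the best subset across paths and starts
wins. Tie-breaking is deterministic: incumbents are retained on equal
error, equally good challengers resolve to the lowest column index, and
equal-error final subsets resolve lexicographically. The
latent-variable count is re-selected per candidate subset (capped at
$d$) — a three-variable model cannot meaningfully use five latent
variables. Subset evaluations are memoised within a call.
`exhaustive_select()` enumerates all $\binom{p}{d}$ subsets under a
10 000-evaluation budget and serves as the global-optimum oracle; on 50
planted-signal instances ($p=12$, $d=3$, $n=100$) the local search
matches it in all instances in the shipped acceptance run.

**Reporting.** `volcano()` pairs per-analyte fold change
(positive/negative mean ratio) with a two-sample t-test — Welch's
unequal-variance form by default (the safer choice when class
dispersions differ, as they do here by design), pooled Student and
Benjamini–Hochberg adjustment by flag; the significance flag uses raw
$p<0.05$ and the extreme-fold flag uses $f<0.5$ or $f>2$, both
exclusive at the boundary. `repeat_split_frequency()` repeats the
PLS-DA pipeline over seeded random 300/124 splits and counts per-sample
false-positive/negative calls, separately for training and held-out
appearances, since the two are not equivalent evidence of atypicality.
`export_report()` writes all tables as TSV with a seed and configuration
hash for byte-identical regeneration.

## 4. Problem sizes used for verification

The shipped test and acceptance runs use desk-scale sizes chosen to
exercise every code path at comfortable margins: round trips on single
spectra of all 33 analytes; PLS/CV oracles at $n=30$, $p=5$; 50
replacement-method instances at $p=12$; SIMCA coverage on 5 000
Gaussian draws against a 400-sample training class; volcano calibration
on three pooled null cohorts of 1 000 analytes; and ten 300/124 splits
of the default 424-sample cohort for the end-to-end analogue. The
Welch-calibration check uses Gaussian analytes deliberately: on skewed
small-sample data the t-test is conservative, and a calibration check
should test the implementation, not the data's skewness. Replacement
runs in these analyses use two random starts; the planted signal is
strong enough that additional starts change nothing (the function's
default remains ten).

## 5. Placeholder constants and limitations

* The exact integration limits, anomeric ratios and multiplicity
  penalties for most analytes are not public; the shipped panel encodes
  the documented regions verbatim (minor-sugar anomeric window, glucose
  H-4 at 3.41 ppm, the fructose triplet, TMSP) and clearly labelled
  synthetic placeholders elsewhere, spaced so that regions are mutually
  clean under the simulator's lineshape. Every value is user-overridable
  through `analyte_panel()` / `load_panel()`.
* The cohort effect table is synthetic; no number derived from it should
  be read as a property of real honey beyond the encoded qualitative
  structure.
* Quantitation assumes clean, fully processed spectra: overlapping
  resonances, imperfect phasing or residual baseline are not corrected
  (deconvolution is explicitly out of scope).
* SIMCA critical limits are Gaussian-theory approximations; on heavily
  skewed classes the realised in-class acceptance falls below nominal.
* The replacement method is a local search; optimality is guaranteed
  only against the exhaustive oracle on small problems, and the
  multi-start default is the safeguard on larger ones.
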