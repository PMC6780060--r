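---
title: "Methods: targeted SRM quantitation, validation and cohort association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted SRM quantitation, validation and cohort association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmquant)
```

## Scope and data model

`srmquant` implements the computational chain of a targeted UHPLC-MS/MS
(selected reaction monitoring) metabolite-panel assay, from picked peak
areas to clinical association results:

1. **Panel registry** — analytes, their quantifier/qualifier ion
   transitions, internal-standard (ISTD) pairings, and co-quantified
   groups of chromatographically unresolved isomers.
2. **ISTD normalization** — peak-area ratios against the matched
   stable-isotope-labelled standard.
3. **1/x-weighted calibration** — per-entity weighted linear regression,
   limit of detection (LOD), and the validated linear range
   (LLOQ--ULOQ).
4. **Repeatability validation** — intra- and inter-day %RSD at three QC
   concentrations.
5. **Confound-minimizing subsampling** — stratified random search for a
   balanced case/control subset of a cohort.
6. **Association analysis** — per-metabolite linear mixed models over
   technical replicates with Benjamini--Hochberg FDR control and a
   bipartite network of the significant coefficients.

The package consumes long-format peak tables (the output stage of
upstream peak-picking tools such as Skyline), a sample-metadata table,
and a per-participant clinical table. Because no public dataset
accompanies this kind of assay, a first-class synthetic-data module
generates all inputs with known ground truth; every downstream stage is
tested against that truth.

The shipped panel fixture (`load_panel("diabetes_t1d_34")`) encodes a
34-analyte plasma panel spanning amino acids and related metabolites,
bile acids, small organic acids and other polar metabolites, with 33
ISTDs. Four analyte pairs that co-elute with indistinguishable MS/MS
spectra (Leu+Ile, ADMA+SDMA, GCDCA+GDCA, TDCA+TCDCA) are represented as
merged *quantification entities* — one concentration, one shared ISTD —
giving 30 entities. Three analytes (creatinine, gamma-butyrobetaine and
3-hydroxybutyrate) are quantified on raw peak area because their ISTD
signal is not repeatable; the package tags them `normalized = FALSE`
everywhere. The two 2-hydroxybutyrate enantiomers are not in the default
fixture: they support only a three-point curve at the standard
concentration range, which the package handles through the explicit
`min_points` override rather than a fixture entry.

## The response and noise model

The generator maps a true concentration $c$ to a peak area as

$$A = R \, c \,(1 + \varepsilon_p) + \varepsilon_b, \qquad
  \varepsilon_p \sim N(0, \mathrm{CV}_p^2),\;
  \varepsilon_b \sim N(0, \sigma_b^2),$$

the simplest model that produces both of the phenomena the analysis
pipeline is built around: proportional (heteroscedastic) noise, which
motivates $1/x$ regression weights, and an additive baseline floor,
which creates finite signal-to-noise values and hence finite LODs
($S/N = A/\sigma_b$). Negative simulated areas are clamped to zero
(areas are physical quantities; the clamp introduces a slight bias only
far below the LOD, where values are censored anyway). Defaults:
$R = 50$ area units per ng/mL, $\mathrm{CV}_p = 5\%$, $\sigma_b = 200$
area units, ISTD CV 3%. With these defaults the LOD falls at
$\approx 12$ ng/mL, inside the 2.5--75,000 ng/mL standard series, so the
boundary behaviours (below-lowest flags, below-LOD censoring) are all
exercised. An *unstable* ISTD is modelled as an inflated ISTD CV
($\geq 25\%$); in the clinical fixture the three affected analytes
simply carry no ISTD pairing, which is how the assay itself treats them.

Calibration standards are generated as two full series, one at the
start and one at the end of the injection sequence. QC repeatability
data follow the validation design: four consecutive runs on one day
(intra-day) and three runs on each of five consecutive days (inter-day,
$N = 15$). A per-day multiplicative shift (default CV 8%) is applied to
the **analyte channel only**: day-to-day variation that also scaled the
ISTD would cancel in the area ratio, and the empirical observation the
generator emulates is precisely that inter-day %RSD of *normalized*
ratios exceeds intra-day %RSD.

What the generator does **not** emulate: retention-time drift and
carry-over, between-batch effects, matrix effects, non-Gaussian noise,
and correlated metabolite panels. Passing tests therefore demonstrate
the correctness of the computations under the stated noise model, not
robustness to every artefact of real instrument data.

## Calibration, LOD and the linear range

The calibration fit is ordinary weighted least squares of response on
nominal concentration with weights $1/x$ — the exact solution of the
two-parameter weighted normal equations — requiring at least five
distinct levels unless `min_points` is explicitly lowered (short curves
are legitimate for analytes with high LODs). The two series are pooled
into a single fit by default; a coefficient-averaging alternative
(`combine_series = "average"`) exists because the field does both and
the choice is rarely documented. $R^2$ is the weighted coefficient of
determination.

The **LOD** is the lowest standard level whose *median* S/N across the
replicate series reaches 3. The median was chosen over the mean for
robustness to a single aberrant injection; with only two series per
level the two choices rarely differ. When the lowest measured level
already qualifies, the LOD is reported as `"< 2.5"`-style (below the
lowest standard) rather than extrapolated.

The **linear range** is defined by back-calculated accuracy, not by
residual diagnostics: among all contiguous runs of at least
`min_points` levels, a run qualifies if every level's mean response,
back-calculated through a fit restricted to that run, lands within
80--120% of nominal. The largest qualifying run wins; ties prefer the
wider concentration span, then the lower starting level, making the
result deterministic. The selection is an exhaustive scan over all
contiguous runs — at 19 levels that is at most 120 candidate fits, so
there is no reason to approximate — and the test suite checks it
against an independently coded scan.

Back-calculation inverts the line, $\hat c = (r - b)/m$, and flags each
injection: `below_lod` (concentration censored to `NA`), `below_lloq`
(value reported but outside the validated range — downstream detection
filtering needs the information that the analyte *was* seen),
`ok`, or `above_uloq`. Two rules censor to `below_lod`: a negative
back-calculation, and an injection whose own S/N is below the LOD
threshold — the same S/N ≥ 3 rule that defines the LOD on standards,
applied per study injection. Technical replicates are quantified
independently; no averaging happens before the mixed model, which
consumes replicate-level data.

## Repeatability metrics

%RSD is $100\,s/\bar x$ with the sample ($n-1$) standard deviation —
appropriate at QC sample sizes of 4 and 15. The intra-day statistic
pools the four consecutive runs; the inter-day statistic pools all 15
runs rather than averaging daily means (the pooled $N$ is what
validation reports conventionally quote). The response metric is the
ISTD-normalized ratio where an ISTD exists and the raw area otherwise;
retention-time %RSD always comes from the analyte channel. Entities
missing a QC level are omitted from the report with a warning — never
silently.

## Balanced subsample selection

Given a cohort with a binary outcome group and a list of potential
confounders, the selector draws `n_draws` stratified subsamples
(`k_per_group` per group, uniform without replacement within group,
duplicates not deduplicated), computes for each the Pearson correlation
of every screened covariate with the 0/1 group indicator, and keeps the
draw whose **maximum absolute correlation** is smallest. Binary
covariates are encoded 0/1 first, making their score a point-biserial
coefficient — the natural reading when medication and smoking variables
are correlated against a group variable. A covariate with zero variance
inside a draw cannot confound that comparison; it scores $r = 0$ with a
degeneracy flag. Ties break by draw order, and the draw stream is
seeded, so for a fixed seed the result over a larger budget is never
worse than over a smaller one. The default budget is $10^6$ draws, the
scale used to select 25+25 participants from a several-hundred-person
cohort; the scorer is vectorised over chunks of draws so that budget
completes in minutes. Exhaustive enumeration on small cohorts verifies
that a seeded 1000-draw search finds the global optimum on
16-subsample problems.

## Mixed-effects association and FDR control

For each metabolite passing the detection filter — retained only when
detected (any replicate injection not `below_lod`) in *strictly more
than* 70% of samples — the package fits

$$\log_{10} c_{ij} = \beta_0 + \mathbf{x}_i^\top \boldsymbol\beta
  + u_i + \epsilon_{ij}, \qquad u_i \sim N(0, \sigma_u^2),$$

a linear mixed model with a random intercept per participant $i$
capturing the correlation among that participant's technical replicate
injections $j$, fitted by REML (`lme4`/`lmerTest`), with Satterthwaite
degrees of freedom for the per-coefficient two-sided tests. The default
fixed effects are the clinical variables of the kidney-disease study:
albuminuria group, age, BMI, eGFR, HbA1c, sex, systolic blood pressure,
total cholesterol and total triglycerides; smoking, statin and
antihypertensive medication can be added as extra terms. The response
is $\log_{10}$ concentration by default (concentration distributions
are right-skewed and effect strengths are conventionally displayed on a
log10 scale); a raw-scale option exists. Empirical-Bayes variance
moderation (as in `limma`) is deliberately **not** reproduced: with
technical triplicates the participant random intercept is the essential
structure, and moderated statistics would change the per-metabolite
p-values in ways that are hard to audit against an oracle.

`below_lloq` values enter the model as reported; `below_lod` rows are
excluded row-wise; no imputation. Rank-deficient fixed-effect designs
raise an error naming the aliased columns; non-converged fits are
flagged and excluded from the adjustment universe. Benjamini--Hochberg
correction is applied **within each fixed-effect term across
metabolites** (the families a reader of the results table actually
scans), and the number of metabolites in the adjustment universe is
recorded on the result object. Significant associations become edges of
a bipartite clinical-variable/metabolite network with sign, log10
coefficient strength, a positive width scale, and highlighting of the
two kidney-disease variables (group and eGFR).

### Operating characteristics at the study design size

The test suite measures the stage's error control by simulation at the
study's design size (20 metabolites, 25+25 participants, 3 replicates):
across 200 null cohorts the mean fraction of group-term discoveries is
about 0.4%, comfortably below the nominal 5%. Power, with effects of
one between-participant SD planted on 5 of 20 metabolites, averages
about 72% across 100 simulated cohorts. An analytic calculation
reproduces that figure: the group-contrast SE of
$\sigma\sqrt{2/25}$, inflated by $\sqrt{\mathrm{VIF}} \approx 1.1$ from
adjusting nine covariates in $n = 50$, gives a noncentrality of about
3.2, and at the BH-effective per-test threshold ($\approx 0.0125$ when
roughly 5 of 20 tests are true) the power of a $t_{40}$ test is 0.72.
Detecting such effects at higher rates under FDR control requires
either larger effects or more participants; this is a property of the
design, not of the implementation.

## Numerical and degenerate-input choices

* All randomness in a pipeline run flows from one master seed through a
  deterministic splitting scheme (`seed`, stage tag) → stage seed, so
  end-to-end outputs are byte-identical under a repeated seed.
* The weighted $R^2$ is computed directly from weighted sums of squares
  rather than via `summary.lm`, which warns on exact fits; a perfect
  line reports $R^2 = 1$ exactly.
* `%RSD` refuses fewer than two finite values or a zero mean; the
  linear-range search raises a typed error when no contiguous run
  qualifies; calibration with a non-positive slope refuses to
  back-calculate.
* Zero or missing ISTD peaks yield per-row error records that
  propagate to the caller (`status` column, `errors` attribute) rather
  than silent drops; the command-line `quantify` stage turns them into
  a non-zero exit naming the affected entity.
* Simulation problem sizes in the test suite are chosen to exercise
  each property at the smallest scale that is statistically
  informative: 200 replicates for the null error-control check, 100
  seeds for power, 1000-draw budgets on exhaustively enumerable
  subsampling problems, and $10^3$--$10^4$ random instances for the
  algebraic oracles.

## Known limitations

* Calibration is strictly linear; quadratic or 4PL curves, drift
  correction and carry-over detection are out of scope.
* Qualifier-transition agreement is carried in the panel model but no
  qualifier/quantifier ratio filter is applied during quantitation.
* The subsample selector optimizes the maximum absolute correlation
  only; it is not an optimal-matching or propensity-score method.
* The association stage assumes participant-level covariates;
  time-varying covariates have no representation.
* Synthetic cohort covariate distributions are documented placeholders
  (e.g. age $\sim N(55, 10^2)$, binary covariates Bernoulli(0.5)), not
  estimates of any real cohort.
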