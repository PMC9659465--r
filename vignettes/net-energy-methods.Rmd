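---
title: "Net energy determination for broiler feed ingredients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net energy determination for broiler feed ingredients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilerNE)
```

## The problem

Poultry diets are usually formulated on metabolizable energy (ME), but ME
ignores the heat increment — the heat an animal produces while digesting and
metabolizing feed — and therefore overstates the energy actually available
for maintenance and growth. The net energy (NE) system subtracts that heat
cost. `broilerNE` implements the complete measurement chain by which NE
values of single feed ingredients are determined in young broilers:

1. **Total-collection metabolizability.** Cages of birds are fed a diet for
   a short balance window and their excreta collected quantitatively. The
   apparent metabolizable energy of the diet is the gross-energy difference
   between feed and excreta per kg of dry matter (DM) intake, and AMEn
   corrects it to zero nitrogen retention.
2. **Indirect calorimetry.** Parallel groups of birds on the same diets sit
   in open-circuit respiration chambers. Total heat production (THP)
   follows from O2 consumption and CO2 production through fixed thermal
   equivalents; subtracting an allometric fasting heat production (FHP)
   gives the heat increment (HI), and NE intake is AME intake minus HI.
3. **Substitution method.** Single ingredients cannot be fed alone, so each
   test diet replaces a fixed share of a reference diet with the test
   ingredient, and the ingredient's energy values are recovered by linear
   decomposition.
4. **Prediction equations.** Measured NE values across ingredient samples
   are regressed, by bidirectional stepwise selection, on proximate
   composition and ME values, yielding equations a formulator can apply
   without running a calorimetry trial.

The package ships the tables of a 5-wheat / 5-wheat-bran broiler trial as
plain-text fixtures (`study_*()` accessors) and a synthetic trial generator
with known ground truth, so every stage is testable end to end.

## Energy-balance model

All flows are expressed per kg metabolic body weight per day, with
metabolic body weight defined as $(\mathrm{ABW}/1000)^{0.70}$ for an
average body weight ABW in grams. For a replicate on a diet with assayed
gross energy $GE$ (MJ/kg DM):

$$\mathrm{AME} = GE - GE_{excreta}\cdot\frac{m_{excreta}}{m_{feed}}, \qquad
\mathrm{AMEn} = \mathrm{AME} - 34.39\,\mathrm{kJ/g}\cdot \mathrm{TNR}_{kg}$$

where $\mathrm{TNR}_{kg}$ is nitrogen retained per kg DM feed. From gas
exchange,

$$\mathrm{THP\,[kJ]} = 16.1753\cdot V_{O_2}\,[\mathrm{L}] + 5.0208\cdot
V_{CO_2}\,[\mathrm{L}], \qquad \mathrm{RQ} = V_{CO_2}/V_{O_2}$$

and the partition is

$$\mathrm{HI} = \mathrm{THP} - \mathrm{FHP}, \quad
\mathrm{NEI} = \mathrm{AMEI} - \mathrm{HI}, \quad
\mathrm{RE} = \mathrm{AMEI} - \mathrm{THP},$$

with RE split into protein retention
($\mathrm{TNR}\times 6.25 \times 23.85\ \mathrm{kJ/g}$) and fat retention
(the remainder). Two conventions deserve comment, because the printed forms
of such equations are often dimensionally loose:

* The gas-exchange coefficients are applied as **kJ per liter** and the
  chamber totals divided by bird-days before scaling by metabolic weight.
  This is the only reading that lands THP in the observed
  0.9–1.1 MJ/kg^0.70^/d range for 400-g broilers; treating the
  coefficients as MJ-scale would be off by three orders of magnitude.
* The protein energy equivalent of 5.7 is taken as **kcal per g protein**
  and converted to 23.85 kJ/g. Both constants are fields of
  `energy_constants()` and can be overridden.

FHP is 450 kJ/kg^0.70^/d, i.e. exactly 0.450 MJ in the reported unit, so
HI = THP − 0.450 row by row; this identity reproduces the packaged trial
summaries to the printed 0.01. Diet NE scales the diet's AME by the
fraction of AME intake that survives as NE intake:
$\mathrm{NE} = \mathrm{AME}\cdot \mathrm{NEI}/\mathrm{AMEI}$, which
degenerates to NE = AME when HI = 0, as it must.

Chamber birds have no excreta collection, so their AME, AMEn and nitrogen
retention are taken from the **paired total-collection cages of the same
run and diet**. The source data do not state how this pairing was done; we
chose run-and-diet means as the least-variance defensible rule, and it is
the generator's rule too, so the choice is internally consistent and
testable.

Negative heat increments or retained energies are reported and flagged,
never clipped: a THP below FHP usually flags an FHP overestimate for that
group, which the analyst should see.

## Substitution method

With $a$ the percent of test-diet DM contributed by the reference diet's
energy-yielding ingredients and $b$ the percent contributed by the test
ingredient,

$$E_{ingredient} = \frac{E_{test} - E_{ref}\cdot a/100}{b/100}$$

for each of AME, AMEn and NE. This is the exact inverse of the mixing rule
$E_{test} = E_{ref}\, a/100 + E_{ingredient}\, b/100$, a property the test
suite checks to machine precision. The packaged trial's constants are
$a = 67.58$, $b = 31.32$ (DM basis) and are the defaults of
`substitution_scheme()`. `substitution_levels()` recomputes the shares
from the air-dry formulation and ingredient DM contents; because the DM of
the minor ingredients (amino acids, minerals, premix) was not assayed, the
recomputation uses nominal handbook DM values and lands near, but not
exactly on, the trial constants (a ≈ 66.4, b ≈ 30.1 with the packaged
nominal values). The printed constants therefore stay the default for
reproducing the trial's numbers, and the recomputation is available for
sensitivity analysis.

Ingredient values are computed **per run against that run's own reference
diet** and then averaged across runs. Reference and test diets measured in
different runs are never paired, which also means pooled cross-run diet
means are not expected to reconcile exactly with the ingredient tables
through the substitution formula.

## Statistical inference

* **Correlation screening** (`pearson_matrix()`) uses pairwise-complete
  Pearson coefficients with two-sided t-test p-values.
* **ANOVA and Duncan grouping** (`one_way_anova()`,
  `duncan_groups()`): the multiple-range critical value for a stretch of
  $p$ ordered means is the studentized-range quantile at protection level
  $(1-\alpha)^{p-1}$, computed from `stats::qtukey` rather than printed
  tables; unequal group sizes use the harmonic mean with a warning. At
  extreme protection levels where the quantile search cannot converge the
  critical range is treated as infinite (all means share a letter), which
  is the correct $\alpha \to 0$ limit.
* **Stepwise fitting** (`stepwise_fit()`) is bidirectional least squares:
  the candidate with the smallest partial-F p-value enters while below
  `alpha_enter`, terms above `alpha_remove` are dropped, and — a constraint
  specific to this application — a candidate cannot enter if it correlates
  significantly with an already-included predictor, keeping the predictor
  set mutually uncorrelated. The thresholds default to 0.05/0.10/0.05 (the
  common statistics-package defaults; the original analysis names none) and
  are all configurable. With `alpha_enter = 1` and the screen disabled the
  procedure reduces to ordinary multiple OLS, which the tests verify
  against a normal-equations solve.

Fitting operates on sample-level data (n = 5 per ingredient class) by
default, because replicate-level NE per sample is not published. On the
wheat panel this reproduces the trial's equation almost exactly
(coefficients 1.968 on AME, −0.411 on ADF, intercept −14.227, R² > 0.99),
with AMEn — the second-best single predictor — correctly barred by the
collinearity screen (r(AME, AMEn) ≈ 0.99). On the wheat-bran panel the
sample-level fit instead selects AME (R² ≈ 0.78), not the published
CP/CF/ADF equation with R² = 0.785; that equation is evidently a
replicate-level fit whose underlying data are unpublished, so the package
treats the published bran coefficients as quoted constants
(`study_equations()`) rather than a reproducible fit. Similarly, our
pooled predicted-vs-measured correlation for wheat (5 training samples
plus the validation sample) is r ≈ 0.96; the exact point set behind the
originally reported r = 0.98 is not specified.

## Synthetic trial generator

`simulate_study()` emulates the trial design: runs of two diets (each
run measures the reference diet and one or more test diets), 6
total-collection cages of 8 birds and 6 chambers of 4 birds per diet and
run, and a 3-day balance window. Test-diet true energies follow the mixing
rule; cage excreta mass, energy and nitrogen are back-solved so the
total-collection arithmetic recovers the intended (noise-perturbed) diet
AME and N retention; chamber gas volumes are back-solved from the true
heat production implied by the diet's AME–NE gap, the FHP constant and the
true RQ. Each diet's true N retention is derived from its own AME−AMEn gap
so the nitrogen correction is internally consistent.

Noise is multiplicative lognormal per observable, parameterized by percent
CV and mean-preserving (the lognormal location is offset by
$-\sigma^2/2$), so a CV of zero returns the exact truth and expectations
do not drift with the noise level. Default CVs are calibrated to the
across-replicate relative standard deviations of the packaged trial
summaries: feed intake 7.4%, body weight 5.2%, diet AME 1.7%, heat
production 8%, RQ 3.5%, N retention 10%. With these defaults the
heat-production noise propagates to a diet-NE RSD of roughly 8–9%,
matching the packaged summaries' NE dispersion. One point worth noting
when comparing to the trial: the design runs the reference diet in every
run (so substitution always pairs within a run), whereas the original
trial's description of reference-diet allocation is ambiguous; the
generator's choice is the one its analysis assumes.

Per-run random substreams are derived from the user seed by a fixed
offset, so a run's records do not depend on how many other runs are
generated; the same seed yields a bit-identical bundle.

What the generator deliberately does **not** model: within-day gas
kinetics, circadian or activity-driven heat patterns, thermoregulatory
responses, growth curvature beyond linear gain at a fixed feed conversion
ratio, and bird-level (as opposed to replicate-level) variance components,
which are not identifiable from the published dispersion summaries anyway.
Passing recovery tests on synthetic data therefore demonstrates the
correctness and calibration of the computational chain, not the biological
fidelity of any particular trial.

## Numerical and testing choices

* Conservation identities (AMEI = NEI + HI, RE = AMEI − THP,
  RE = RE~protein~ + RE~fat~) are construction-exact and asserted to 1e−9
  on every simulated record.
* The noise-free generator/analyzer round trip is asserted to 1e−9 on all
  12 packaged ingredients; Monte-Carlo recovery at the calibrated CVs uses
  500 single-run studies (about 10 s on one CPU) and requires the mean
  recovered wheat NE to sit within 2% of truth — the observed bias is
  about −0.4%, from the mild nonlinearity of the NEI/AMEI ratio under
  intake noise.
* Coefficient-recovery properties for the regression module use 500
  synthetic panels of n = 20; recovered coefficients must sit within two
  Monte-Carlo standard errors of truth.
* CSV round trips are exercised at full write precision; summary tables
  recompute their means and CVs from per-sample values rather than
  trusting any printed summary cell (one packaged summary cell — the wheat
  NDF mean — is inconsistent with its own per-sample values, which is why
  recomputation is the rule).

## Known limitations

* The wheat-bran prediction equation and the validation correlations are
  quoted, not reproduced, for the data-availability reasons above.
* FHP is a literature constant, not measured per bird; groups with true
  maintenance below it will show flagged negative HI rather than a
  corrected estimate.
* The substitution method assumes energy additivity between the reference
  diet and the test ingredient; interactions (e.g. viscosity effects of
  fiber on the rest of the diet) bias the recovered values and are not
  modeled.
* Recomputed substitution shares depend on nominal DM values for minor
  ingredients; use the trial constants unless all DM contents are assayed.

## A worked example

```{r example}
# refit the wheat NE equation from the packaged panel
en <- study_ingredient_energy("wheat")
comp <- study_ingredients("wheat", experiment = 2)
eq <- stepwise_fit(en$ne, data.frame(ame = en$ame, amen = en$amen,
                                     cp = comp$cp, ee = comp$ee,
                                     cf = comp$cf, ndf = comp$ndf,
                                     adf = comp$adf, st = comp$st))
eq

# apply it to the validation sample and pool with the training panel
v <- validate_equation(eq, data.frame(ame = 13.79, adf = 4.78),
                       measured = 10.48,
                       training = list(data = data.frame(ame = en$ame,
                                                         adf = comp$adf),
                                       measured = en$ne))
v

# a noise-free synthetic study is a fixed point of the analysis
tr <- study_truth("wheat")
tr$noise_cvs[] <- 0
sim <- simulate_study(tr, generator_config(n_runs = 5, cage_replicates = 2,
                                           chamber_replicates = 2), seed = 1)
an <- analyze_trial(sim$bundle, scheme = tr$scheme)
an$ingredient_energy[, c("ingredient_id", "ame", "amen", "ne")]
```
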