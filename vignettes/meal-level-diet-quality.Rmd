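---
title: "Meal-level diet quality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal-level diet quality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures the package
implements, the parameters that matter and their defaults, what the
synthetic-record generator does and does not emulate, and the design
choices made where more than one reasonable convention exists.

## The data model

Three tables travel through the pipeline. *Diary lines*: one row per
food item within an eating occasion — participant, record day, diary
section (breakfast/lunch/dinner/snack), start and finish clock times,
food code, amount in grams. *Participants*: sex, age, height, weight and
a survey-year label; adults only. *Food composition*: per-100 g
nutrients (energy kcal; protein, fats and fatty-acid classes,
carbohydrate, added sugars, alcohol, fibre in g; Na/K/Ca/Mg/Fe in mg;
vitamins A (µg RAE), D (µg), C (mg)), USDA-pattern HEI equivalents
(cup- and oz-equivalents per 100 g), a single food-group assignment from
a fixed set of fifteen, and a water flag.

Clock times are stored as integer minutes since midnight. An occasion
that crosses midnight carries a next-day flag on its end time and is
attributed to the day on which it starts; a single convention keeps the
overlap logic one-dimensional. The composition reader checks energy
against the Atwater general factors (4/9/4/7 kcal/g for
protein/fat/carbohydrate/alcohol) within 25 % — enough slack for fibre
fermentation energy and rounding, tight enough to catch unit errors.

The bundled composition table (61 codes, at least three per food group,
values loosely modeled on Japanese staple foods) is a synthetic fixture,
not a nutritional reference; any table passing `validate_composition()`
can replace it. Carrying the HEI equivalents per food, as explicit
columns, makes the otherwise under-specified mapping from Japanese foods
to HEI-2015 components auditable, configurable data rather than hidden
logic.

## Eating-occasion classification

An eating occasion is a diary entry with its own start clock time and
name, keyed by (participant, day, section, start time). The pipeline
applies, in order:

1. **Water-only exclusion.** Occasions in which every member food is
   plain tap or mineral water are dropped; water alongside food stays.
2. **Multiple-entry resolution.** Within one main-meal section of one
   day, the earliest entry keeps the meal label; later entries become
   snacks. Ties on start time break by input order.
3. **Overlap merging.** Occasions whose half-open minute intervals
   overlap are merged transitively into one occasion spanning the
   earliest start to the latest end. A meal+snack merge keeps the meal
   label unless the same main meal already occurred earlier that day, in
   which case the merged occasion is a snack.

Three conventions were genuinely open and are fixed as follows. Overlap
is defined on half-open intervals, so occasions that merely touch at a
boundary minute do not merge — the least surprising reading of
"overlapping time period". Two *different* main meals overlapping is not
anticipated by the diary design; the earlier-starting label wins and the
event is reported, which preserves the at-most-one-of-each invariant
deterministically. And the multiple-entry rule is applied *before*
overlap merging; the reverse order is defensible too, but fixing
multiple-entry-first means the "same meal earlier in the day" exception
can only be triggered through section relabelling, and the final
labelling is identical on every fixture we constructed either way. After
the pipeline, classification is idempotent and every retained line
belongs to exactly one occasion.

The diary section is authoritative: no meal labels are inferred from
time of day alone.

## Aggregation and contribution decomposition

All dietary variables are analysed as mean daily values over the record
period (default 4 days), with zero assigned to non-consumers, so every
participant appears in every stratum (breakfast, lunch, dinner, snack,
total). The percentage contribution of meal type $m$ to a variable is

$$c_m = 100 \cdot \bar{x}_m / \bar{x}_{\mathrm{total}},$$

a ratio of population means (per-capita convention): contributions of
the four meal types sum to exactly 100 before rounding, and the
statistic is robust to individual zero totals. The alternative —
averaging per-participant ratios over consumers only — is reported for
food groups via the consumer-only means of `food_group_summary()`, but
is not the headline decomposition. Percentage-of-energy profiles use
Atwater factors (added sugars at 4, saturated fat at 9 kcal/g, i.e. the
factors of their parent macronutrients) and consumer-only denominators:
a participant who never consumed a stratum carries no information about
its macronutrient composition.

## Diet-quality scoring

**HEI-2015.** Thirteen components, 100 points. Intakes are
energy-adjusted by the density method — amount per 1000 kcal for cup/oz
equivalents and sodium, percentage of energy for added sugars and
saturated fats — except the fatty-acid component, which is the
unadjusted ratio (MUFA+PUFA)/SFA. Each component scores linearly between
a zero threshold and a maximum threshold, clamped at both ends; adequacy
components rise with intake, moderation components fall. The component
standards ship as a YAML table (`hei2015_standards.yaml`) transcribed
from the published HEI-2015 scoring standards, so the thresholds are
inspectable and swappable rather than hard-coded. A diet with zero SFA
scores full fatty-acid points when unsaturated fat is present (the ratio
tends to infinity) and zero when fat is absent entirely — the continuous
limit of the adequacy direction.

**NRF9.3.** Nine qualifying nutrients (protein, fibre, vitamins A, C, D,
Ca, Fe, K, Mg) and three disqualifying (added sugars, saturated fats,
Na). Each intake is energy-adjusted and re-scaled to an absolute daily
amount by the participant's sex- and age-specific Estimated Energy
Requirement (moderate physical activity), then expressed as a percentage
of its reference daily value. Qualifying percentages cap at 100;
disqualifying percentages do not (consistent with the 900-point maximum
and an unbounded minimum). Reference values ship as a YAML table
transcribed from the 2015 Japanese Dietary Reference Intakes, in
sex × age bands (18–29, 30–49, 50–69, 70+); the added-sugar limit is 5 %
of EER energy (the WHO conditional recommendation, there being no
Japanese value) and the saturated-fat limit 7 % of EER energy.

Both scores are invariant to multiplying every food amount by a positive
constant — the property that makes them comparable across strata of very
different sizes. Meal-stratum scores use the stratum's own energy for
the density step and the participant's full-day EER for normalisation; a
meal-share-scaled EER would be an equally defensible convention, but the
full-day EER keeps the per-meal score interpretable as "the nutrient
density of this meal, held to daily reference values" and is what we
adopt and document. Zero-energy strata yield missing scores rather than
errors.

## Misreporting screening

BMI categories are <18.5 / [18.5, 25) / ≥25 kg/m². Energy-intake
reporting is screened by the Goldberg ratio of reported mean daily
energy intake to estimated BMR with fixed cut-offs 1.02 and 2.35
(boundaries inclusive on the plausible and overreporting sides). These
cut-offs were derived for a 4-day record assuming a sedentary physical
activity level of 1.55; the PAL enters only through that derivation and
is carried as metadata, not recomputed. The default BMR equation is the
Japanese-adult equation of Ganpule and colleagues,
$\mathrm{BMR}\,(\mathrm{MJ/d}) = 0.0481\,W + 0.0234\,H - 0.0138\,A - k$
with $k$ = 0.4235 (men) / 0.9708 (women), converted at 239.006 kcal/MJ
and pinned by regression-test fixtures; any function of (sex, age,
height, weight) can be plugged in without touching the screening
contract.

## Association analysis

Tertiles of a total-diet score are assigned by ascending score with
stable tie-breaking, sizes differing by at most one in the usual case.
The tertile model is an ordinary linear model of the outcome on the
tertile factor plus categorical covariates (sex, three age bands, weight
status, reporting status, survey year). Adjusted means are
population-marginal means — predictions with every participant assigned
to a tertile, averaged over the observed covariate distribution — which
reduce exactly to raw tertile means when covariates are absent or
orthogonal. The trend test enters the tertile as the ordinal score
1/2/3; its type-I error is verified by simulation (2000 null
replicates, n = 90 each) to sit within 0.05 ± 0.02. Group comparisons
use the pooled-variance t test for two levels and one-way ANOVA
otherwise, with Bonferroni-adjusted all-pairs post hoc tests (and
compact letters) only when the overall P falls below 0.05. No
multiple-testing correction is applied across outcome rows, matching the
exploratory convention of contribution tables.

## The synthetic-record generator

The generator's defaults are the study conditions everything downstream
is tested under; they are fixed, not tuned per run:

| parameter | default | rationale |
|---|---|---|
| participants, days | 639 × 4 | the scale of a combined two-wave record study |
| meal energy shares | 21/32/40/11 % ÷ 1.04 | descriptive targets, normalized to the simplex (independently rounded percentages sum to 104; a per-capita decomposition must sum to 100) |
| share concentration | 36 | Dirichlet concentration giving a between-person SD of about 8 points on the dinner share |
| meal start times | 07:28 ± 46, 12:32 ± 32, 19:25 ± 56 min | normal draws per occasion |
| snack count/day | beta-binomial on 0–8, mean 1.8, SD 1.3 | bounded support with the target moments |
| skip probability/day | 3.1/2.0/0.8 % | calibrated so ~88/92/97 % of participants consume each main meal on all four days |
| occasion duration | uniform 10–40 min | durations are not reported anywhere; only start/finish existence matters |
| daily energy | N(2300, 350) men, N(1850, 300) women kcal | plausible Japanese adult intakes; EI:BMR then lands mostly in the plausible Goldberg band with a few percent under- and over-reporters |
| anomaly rates | 0.4 % double-entry, 9.5 % overlap per day | the relative frequencies a 639 × 4 diary produces (~10 and ~243 cases) |

Energy flows top-down: a participant-day draws its total energy, a
Dirichlet draw centred on the meal shares partitions it over the
occasions actually present (the conditional snack share is inflated by
$1/(1 - P(\text{no snacks}))$ so the *population mean* share hits the
target despite zero-snack days), and line amounts are back-solved from
per-100 g energies so line energies sum exactly to the day's draw.

Food-to-meal dependence is controlled by a 15 × 4 allocation matrix
whose rows are the target percentage contributions of each meal type to
each food group (confectioneries (2, 10, 9, 79) %, bread (71, 15, 6, 8) %,
and so on). Sampling foods with within-meal probabilities proportional
to the matrix column alone would *not* reproduce those targets — the
realized contribution would be distorted by the meal energy shares. The
generator therefore solves, once per configuration, for per-group daily
energy shares $r_g$ satisfying $\sum_g r_g\,c_{gm} = E_m$ (the
minimum-distance solution from a plausible starting vector), and samples
group $g$ at meal $m$ with probability proportional to $r_g c_{gm}$;
the realized contribution matrix then converges to the configured one
(verified at n = 2000 within ±3 points). Non-energetic beverages carry
zero energy by table construction and are added as fixed-gram side
lines, so they cannot perturb energy conservation.

Anomaly days inject (a) a second occasion into an already-used main-meal
diary section and (b) a snack-section occasion overlapping a main meal.
Because the classifier will demote the former to a snack and merge the
latter into its meal, the anomalies draw their foods from the column of
the stratum they will *end up in*, keeping the post-classification
calibration intact while still exercising every rule.

What the generator does **not** emulate: day-to-day within-person
correlation of intake (days are independent; real records are not),
seasonality and day-of-week structure, survey-wave intake differences
beyond a label, composite-dish disaggregation (each food code has
exactly one group), and any correlation between diet quality and
demographics (so group comparisons on generated data are null
comparisons). Passing tests on generated data therefore demonstrate
that the *machinery* is correct and calibrated, not that real Japanese
records would yield these numbers.

## Numerical choices and degenerate inputs

Amounts are kept at full floating precision so per-day energy
conservation holds to ~1e-15 relative error; CSV round trips preserve
all fields exactly under canonical formatting. Duplicate (section,
start-time) keys are one occasion by definition. Zero-variance score
vectors yield missing correlations; variables with zero population
total yield missing (not NaN) contributions; covariates observed at a
single level are dropped from the tertile model with a warning; groups
with fewer than two observations are dropped from comparisons with a
warning.

Problem sizes in the test suite are chosen to keep the full run around
two minutes on one core: calibration checks at n = 500–600, allocation
fidelity at n = 2000, the null-simulation of the trend test at 2000
replicates of n = 90, and score property sweeps over 500 randomized
diets.

## Known limitations

The HEI equivalents of the bundled table are coarse single-food
assignments; a real analysis would map a full composition database. The
NRF reference table uses four broad age bands and does not distinguish
pre-/post-menopausal iron needs within 30–49. The Goldberg screen is the
simple cut-off variant, without within-person CV confidence terms. The
generator's independence assumptions above mean variance components
(between- vs within-person) should not be read off synthetic data.
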