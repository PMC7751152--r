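---
title: "Cow size bioeconomics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cow size bioeconomics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowsize)
```

`cowsize` asks a production-systems question: for a cow-calf herd on a
fixed land base in the upper Midwest, which mature cow size maximizes value
per hectare? The package chains four models — intake/land use, biological
efficiency, enterprise budgeting, and discounted forward value — and this
vignette documents each model's assumptions, the tunable parameters, and
the design choices made where the problem was genuinely open.

## Weight normalization and weight tiers

Cow weights taken at weaning confound frame size with fleshiness, so all
analyses run on weight normalized to body condition score (BCS) 5:

$$\mathrm{DBW} = \mathrm{BW}\,(1 + f\,(5 - \mathrm{BCS}))$$

The per-score fraction `f` is a configuration knob (default 0.04, i.e. ~4%
of body weight per condition score, the conventional magnitude in
NRC-style condition adjustments). The linear form and the default are the
package's own choice — published herd analyses of this kind cite external
normalization equations without printing them — so `f` is exposed in
`normalize_to_bcs5()` and in the herd reader rather than hard-coded. When
BCS is unrecorded the actual weight is used, mirroring how study herds
handle years without condition scoring.

Cows are classified into eleven weight tiers. The boundary sequence
(430.84, 453.51, ..., 634.92 kg) is the canonical 50-lb ladder used in
cow-size tier analyses; steps alternate between 22.67 and 22.68 kg because
the boundaries are round numbers in pounds. Tiers are half-open intervals
$[\ell, u)$: deterministic assignment at boundaries, with tier 1 everything
below 430.84 kg (`assign_weight_tier(430.84)` is tier 2).

## Intake and land use

Daily dry-matter intake uses the NRC-style metabolic-weight prediction
(`daily_dmi()`), with three physiological states: dry pregnant (additive
constant 0.04631), nonpregnant (0.0384), and lactating (dry pregnant plus
0.2 kg DM per kg of daily milk). The body-weight term is the BCS-5 weight
directly, with no shrink factor: under that convention the aggregated
winter hay total for a 450 kg cow reproduces the published seasonal figure
to about 0.1%, which is the strongest available calibration anchor.

The production year is 364 days. The baseline splits it as 200 grazing
days (lactating intake on pasture, NEm 1.43 Mcal/kg DM), 49 hay days at
dry pregnant intake (NEm 1.20) and 115 cold-stress hay days at a 5% intake
premium. In sensitivity scenarios only grazing and no-stress hay days
trade off; the 115 cold-stress days are fixed, because winter severity
does not move with turn-out dates. When a scenario pushes hay days beyond
the 164-day baseline, the extra days fall during lactation and are charged
at the lactating hay intake (`season_plan()` tracks the three hay segments
explicitly).

Milk yield peaks at 8 kg/d at maturity. The age adjustment is the
package's choice: yield scales with the cow's position on her growth curve
(85% of peak at age 2, full at 6), implemented in `milk_yield_at_age()`.
Published treatments say intake is "adjusted for age of cow" without a
formula; tying milk to the growth fraction keeps one consistent maturity
scale across intake, revenue and depreciation.

Stocking rate is seasonal grazed DM over usable forage
(productivity × utilization; defaults 5,662 kg DM/ha and 50%). Herd size
on the 40.5 ha reference operation is continuous — per-cow budgets are
linear, so fractional herds keep the NPV surface smooth instead of
introducing integer jumps; users wanting whole cows can floor the result.

Two published daily-intake figures (10.84 and 15.91 kg DM/d during
grazing for 450 and 750 kg cows) are not reproducible from the stated
equation plus lactation adjustment (hand values 11.75 and 16.48); the
aggregation behind them is unstated, so the package treats seasonal totals
— which do reproduce — as the operative quantities and does not chase the
dailies.

## Biological-efficiency models

The three responses — CWP (weaning weight as a percent of cow weight), WW
(205-d adjusted weaning weight) and YW (yearling weight) — share one
design: intercept, ln(DBW), calf birth weight, calf sex, cow age, age².
The log weight term makes the headline contrasts elasticities: per 1%
weight increase, WW moves by $36.92\ln(1.01)$ kg and CWP by
$-38.58\ln(1.01)$ points. The packaged coefficient sets live in
`inst/extdata/coefficients_*.csv` and users can substitute their own in
the same layout; no model selection is performed — the design is fixed.

Refitting (`fit_efficiency_model()`) uses `lme4::lmer` with crossed year
and cow random intercepts, REML. Marginal and conditional R² follow the
standard variance-partition definition: fixed-effect variance (variance of
the linear predictor) over total, and fixed-plus-random over total.
Degenerate designs (a single year or a single cow) raise an error naming
the deficient factor rather than returning an unidentified fit.

The sex factor deserves a note: published coefficient tables list *both*
heifer and steer offsets, implying an unnamed reference level. The package
implements a three-level factor (`base`, `heifer`, `steer`) and always
applies an explicit heifer or steer offset for study-herd predictions. In
refits the reference is heifer, so the fitted intercept absorbs the
generating heifer offset and the steer term becomes the steer–heifer
contrast; the noiseless-recovery test asserts exactly that
reparameterization.

## Enterprise budgets

`enterprise_budget()` assembles, per cow-year: revenue (steer calf, heifer
calf × (1 − 0.3207 retention), cull cow × Prob(cull | age), cull bull
× 1/125), variable costs (feed, mineral, veterinary, labor, equipment
repairs, other, marketing) and fixed costs (pasture care,
machinery/livestock depreciation, miscellaneous, taxes). The rate items
follow a fixed ordering contract, chosen where the published wording is
ambiguous and exposed here so the arithmetic is auditable:

* marketing = 5% of revenue, and is itself a variable cost;
* interest = 5% of the variable subtotal *including* marketing;
* miscellaneous = 10% of the overhead (fixed) subtotal;
* taxes = the tax rate × (variable + fixed subtotal), i.e. expenditures
  before taxes and miscellaneous.

Hay "tons" are US short tons (907.185 kg) with a metric-tonne flag. The
literal printed form of the revenue identity in some treatments attaches
the cull probability to heifer revenue; the package treats that as a
typesetting artifact but exposes `literal_heifer_cull = TRUE` to compare.

No cull-probability schedule is ever printed for herds like this, and the
study herd's culling records did not exist. The default is a deterministic
productive life: certain culling at age 11 and an optional flat
involuntary rate before it. Age 11, not 10, because the NPV cow enters at
age 2 and a 10-year productive horizon then ends at age 11; culling at 10
would zero the final horizon year. Both the age and the involuntary rate
are arguments of `cull_schedule()`.

The projected machinery/livestock fixed cost is built from its stated
parts — cow depreciation (1200 − 782.65)/10, a 1/25 share of bull
depreciation over 5 years with salvage at the cull-bull price, and a
per-cow machinery scalar (default $37/cow, sized so the total lands in the
low-to-mid $90s/cow range typical of such budgets). The historical
schedule instead uses its tabulated $28.06/cow directly.

## Net present value

`npv_for_class()` simulates one cow per mature-weight class entering at
age 2 and aging a year per period over a 10-year horizon:

$$\mathrm{NPV} = \sum_{t=1}^{10}
  \frac{\mathrm{NetReturn}_t}{(1+0.05)^t \cdot \mathrm{ha,per,cow}_t}$$

Weight follows the growth rule (85% of mature weight at age 2, +4%/yr to
maturity at 6), and intake, stocking, calf weights, revenue and
depreciation all track the current weight. The cost schedule covers
2019–2027; the tenth horizon year extends the schedule's own construction
rules one more year (1% inflation on per-cow items, static land and
pasture care, hay carried forward, labor wage at its mean growth rate) in
`cost_year()`.

Market price paths for calves and cull stock are *synthetic* — shipped
series are clearly labelled as such (`inst/extdata/README_synthetic_prices.txt`)
because observed market series are not redistributable. Consequently the
package never treats absolute dollar NPVs as reproduction targets. What is
validated, exactly, is the arithmetic and ranking layer: the transcribed
reference NPV grid (`reference_npv_grid()`) feeds
`relative_change_grid()` and `optimal_class()`, which reproduce the
published percent grid (103 of 110 cells exactly at two decimals, all 110
within one unit of the last printed digit — the dollar grid is itself
transcribed at cent precision, so one-ulp disagreements are expected) and
the published optima (453.51 kg at the 200-d baseline, 430.84 kg from
205 d up). Ties in `optimal_class()` break toward the lighter class. On
the package's internally consistent grid, computed with synthetic prices,
NPV is negative everywhere and non-decreasing in grazing days (hay is the
costlier feed), matching the qualitative structure of the reference grid;
the reference grid's own baseline column breaks its otherwise uniform
~24 $/5-d column spacing for reasons its source does not explain, and the
package does not attempt to guess.

## The synthetic herd generator

`generate_herd()` exists so every downstream stage is testable without
proprietary herd records. It emulates:

* a stationary open herd (~130 cows × 8 years ≈ 1,040 cow-year records)
  with 28% annual replacement by age-2 heifers, giving a mean cow age near
  4.6 yr;
* persistent cow identity: a latent mature weight and random intercepts
  carried across years;
* growth along a logistic curve in age (inflection near 4 yr, asymptote at
  the cow's mature weight, entry at ~85%);
* BCS drawn per cow-year (5.37 ± 0.44) with raw weight back-computed
  through the normalization, so reader and generator are mutually
  consistent;
* weaning weights as the coefficient-set linear predictor plus crossed
  year and cow intercepts plus residual; yearling weights analogously.

Two calibrations are derivations, not tuning. First, the target moments
(538.74 ± 65.37 kg) describe the *observed* cross-section, but young cows
sit below their mature weight; the generator computes the expected growth
fraction under the stationary age distribution and back-solves the latent
mature-weight distribution so the observed cross-section hits the target.
Second, the noise SDs (WW: residual 23, cow 13, year 13 kg; YW: 35/11/11)
are solved once from the published variance partition — conditional R²
fixes the residual share of the printed herd SD, the marginal/conditional
gap fixes the random-effect share, split evenly between cow and year for
want of a printed split.

Calf birth weights (35 ± 4 kg) are synthetic defaults — the emulated
herd's birth-weight distribution is unreported — and are flagged as such.
The generator does not emulate: culling decisions or open cows (the real
records contain only cows that calved every year), selection or genetic
trend, within-season weight loss, or correlation between a cow's WW and YW
intercepts. Passing recovery tests therefore demonstrate that the
estimation machinery is correct under the stated generative model, not
that the model captures every feature of real herd data.

## Numerical choices and problem sizes

* Budget identities are exact in double precision; tests assert them to
  the cent (±0.005).
* The intake oracle tests compare against literal spreadsheet-style
  arithmetic to 6 significant digits on 20 random (weight, NEm) pairs.
* Mixed-model recovery tests use a ~1,040-record herd (one REML fit takes
  ~1–2 s); the quadratic-age coverage check uses 20 replicates of a
  200-record herd. The full default NPV grid (10 × 11 cells × 10 years)
  evaluates in about a second.
* All stochastic tests fix their seeds; `generate_herd()` is byte-identical
  under a fixed seed.
* Zero-variance (noiseless) mixed-model fits sit on the parameter
  boundary; lme4's convergence checker warns, the fixed effects are exact,
  and the package ignores the singular-fit message class in its control
  settings.

## Known limitations

Absolute dollar outputs inherit the synthetic price paths; only relative
and structural results are validated. The BCS normalization is linear with
a conventional slope, not a breed-specific equation. The cull schedule is
deterministic by default. Forage productivity is an annual scalar — no
within-season growth curve or rotation model. And the efficiency
regressions are associative models of one herd's structure; nothing here
estimates causal effects of changing cow size within an existing herd.
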