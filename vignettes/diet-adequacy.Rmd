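---
title: "Methods: household recalls to women's micronutrient adequacy and dietary diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: household recalls to women's micronutrient adequacy and dietary diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wradiet)
```

## The problem

In many rural settings, dietary data on women of reproductive age (WRA,
15–49 years) come from a single 24-hour recall administered at the
*household* level: the respondent lists every food the household
consumed in the previous day with approximate cooked or raw weights.
Two woman-level quantities must then be inferred: her **micronutrient
adequacy** relative to requirement standards, and her **dietary
diversity** as the Minimum Dietary Diversity for Women (MDD-W)
indicator, a validated proxy for micronutrient adequacy. `wradiet`
implements that chain with explicit, testable conventions at every
point where field practice leaves a choice open.

## From household foods to one woman's intake

Food codes resolve against a food composition table with ordered
fallback sources (default `BGD_FCT > IFCT > USDA > OTHER`; the first
table carrying a code wins, and the entry's provenance travels with
it). Densities are per 100 g **edible portion**; any refuse factor must
be applied upstream when the FCT is built, and no cooking
retention factors are applied — tables may instead carry separate codes
for cooked and raw forms.

Household nutrient totals are apportioned with adult-male-equivalent
(AME) consumption units. Each member gets a weight $w$ from an
age-by-sex band table (adult male $= 1$), and the index woman receives

$$\text{intake}_w \;=\; \text{household total} \times \frac{w_{\text{woman}}}{\sum_{m} w_m}.$$

The allocation is linear, so it conserves the household total over
members, is equivariant in grams, and is invariant to rescaling all
AME weights — all three are enforced as property tests. AME reference
weights differ between standards, so the band table is a required
input; the packaged fixture (adult male 1.00, adult female 0.80, ages
10–17 0.75, 5–9 0.60, 1–4 0.40, under 1 0.25) is deliberately simple
test scaffolding, not an endorsement of any particular standard. Foods
a woman ate outside the home are entered as ordinary household recall
records; pregnancy or lactation adjustments are not applied.

## Adequacy: NAR, truncation, MAR

Per nutrient, the nutrient adequacy ratio is $NAR = I/EAR$ with $I$
the daily intake and $EAR$ the age- and sex-specific estimated average
requirement (an ICMR-based reference for WRA ships with the package;
the table accepts arbitrary sex/age strata). The mean adequacy ratio
averages truncated NARs over exactly the 11 configured micronutrients.

Two truncation conventions are implemented as first-class modes:

* **binary** — a nutrient scores 1 when $NAR \ge 1$, else 0, making the
  MAR the *fraction of requirements met*;
* **cap** — the usual ceiling $\min(NAR, 1)$, which keeps partial
  credit below requirement.

The default is binary, because that is the convention the calibration
survey stated. But the two modes are not interchangeable: by linearity,
the population mean of a binary-mode MAR must equal the mean
per-nutrient adequacy fraction, and the calibration survey's printed
inadequacy prevalences imply a binary-mode mean of about 0.36 — while
its printed overall MAR is 0.43, a value consistent only with cap-style
truncation. The package therefore always carries the mode label in its
outputs, and the acceptance suite demonstrates the discrepancy rather
than hiding it.

Conventions fixed here (the literature is silent or inconsistent):
intake exactly at the EAR counts as **adequate** ("below EAR" is
strict); quantiles use linear interpolation between closest ranks;
nutrients without a tolerable upper level (thiamin, riboflavin,
B12) report exceedance as undefined, never as zero. For a population
whose ages fall in a single EAR stratum, the median NAR equals median
intake / EAR (a monotone-transform property that is also tested).
Several of the calibration survey's printed median NARs (thiamin,
riboflavin, niacin, B6, B12, iron) are *not* equal to its printed
median intake over its printed EAR, implying age-stratified
requirements were used for those nutrients without printing the
strata; the worked-value checks therefore assert only the five
nutrients (vitamin A, vitamin C, calcium, folate, zinc) where the
single-stratum arithmetic is exact.

No usual-intake (measurement-error) modelling is attempted: with a
single recall day the EAR cut-point prevalence conflates within- and
between-person variance, as it does in any single-day survey.

## Dietary diversity: the 15-g rule, twice

Foods map to the ten MDD-W groups through their FCT entry (mixed
dishes carry the single group of their entry; no ingredient
disaggregation). A group counts toward the 0–10 score only with at
least 15 g consumed. Field descriptions of this rule are genuinely
ambiguous between two readings, so both are implemented:

* `group_sum` (default, the FAO guideline reading): the group's summed
  grams must reach 15 g;
* `item_level`: some single food in the group must reach 15 g on its
  own.

An item-level flag implies the group-sum flag, hence
$DDS_{item} \le DDS_{group}$ always — a tested invariant, alongside
monotonicity in grams and equivalence with a brute-force enumeration
oracle. MDD-W is met at DDS ≥ 5. Because recall is household-level,
the woman's grams for grouping are her AME share of household grams —
the only reading under which a woman-level MDD-W is computable from
these data; the interface accepts true individual recall files when
they exist.

## The synthetic generator

The study the package is calibrated to cannot share its raw records,
so a seeded generator emulates its design: 201 surveyed households
(one index WRA each) across nine villages drawn from a 1169-household
frame, with the published village, age-band, marital, education,
occupation, household-size, decision-role, BMI-category and
food-security proportions as the default covariate marginals, and the
published food-group prevalences (summing to 4.253) as the default
Bernoulli consumption probabilities. Default output is the analyzed
sample of 201 surveyed households — unsurveyed frame households would
carry no recall and are represented only by the frame size.

Three generator choices matter for interpretation:

* **Grams are threshold-shifted lognormal**, `15 + Lognormal(µ, σ)`,
  with field-plausible median portions per group (e.g. 350 g of
  starchy staples, 90 g of flesh foods at the median). The published
  group prevalences are *post-15-g-rule* consumption proportions, so
  the Bernoulli indicator already encodes the rule and a consumed
  group always counts. This keeps the closed-form oracles exact
  (expected DDS = sum of probabilities; MDD-W prevalence = the
  Poisson-binomial tail).
* **Household recall is emitted by scaling the woman's grams back up**
  by the household's consumption units over hers, so the AME
  allocation is exercised non-trivially on every household and
  recovers her intake *exactly* — the pipeline-recovery test asserts
  DDS equality and MAR to 1e-9 for multi-member households.
* **Groups are independent by default**; a latent diet-quality factor
  (`latent_sd`) can shift all of a woman's group log-odds to induce
  the realistic positive DDS–MAR correlation, at the cost of the
  closed forms (which then refuse to compute rather than silently
  mislead).

Injected covariate effects on consumption act on the log-odds of every
group (`group_prob_shift`). For *regression recovery* tests, outcomes
are instead simulated directly from the fitted model's own law
(`simulate_mddw_outcomes`, `simulate_mar_outcomes`): a log-odds shift
on ten group indicators does not induce an exact target odds ratio on
the derived MDD-W indicator, so the direct simulators are the honest
oracle for "is the injected OR/coefficient recovered".

All randomness flows from one seed through a named stream per
component (roster, covariates, recall), so partial reruns are
reproducible. What the generator does **not** emulate: day-to-day and
seasonal intake variation, correlated food choices within markets,
FIES item responses (food security enters as a binary covariate), or
real FCT densities — the packaged FCT is synthetic and plausible, not
a copy of any published table. Passing tests therefore validate the
*computational pipeline*, not substantive nutritional findings about
any real population.

## Determinant models and diagnostics

The MDD-W model is a binomial GLM reported as adjusted odds ratios
with Wald CIs computed on the link scale and exponentiated; the MAR
model is OLS with raw coefficients. Reference levels mirror the
calibration survey's contrast structure (age 15–24, unmarried, no
formal education, housewife, lowest income quartile, household > 5,
no decision role, normal BMI, food-insecure, MDD-W-inadequate).
Covariate derivations: income quartiles cut at sample ranks; the 0–3
decision score counts participation in own health care, large
purchases and family visits, with a "decision-making role" only at the
full score of 3; WHO BMI bands at 18.5 and 25.

Diagnostics follow survey-analysis practice: generalized VIFs per term
(the squared df-adjusted GVIF compared to 2); a Pearson goodness-of-fit
statistic for the logistic model, computed on individual observations
by default with a deciles-of-risk binning available (the two common
conventions, since neither is canonical); Shapiro-Wilk plus moment
summaries for OLS residuals; Cook's distance above 1 and leverage
above `2p/n` flag influential cases. A fixed leverage cutoff (default
0.05) is retained as an option for comparability with reports that
quote an n-independent value, though it is not recommended: leverage
scales with the number of parameters over n.

## Problem sizes and numerical choices

The validation suite uses: 1000 random rosters for allocation
conservation (tolerance 1e-9 relative); 500 random recalls against the
brute-force DDS oracle; n = 20,000 women for the closed-form DDS,
Poisson-binomial and lognormal EAR cut-point checks (within 3–4
standard errors); and 50 seeded replicates at n = 2,500 for effect
recovery (education OR 3.0 on MDD-W, MDD-W coefficient 0.05 on MAR,
with ≥ 90% CI coverage required). Lognormal intake laws are fitted to
published medians and quartiles by
`µ = log(median)`, `σ = log(p75/p25) / (2 Φ⁻¹(0.75))`.
Degenerate inputs fail loudly: zero total consumption units,
single-class outcomes, rank-deficient designs, uncovered EAR or AME
strata, and unresolved food codes (aggregated across the survey before
failing) all raise typed errors rather than producing partial results.
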