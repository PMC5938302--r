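---
title: "An agent-based model of alcohol consumption, harms and policy levers: model description and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the model is

`alcosim` simulates an adult population whose members drink (or abstain),
accumulate blood alcohol, suffer acute harms during and after drinking
episodes, develop alcohol-attributable chronic disease from long-run
consumption, and respond to policy levers on the drinking environment and
on treatment services. It is built for comparative policy analysis: the
output of interest is the *difference* between a scenario and the baseline
("business as usual"), expressed as a percent reduction in mean monthly
harm incidence per 100,000 adults, with a 95% margin of error over
replicate runs — not a precise forecast of any single indicator.

The simulated world contains licensed venues grouped into entertainment
precincts of low/medium/high density, bottle shops, homes, workplaces, and
periodic peer events (home parties) on a small-world friend network.
Geography is deliberately absent: a lognormal travel-time draw per person
stands in for distance and acts only as a penalty in the opportunity
weights.

## Agents and the representative/synthetic split

Each agent carries age (continuous, ageing in simulated time), sex, body
weight (truncated normal per sex), a drinking category — abstainer, low,
moderate or heavy — and a ring buffer of up to 20 annual consumption
averages. Category bands follow the standard definitions in standard
drinks/day (10 g ethanol each): low ≤ 2, moderate 3–6, heavy ≥ 7. Because
the published bands leave (2, 3) and (6, 7) unassigned, the implementation
uses half-open bands with cut points at 2.5 and 6.5 drinks/day; an explicit
abstainer state (absent from the band definitions) is added because
treatment effects and prevalence realism require non-drinkers.

For computational efficiency only a fraction of agents (default 5%) are
*representatives*, simulated in full behavioural detail. The remaining
*synthetic* persons are each linked to a representative matched on
(5-year age band × sex × category) at assignment, and acquire harms by
independent Poisson draws at their representative's realised monthly harm
intensity. Draws — not event copying — preserve count distributions;
strata that lose their last representative promote a synthetic member.
Synthetic persons re-synchronise category and consumption history with
their representative at each year boundary.

## Behaviour: capacity, opportunity, motivation

Each representative makes a daily drinking decision. The rule groups are:

* **Capacity** — abstainers, the hospitalised, the severely intoxicated
  (BAC ≥ 0.25 g/100mL) and agents in non-drinking contexts (work, transit,
  bottle shop) cannot start an episode. The same threshold stops further
  drinks mid-episode.
* **Opportunity** — where: home, a licensed venue, or a peer event, with
  weights by category, day of week (Friday/Saturday uplift), age (under-30
  uplift for venues and late arrival), and the travel-time penalty. Venue
  arrivals are drawn over evening slots (18:00, 20:00, 22:00, 24:00,
  02:00); admission is checked against closing time, lockout and the
  responsible-service-of-alcohol (RSA) BAC threshold, in the precedence
  closed > lockout > RSA. Patrons blocked at the door late at night
  abandon the outing (bottle shops are shut by then, so no compensatory
  home session is possible).
* **Motivation** — how much and how fast: intended drinks per episode are
  negative binomial with category-specific means ordered heavy > moderate
  > low, inflated at venues; pace is one drink per 30 min at venues,
  40 min at peer events, 45 min at home. Venue episodes truncate at
  closing time and at the RSA threshold (service stops and the patron is
  ejected); the severe-intoxication gate truncates anywhere.

A fraction of venue visits (higher for young and heavy drinkers, requiring
an open bottle shop at decision time) is preceded by a short pre-loading
episode at home, which raises the arrival BAC.

Average consumption per category is *emergent* from these rules, and the
defaults were chosen so each category's long-run mean falls inside its
defining band (about 1.4 / 4.5 / 9 drinks/day for low / moderate / heavy);
annual re-categorisation from the trailing mean is therefore stable. A
small symmetric habit drift (2.5%/yr) moves drinkers between adjacent
categories.

## Blood alcohol concentration

BAC follows the Widmark equation: a drink of $A$ grams ethanol raises BAC
by $100A/(rW \cdot 1000)$ g/100mL for body weight $W$ kg and distribution
factor $r$ (0.68 male, 0.55 female), and is eliminated linearly at
$\beta = 0.015$ g/100mL/h with a floor at zero. Absorption is treated as
instantaneous, so within-episode trajectories are rising sawtooths and the
engine can integrate any exponential function of BAC in closed form — each
episode costs O(1) regardless of length, which is what makes 50,000-agent
replicates affordable.

## Harm generation

**Acute harms** (unintentional injury, alcohol poisoning, road traffic
accidents, violence/assault, acute exacerbations of alcohol use disorder)
arise from a non-homogeneous Poisson process whose intensity is
`scale × base(type) × sex × age-band × context × exp(k·BAC)`, active from
the first drink of an episode until BAC returns to zero, including a
transit leg home after venue episodes. The exponential BAC multiplier is
the model's "non-linear in BAC" choice; the per-type slopes (10–22) are
calibration parameters. Road traffic accidents are possible only in
transit; exacerbations only for heavy-category agents; violence is
male-dominated and concentrated at venues; young adults carry roughly five
times the acute hazard of the over-75s at equal BAC. Each event is routed
to emergency-department presentation, hospitalisation and death by
independent per-type Bernoulli flags (ED and hospital are parallel, not
nested), encoding the ordinal facts that violence rarely hospitalises,
poisoning usually presents to ED, and exacerbations almost always
hospitalise.

**Chronic harms** use attributable-fraction epidemiology,
$AF = (RR-1)/RR$, applied once per simulated year to every living adult.
Exposure is the 20-year moving average of the consumption history (short
histories average over available years rather than zero-padding, which
would understate risk in young heavy drinkers). Onset probability is
`baseline incidence(age) × RR(category) × AF`, i.e. only the
alcohol-attributable share of incidence is simulated. Ten condition groups
are carried (upper-digestive, liver, breast and colorectal cancers,
hypertensive disease, ischaemic heart disease, haemorrhagic stroke,
alcoholic liver cirrhosis, alcohol use disorder); cirrhosis and alcohol
use disorder are wholly attributable ($AF = 1$), with their category
columns acting as incidence weights. Ongoing conditions emit annual
ED/hospitalisation events, can be fatal, and resolve after their mean
duration.

**Mortality** combines harm deaths with Gompertz–Makeham background
mortality; the dead are removed. New 18-year-olds enter at a configured
rate; with no migration the population declines slowly (≈0.45%/yr), so all
outputs are per 100,000 adults.

## Scenarios and the interaction mechanisms

Scenarios are pure configuration overlays active from their start date:
venue closing hour, lockout hour, bottle-shop hours, RSA threshold, and
treatment coverage. The packaged set is baseline (5 a.m. closing, 10 p.m.
bottle shops, no lockout) plus: (1) 3 a.m. closing + 1 a.m. lockout,
(2) 3 a.m. closing, (3) treatment expansion to 20% of heavy drinkers, and
(4) the union of (1) and (3).

Treatment enrols heavy drinkers annually; enrolment capacity is sized to
the heavy-drinker population at rollout (an absolute annual reach, capped
by the current pool — a service planned for a caseload does not shrink as
prevalence falls). Enrolled agents transition to the moderate category
with high probability, but in a permissive environment almost all relapse
within a year. Two environmental couplings close the loop, both driven by
a *late-night entry restriction index* — the fraction of baseline venue
entry hours past 1 a.m. removed by the effective configuration (0 at
baseline, 0.5 under a 3 a.m. close, 1 under a 1 a.m. lockout):

* relapse of treated agents is suppressed in proportion to the index;
* habit drift *into* the heavy category is likewise suppressed.

These couplings are how the model realises the empirically reported
super-additivity of combining environmental restriction with treatment:
restriction alone trims late-night harm, treatment alone is
relapse-limited, but together treatment gains stick. They are behavioural
hypotheses, not measured quantities; their strengths are calibration
parameters.

## Calibration

The original model's full parameter tables are not public, so this package
ships a stand-in parameterisation with the same structure, fitted by the
package's own harness (`calibrate()`: Latin-hypercube screening followed
by coordinate descent on a weighted squared relative error). The fitted
targets are the baseline mean monthly acute incidence (44.5/100k), ED
(28.7) and hospitalisation (23.2) rates, the 86.7%/13.3% acute/chronic
split, the 64.5% ED and 52.1% hospitalisation shares of acute harms, the
four scenario reductions (19.5/12.3/9/33.3%), and the ≈0.45%/yr population
decline. Structural parameters (arrival-slot weights, BAC slopes, context
multipliers, the couplings above) position the scenario responses; five
nearly-orthogonal scales (global acute hazard scale, chronic incidence
scale, ED and hospitalisation routing scales, entry rate) then pin the
levels, each approximately linear in its target.

Calibration and evaluation run at desk scale: 12 replicates of 50,000
agents (5% representatives), six years of spin-up (2011–2016) under
baseline conditions and a 2017–2021 reporting window — roughly three
minutes per 12-replicate experiment on one CPU. Outputs are per-100k, so
results are scale-free to first order; at 50k agents a replicate's monthly
mean carries Monte-Carlo noise (±1–2% of the mean) that a multi-million
agent run would not, which is why desk-scale checks combine published
margins with the estimate's own margin of error.

## Numerical and degenerate-case choices

* Episode intensity integrals use the geometric closed form of
  $\int e^{k\,bac(t)}dt$ over the drink sawtooth; a guard replaces
  $|q-1| < 10^{-12}$ with a linearised ratio. Event *times* are drawn by
  inverse sampling within the chosen segment (exact for the exponential
  form), and synthetic persons' event times are resampled from their
  representative's episode intensities.
* Dead agents are flagged immediately and physically removed at year
  boundaries (cheap column-wise state); entrants join at year boundaries.
* Clock wraps: venue hours past midnight use session hours (24 + h);
  closing at or before opening means "next day".
* Degenerate configs: zero venues with venue behaviour enabled, scenario
  overrides with unknown keys, scenario start inside spin-up, and
  non-normalised probability tables are configuration errors; a
  representative death re-links its synthetic persons within stratum,
  promoting one if the stratum empties.

## What the generator does and does not emulate

The synthetic population reproduces marginal age/sex/weight/category
distributions and a plausible venue-going rhythm; it does not carry
household structure, migration, domestic violence, income, or
social-contagion of drinking norms, and peer events affect only where
drinking happens, not how much peers influence each other. Passing the
acceptance checks therefore shows that the mechanism produces the reported
comparative statics under the packaged parameterisation — not that the
parameterisation equals the unpublished original, nor that absolute harm
forecasts for a real jurisdiction would be accurate.

## Known limitations

* The acute/chronic split drifts slowly within the window because chronic
  prevalence (and its annual ED/hospital events) accumulates over
  disease durations longer than the simulation; the split is calibrated on
  the pooled 2017–2021 window.
* Treatment, relapse and the environmental couplings are annual-resolution
  mechanisms; within-year dynamics are not represented.
* Alcohol poisoning among young adults is under-represented relative to
  surveillance data, a known gap in models of this family.
* The hospitalisation rate's published margin (±0.2/100k) is narrower than
  desk-scale Monte-Carlo noise; only the combined-margin check is
  meaningful at 50k agents.
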