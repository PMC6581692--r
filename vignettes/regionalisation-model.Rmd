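---
title: "Modelling delivery-care regionalisation with regiosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delivery-care regionalisation with regiosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiosim)
library(dplyr)
```

regiosim simulates where pregnant women give birth under policies that
*regionalise* delivery care — restrict it to higher-capability facilities —
and what that does to neonatal mortality, travel, household finances and
patient utility. This vignette is the package's account of the model:
what is assumed, which parameters matter, what the synthetic data do and
do not emulate, and where the design was genuinely open.

## The agent model

A simulated world has three parts, each generated synthetically from the
configuration (see `default_config()`):

* a **cohort** of pregnant women with location, urbanicity, wealth
  quintile, literacy, education, parity, age, marital status, antenatal
  visits, multiple gestation, predicted risky delivery, predicted
  caesarean need and yearly consumption expenditure;
* a **facility registry** of delivery sites across seven types (central,
  district, rural/community and other hospitals; health centres; clinics;
  maternities) with management, fee-charging, obstetric readiness (the
  unweighted mean of binary WHO-style equipment/resource items),
  caesarean capability and a 3-month count of basic emergency obstetric
  and neonatal care (BEmONC) signal functions;
* a **road network** over which travel distances are computed.

### Facility choice

Each woman's choice is two-step. First a multinomial logit on her own
characteristics assigns her latent *preference class*. With the default
coefficients about two-thirds of women land in class 1, whose facility
utility is dominated by distance and user fees; the rest form class 2,
which values central hospitals and obstetric readiness and is much less
distance-sensitive. Second, conditional on class $c$, facility $j$ in her
choice set gets the linear utility

$$V_{ij} = \beta^{c}_{d}\,d_{ij} + \beta^{c}_{f}\,\mathrm{fee}_j +
\beta^{c}_{r}\,\mathrm{ready}_j + \beta^{c}_{t(j)},$$

and she delivers at $j$ with the conditional-logit probability
$\exp V_{ij} / \sum_k \exp V_{ik}$ (computed with max-subtraction;
`deterministic_choice = TRUE` switches to the most-likely facility
instead). Sampling is implemented by the Gumbel-max construction — add an
independent standard Gumbel to each $V_{ij}$ and take the argmax — which
is exactly softmax sampling and lets replicate scenarios share one Gumbel
draw per (woman, facility), so scenario contrasts are paired (common
random numbers).

The choice set is every scenario-eligible facility within 100 km of the
woman *by road*. Using road distance keeps the radius commensurate with
the distance covariate. If a restriction empties a woman's radius, the
single nearest eligible facility is included and flagged (`rescue`):
without this, restricted scenarios would strand remote women with no
defined behaviour; with it, they travel far — which is the phenomenon of
interest, not an artefact.

The coefficients carry standard errors; each replicate run perturbs every
coefficient with an independent normal draw (distance coefficients are
resampled to stay negative — longer travel can never be preferred all
else equal). This is the parameter-uncertainty layer of the credible
intervals.

### Routing

Travel uses an undirected road graph whose edge lengths may not undercut
the straight-line (haversine, R = 6371 km) distance between their
endpoints by more than 1% — so the haversine is an admissible A*
heuristic. `shortest_route()` runs A* between snapped nodes and adds
straight-line access legs at both ends; women snapping to a different
connected component than the facility (the lake islands) fall back to the
pure straight-line distance. Bulk woman-by-facility matrices
(`network_distances()`) use Dijkstra over the same weights, which returns
identical distances — the A*–Dijkstra equality is itself one of the test
suite's properties — and cache by snapped node, keeping a
20 000 × 540 query set tractable.

### Outcomes

* **Caesarean section** only at capable facilities: probability `p_need`
  (0.85) given predicted need, else `p_background` (0.12).
* **Neonatal death**: logistic risk on risky delivery (+1.0), multiple
  gestation (+0.7), facility readiness (−1.2), caesarean capability
  (−0.4) and caesarean performed (−0.6), intercept −3.34. This is a
  reduced-form stand-in for a richer risk regression whose inputs are not
  public; mortality contrasts should be read as directional. Wealth never
  enters the risk directly — it acts only through where a woman delivers.
* **Out-of-pocket cost**: the facility fee (only where fees are charged),
  a type-specific non-fee direct cost, and round-trip transport at
  0.04 USD/km. Transport is included deliberately: the scenarios move
  costs chiefly through distance, and a fee-only costing could not
  respond to restriction at all.
* **Catastrophic expenditure**: cost strictly greater than 10% of the
  woman's yearly expenditure (a cost of exactly 10% is not catastrophic).

### Replication and reporting

`run_experiment()` runs every configured scenario `n_runs` times. Run
$r$ draws one cohort, one perturbed parameter set and one set of agent
uniforms/Gumbels, shared by all scenarios of that run; the first
configured scenario (the status quo by default) is the comparison
baseline. Per-run metrics aggregate to means with 95% posterior credible
intervals — empirical 2.5/97.5 percentiles across runs, no distributional
assumption — and paired per-run differences give the contrast intervals.
Significance statements are read off contrast intervals excluding zero;
no hypothesis-test machinery is attached. The utility decrement is
reported in willingness-to-travel km, $\Delta V / |\beta^c_d|$, using each
woman's own class and that run's drawn coefficient.

## Scenarios

The packaged list: status quo; restriction to caesarean-capable
facilities (scenario 1); the same plus 20 facilities upgraded to
caesarean capability (scenario 2); restriction to facilities with ≥5
recent BEmONC signal functions (scenario 3); the same plus 30 upgrades
(scenario 4). `scenario_analyses()` adds the compensatory variants:
upgrades without restriction, fee removal, full readiness, and both.

Upgrades are chosen by greedy maximal coverage: repeatedly pick the
non-qualifying facility whose upgrade covers the most not-yet-covered
women within the coverage radius (20 km by default, straight-line —
siting over every woman-facility pair must stay cheap), counting women
near already-qualifying facilities as covered, ties to the lowest id.
The upgrade counts and radius are configuration knobs, not published
values; the greedy rule carries the classical $(1-1/e)$ guarantee and in
practice matches exhaustive search on small instances (tested). Siting
uses one dedicated reference cohort so the chosen policy is identical
across replicate runs; letting each run re-site would make the policy
itself stochastic. Upgraded facilities also have their readiness raised
to at least the median of already-qualifying facilities — left at their
own (low) readiness they would never be chosen, set to 1.0 they would
always be; the median is the neutral middle.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* the model needs: two urban
kernels plus a rural background inside a Malawi-sized bounding box; a
wealth gradient (ordinal logit on distance to the nearest city, so with a
positive gradient the poorest women live farthest from the cities, and a
zero gradient recovers the configured quintile marginals exactly);
independent covariate marginals; a facility mix dominated by health
centres with readiness rising toward the cities; hospitals that are
caesarean-capable; fees concentrated in the private/NGO sector; a
connected mainland road graph (spanning tree + nearest-neighbour links,
detour factors 1.1–1.4) with a small disconnected island component; and
gamma-distributed expenditure whose quintile means rescale to a national
mean of 137 USD.

They do **not** reproduce real settlement density. Rural women are
spread over the whole bounding box, so baseline travel distances
(≈35–40 km on average) and hence transport costs and catastrophic-risk
levels are several times larger than survey-based estimates, and
scenario contrasts in km are correspondingly stretched. Passing tests
therefore demonstrate the mechanics and directions of the policy effects,
not their magnitudes in any real country. Quantities that do not lean on
geography land close to their anchors: status-quo neonatal mortality
≈ 20–23 per 1000, caesarean rate ≈ 3%, class-1 share ≈ 66%, two-thirds of
deliveries in health centres, and status-quo out-of-pocket spend ≈ $6.

## Numerical choices and degenerate inputs

Softmax and the latent-class likelihood subtract the maximum utility
before exponentiating. Choice sets of one collapse to probability 1;
equidistant snap candidates break to the lowest node id; greedy-siting
ties break to the lowest facility id; `pci()` on a single replicate
returns a zero-width interval. Seeds derive from one master seed through
a pure 31-bit multiplicative hash keyed by stream name and run index,
so any run of any scenario is reproducible in isolation.
`fit_latent_class_logit()` maximises the marginal likelihood by BFGS from
several perturbed starts, reports inverse-Hessian standard errors and
canonicalises class order by the distance coefficient (most negative
first), flipping the membership logit when two classes swap.

## Problem sizes

The full study conditions — 20 000 women × 200 runs × 5 scenarios — are
the configuration defaults. The test suite and the acceptance script run
the same pipeline at reduced scale (hundreds to a few thousand women,
2–20 runs), chosen so the whole suite completes in minutes while every
Monte-Carlo assertion still uses the standard error at the n it actually
draws. A 20-run × 2000-woman experiment over all five scenarios takes
roughly 15 s on one CPU.

```{r example, eval = FALSE}
cfg <- default_config()
cfg$cohort_size <- 2000L
cfg$n_runs <- 20L
res <- run_experiment(validate_config(cfg))
tidy(res, contrasts = TRUE)
plot_utilisation(res)
```

## Known limitations

Home delivery is not an outside option (the policy setting discourages
it, and the utilisation data the choice model emulates are
facility-based). Facility capacity is unconstrained: a scenario can send
275% more deliveries to district hospitals without congestion, queues or
staffing effects. Travel time, seasonal road conditions and transport
mode are not modelled — distance is the single access cost. The mortality
model is a calibrated reduced form; its coefficients are configuration,
not estimates. All default coefficients are synthetic stand-ins encoding
qualitative findings (which class values what, signs and rough
magnitudes), and every one of them is overridable through the
configuration file.
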