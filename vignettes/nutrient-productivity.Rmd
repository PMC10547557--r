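---
title: "Estimating the trophic distribution of reef fishery services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the trophic distribution of reef fishery services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefnutro)
```

`reefnutro` estimates how coral-reef fishery services — standing biomass,
biomass turnover, and the production of six dietary nutrients — are
distributed across fish trophic groups, and models that distribution against
fishing and habitat gradients. This vignette documents the science the package
implements, the choices that were genuinely open, and what its synthetic
validation can and cannot show.

## From survey rows to fishery services

The raw inputs are the three tables a belt-transect UVC program produces: a
long survey table (site, transect, species, length, count, transect
dimensions), a site table (country, management regime, depth, percent cover of
hard coral, turf algae, macroalgae, rubble and bare substrate), and a species
trait table (maximum length, standardized growth coefficient, length–weight
coefficients, trophic group, six nutrient concentrations per 100 g of raw
muscle tissue).

Ingest applies three exclusion rules: fish shorter than 5 cm, damselfish
species, and highly mobile elasmobranchs are not fishery targets (or cannot be
censused reliably) and are removed, with a per-rule log. A species observed
but missing from the trait table aborts ingest rather than being dropped
silently — a silent drop would bias production downward invisibly. Lengths
recorded in 5 cm bins (used in some countries up to a 40 cm cut-off) are
resolved to the bin midpoint by default. The survey convention does not
dictate a resolution rule, so the bin-to-length function is pluggable;
midpoint is the neutral choice and the convention is worth a sensitivity check
when bins are wide relative to body size.

Each fish then gets:

* **mass** from the allometric length–weight relationship $W = aL^b$ (grams,
  length in cm);
* **daily somatic growth** by advancing its von Bertalanffy trajectory one
  day: $\Delta L = (L_{max} - L)(1 - e^{-K_{max}/365})$, with the asymptotic
  length taken equal to the species maximum length $L_{max}$ and the
  standardized coefficient $K_{max}$ (yr⁻¹, admissible range 0.011–16.43);
* **daily mass production** $\Delta W = a(L+\Delta L)^b - aL^b$;
* **daily nutrient production** $\Delta W \times e \times c_n / 100$ for each
  nutrient, where $e$ is the edible fraction (default 0.87, the finfish
  average) and $c_n$ the tissue concentration per 100 g.

Two modelling assumptions deserve emphasis. First, equating the asymptotic
length with $L_{max}$ is the simplest faithful reading of the standardized
growth coefficient; the equivalence is isolated in one argument of
`daily_growth()` so a corrected asymptotic length can be substituted. Second,
fish recorded at or above $L_{max}$ (possible with binned lengths) are clamped
to zero growth rather than assigned a negative age. All rates are *potential*:
natural and fishing mortality are excluded by construction, so production
numbers are ceilings, not yields.

Transect sums are scaled to per-hectare rates (×10000/area) and averaged,
unweighted, across a site's transects. Averaging at the transect level damps
the sampling variability that comes from heterogeneous replication (1–8
transects of 60–500 m²); no area re-weighting is applied beyond the
per-hectare conversion. Biomass turnover is production divided by standing
biomass, reported as a percentage. The reporting basis is configurable; the
default is annual (×365), since daily percentages are fractions of a percent
and annual turnover is the quantity fisheries scientists compare against
production/biomass ratios. Zero biomass with zero production defines turnover
as 0; zero biomass with positive production is rejected as an impossible
state. Sessile invertivores are carried through the service table but excluded
from contributions and compositions — they are not fishery targets.

## Nutrient density

A species' nutritional quality is summarized as the percent contribution of
one 100 g fillet portion to recommended daily intakes, summed over the six
nutrients with each nutrient capped at 100% *before* summation, so a single
highly concentrated nutrient (selenium, in practice) cannot dominate. The
score lies in [0, 600]. Portion size and cap are parameters (defaults 100 g,
100%).

The reference intakes are configuration, not constants: the shipped table
(`inst/extdata/rni_women_18_65.csv`) holds values for adult women aged 18–65
assembled from WHO/FAO requirement reports (calcium 1000 mg, iron 29.4 mg at
moderate bioavailability, zinc 4.9 mg, selenium 26 µg, vitamin A 500 µg) and
the EFSA adequate intake for long-chain omega-3 fatty acids (1.1 g). Users
targeting a different reference population replace the file; the population
label travels with the table. Species-level associations between nutrition and
growth (`growth_nutrient_association()`) are Pearson correlations against
$\log_{10} K_{max}$ — growth coefficients span three orders of magnitude, so
the log scale is the natural axis — with a Spearman option.

## The composition model

For each service, the site's three fishery-target groups — herbivores
(scrapers/detritivores and browsers combined), mobile invertivores,
piscivores — form a 3-part composition. Exact zeros occur (piscivores are
absent from many heavily fished reefs), and the Dirichlet has no mass on the
boundary, so zero parts are replaced by a small fraction (`zero_adjust`,
default 1e-4) and the composition renormalized; the distortion per part is
bounded by twice the adjustment.

The model is a Dirichlet regression in mean/precision form: mean composition
$\mu = \mathrm{softmax}(\eta)$ with the mobile-invertivore linear predictor
fixed at 0 (reference category), concentration $\alpha = \mu\phi$ with one
scalar precision $\phi$. The linear predictor for each non-reference category
contains an intercept; standardized fixed effects for fishable biomass, the
five benthic covers and depth; a country-varying biomass slope; and a
management-regime intercept nested in country. Covariates are centred and
scaled to unit standard deviation, and the constants are stored so prediction
grids can be transformed onto the fitted scale — this also makes the fit
invariant to affine rescaling of the raw covariates. All five benthic covers
enter despite their sum constraint; because reefs carry a variable
unclassified remainder (sand, soft corals, sponges), the five covers are not a
closed composition, but a cover can be dropped via the `covariates` argument
if collinearity is a concern in a particular data set.

Priors are weakly informative and configurable: normal(0, 2.5) on
standardized-scale coefficients, half-normal(0, 1) on the two group-effect
standard deviations, half-normal(0, 50) on $\phi$. Group effects are
parameterized non-centred ($u = \sigma z$, $z \sim N(0,1)$), which keeps the
posterior geometry well behaved when the group effects are weak. Setting
`beta_scale = Inf` gives maximum likelihood; with flat coefficient priors the
fitted mean compositions are invariant to relabelling the reference category
(checked to 1e-6 in the tests).

Two estimation routes share one implementation of the log posterior and its
analytic gradient:

* **MAP + Laplace** (default): BFGS from a zero initialization
  ($\log\phi$ starts at $\log 10$), relative tolerance 1e-14 with a second
  polishing run; the observed curvature at the mode (numerically
  differentiated gradient) supplies a normal approximation from which
  intervals and prediction bands are drawn. A known artefact of the
  non-centred MAP is that the group-effect scale parameters drift toward
  their prior scale rather than the posterior bulk; the fixed effects —
  the scientific quantities — are unaffected, but the reported $\sigma$ point
  estimates should not be interpreted under `method = "map"`.
* **Hamiltonian Monte Carlo** (`method = "mcmc"`; default 4 chains × 3000
  iterations, first half warm-up): leapfrog integration with jittered
  trajectory lengths (12–24 steps), dual-averaging step-size adaptation
  targeting 0.85 acceptance, and a Stan-like windowed warm-up that
  re-estimates the diagonal mass matrix from the chain's own draws (the
  Laplace curvature only seeds the initial mass — at the non-centred mode it
  is unreliable for the scale parameters, which is also why a full-covariance
  preconditioner is deliberately *not* used). Iterations whose trajectory
  produces a non-finite gradient or an energy error above 1000 are counted as
  divergences. Convergence is summarized by split-Rhat and effective sample
  size per parameter; a fit with max Rhat ≥ 1.01 is returned with a
  failed-diagnostics flag and a warning, never silently.

Chain seeds derive deterministically from one master seed. Out-of-sample
prediction along a biomass gradient (`predict_along_biomass()`) holds other
covariates at their means, sets the management effect to zero, includes the
country's own slope, and refuses grids beyond the fitted biomass range plus a
10% extrapolation guard. Because every posterior draw's composition sums to
1, the posterior *means* close exactly at each grid point; medians close only
approximately, so both are reported.

## Pyramid classification

Two definitions of a bottom-heavy reef are in circulation and both are
implemented: `herbivore_majority` (bottom-heavy iff the herbivore share
exceeds 50%; ties top-heavy) and `herbivore_vs_piscivore` (bottom-heavy iff
herbivores exceed piscivores; exact ties flagged). The second is the default,
matching the framing in which bottom- versus top-heaviness contrasts the base
and apex of the food web. The rules agree whenever herbivores or piscivores
hold an outright majority; they can disagree when no herbivore majority
exists — including invertivore-dominated compositions where herbivores still
exceed piscivores — and the tests verify this characterization exhaustively on
a 0.01-step simplex grid.

## The synthetic-study generator

Real survey data for this kind of analysis are multi-country compilations that
cannot be shipped with a package, so `reefnutro` generates complete studies
with known ground truth. The defaults are the conditions the package treats as
its study design: 4 countries × 75 sites, 1–8 transects per site (median 3)
with dimensions drawn from {5×50, 10×50, 2×30} m at 79/14/7% weights, a
541-species trait pool, and site fishable biomass log-uniform over
10–6000 kg ha⁻¹.

The trait pool emulates the structure observed in reef fishes: log-normal
maximum lengths by trophic group; growth coefficients declining with maximum
length as a power law ($K_{max} = 8.9\,m_g\,L_{max}^{-0.9}\,e^{\varepsilon}$,
$\varepsilon \sim N(0, 0.4)$, clipped to the admissible range) with diet
multipliers $m_g$ (scrapers 1.6 down to piscivores 0.6) because growth in
this fauna is structured by diet as well as size — without the diet term the
herbivore–piscivore growth contrast is too weak for group-level turnover to
behave realistically; calcium, iron and zinc declining with body size,
selenium increasing, vitamin A and omega-3 independent of both (a
`nutrient_size_links = FALSE` switch removes the links for null-association
studies). Small planktivores/omnivores are flagged as damselfish and some
large piscivores as elasmobranchs so the exclusion filters have real work to
do; contaminated rows (flagged taxa plus sub-5 cm fish) are injected at a
configurable rate (default 5%).

Site compositions are drawn from the same hierarchical Dirichlet model the
fitter assumes (the well-specified case), with true parameters in the
configuration. The default fixed effects encode the qualitative structure of
fished reefs: herbivores dominate on average (intercepts +0.8/−0.8 on the
softmax scale), the piscivore share rises with biomass (+0.5) and depth,
herbivore share rises with coral and macroalgal cover and falls on rubble.
Residual precision defaults to $\phi = 50$ — site compositions are averages
over ~3 transects, so their residual scatter (shares ±~0.07) is tighter than
raw transect compositions — and the group-effect scales default to 0.1,
consistent with management effects that are real but weak. Benthic covers come
from a six-part Dirichlet (five tracked groups plus the unclassified
remainder) with one regime boosted per site.

Surveys realize those targets by drawing individual fish per trophic group
until the group's biomass budget on the transect is filled. Sizes come from
the species' unconditional distribution (a beta(3, 2) over 5 cm to
0.95 L_max, putting most biomass in adult size classes); the fish that crosses
the remaining budget is admitted with probability `remaining/mass`, which
keeps the expected realized biomass on target without biasing rare groups
toward implausibly small individuals, and a shared overshoot allowance (10%
of the transect budget) bounds the lumpiness a single large fish can add.
Realized site biomass lands within ~15% of target at default effort.

What the generator does *not* emulate: real species identities and phylogeny,
observer and detectability error, size-spectrum truncation by fishing,
spatial autocorrelation among sites, temporal revisits, and any systematic
mismatch between the composition model and nature (an optional
logistic-normal mode would be the place to study misspecification; the
current generator is well-specified by design). Passing tests therefore
demonstrate internal consistency and estimator correctness — not that the
model is right for any particular reef system.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle: one-day
growth increments against numerical ODE integration (relative tolerance 1e-6
over 1000 random parameter triples spanning the admissible growth-coefficient
range); production and nutrient rates against brute-force per-individual
loops; site aggregation against independent group-by means; the Dirichlet
log density against direct log-gamma arithmetic and Monte-Carlo integration
to 1 within three standard errors (10⁵ uniform-simplex draws, including a
boundary-concentrated α = 0.5 case whose importance weights are heavy-tailed);
and conservation laws (contributions sum to 100%, invariance of turnover and
contributions to a tenfold count rescaling).

Estimator checks use simulation at sizes chosen to balance power against a
test suite that runs in minutes: MAP recovery of all 16 fixed effects within
±0.15 on the standardized scale in ≥18 of 20 replicates at 300 sites and 3
countries; one full HMC fit (4 × 3000) with max Rhat < 1.01; interval
coverage and zero-signal calibration at 5 replicates each; sign recovery of
strong effects (|β| ≥ 0.3) through the complete survey pipeline at 150 sites
× 5 replicates; and an end-to-end regime test in which a strongly
herbivore-dominated configuration (intercepts ±2.5) yields >90% bottom-heavy
classifications for biomass, turnover and the five mineral/omega-3 services
across 200 sites. Turnover is the tightest of these: group-level turnover is
a ratio, so sites where a group is represented by one or two individuals
carry noisy turnover shares, and the bottom-heavy fraction for turnover sits
just above the 90% line rather than near 100% like the other services.

## Known limitations

* Production is potential, not realized: no mortality, no catch.
* A single edible fraction and a single set of reference intakes apply to all
  species; cooking and processing losses are out of scope.
* The Dirichlet precision is a single scalar; per-category precision and
  model comparison (LOO/WAIC) are out of scope.
* MAP scale estimates for group effects are not interpretable (see above);
  use MCMC when the hierarchy itself is of interest.
* Binned lengths make individual masses uncertain in ways the midpoint rule
  only averages out; analyses sensitive to the largest size classes should
  check the lower-edge convention as well.
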