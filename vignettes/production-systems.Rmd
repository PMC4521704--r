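---
title: "Mapping extensive and intensive monogastric production systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping extensive and intensive monogastric production systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpsmap)
```

## The problem

Global livestock maps report how many chickens or pigs sit in each pixel,
but not *how* they are raised. A density of 10,000 birds per km² means
something very different when spread over a thousand backyards than when
concentrated in one industrial unit — for disease risk, antimicrobial use,
nutrient loading and the livelihoods of smallholders. `lpsmap` splits a
gridded total stock layer into production systems: extensive (backyard,
scavenging-fed, minimal biosecurity), and intensive (confined, purchased
feed, market-oriented), with an intermediate semi-intensive tier for pigs.

The key empirical regularity exploited is economic: the share of animals
raised extensively falls from near 1 in poor economies to near 0 in rich
ones, and national GDP per capita (in purchasing power parity, so that
incomes are comparable across countries) predicts that share well. The
package therefore has two halves: a national-level statistical model of
system shares as a function of income, and a spatial allocation that turns
those shares into per-pixel system maps with exact mass conservation.

## The share model

Let $g$ be the log10 GDP per capita (PPP) of an administrative unit — a
country, or a province for very large, internally heterogeneous countries.
The proportion of extensively raised chickens follows a logistic curve

$$P_{ext}(g) = \frac{1}{1 + e^{4\mu(\lambda - g) + 2}},$$

parameterised so that $\mu$ is the slope of the curve at its midpoint
(share $1/2$, attained at $g = \lambda + 1/(2\mu)$) and $\lambda$ positions
the transition on the income axis. At $g = \lambda$ the share equals
$1/(1+e^2) \approx 0.119$. Fitted $\mu$ is negative: richer countries raise
fewer animals extensively. The intensive chicken share is the complement
$1 - P_{ext}$.

Pig systems use three tiers, and two bounded curves:

$$P_{ext}(g) = \frac{\alpha_{ext}}{1 + e^{4(\mu_{ext}/\alpha_{ext})(\lambda_{ext} - g) + 2}}, \qquad
  P_{int}(g) = 1 - \frac{\alpha_{int}}{1 + e^{4(\mu_{int}/\alpha_{int})(\lambda_{int} - g) + 2}},$$

with the semi-intensive share as the residual $1 - (P_{ext} + P_{int})$.
The $\mu/\alpha$ scaling preserves the midpoint-slope interpretation of
$\mu$: at the half-range point the extensive curve has slope exactly
$\mu$, and the intensive curve slope $-\mu$ (it is the mirror of a
descending curve). With $\alpha = 1$ the pig extensive curve reduces
exactly to the chicken curve.

The printed intensive form above has range $(1-\alpha_{int},\, 1)$: at low
income it floors at $1-\alpha_{int}$ rather than falling to zero, which
sits oddly with reading $\alpha_{int}$ as the *maximum* attainable
intensive share. Because the intent is ambiguous, `p_int_pig()` implements
both readings — `as_printed` (the formula above, the default) and
`bounded` ($\alpha\,e^u/(1+e^u)$, range $(0, \alpha)$, evaluated as
$\alpha/(1+e^{-u})$ for numerical stability) — selectable everywhere the
curve is used, and the test suite exercises both. We deliberately do not
guess which was meant.

If the two fitted pig curves overlap enough to drive the semi-intensive
residual negative, [shares_pig()] clamps it to zero and renormalises the
extensive and intensive shares proportionally (with a warning); the three
shares then still sum to one.

### Fitting

Parameters are estimated by nonlinear least squares on the observed
national shares (bounded Levenberg–Marquardt, `minpack.lm::nls.lm`,
cost tolerance $10^{-10}$), with $\alpha$ constrained to $(0, 1]$ and no
sign constraint on $\mu$ — the direction of the curve is an empirical
outcome, not an assumption. Starting values are $\mu = -1$, $\lambda$ at
the median observed $g$, and $\alpha$ anchored to the relevant observed
extreme (the largest share for ceiling-type curves; one minus the smallest
share for the floor-type printed intensive form). Because the likelihood
surface in $\alpha$ is flat near its bound and the optimizer can stall
there, three-parameter fits are multi-started over a few $\alpha$ values
and the converged solution with the lowest residual sum of squares is
kept. Non-convergence is flagged, not thrown, so ensemble callers can
discard failed replicates. Standard errors come from the optimizer's
Gauss–Newton approximation; when a parameter sits on a bound (which zeroes
its row of the returned Hessian) they are recomputed from a
finite-difference Jacobian with a pseudo-inverse.

### Stock-weighted bootstrap

A country with ten billion birds should constrain the global curve more
than an island state with ten thousand, and the observed shares are of
very uneven quality. Both concerns are addressed by a Monte-Carlo
bootstrap: 1,000 replicates, each refitting the curve on 25 units drawn
with replacement with probability proportional to national stock. Units
without an observed share receive the median of the per-unit replicate
predictions. Units *with* an observed share keep it only if it lies inside
the 1st–99th percentile envelope of their replicate predictions; values
outside — typically from informal sources — are replaced by the nearer
envelope bound. Percentiles use linear interpolation between order
statistics (R's default type 7). Replicates whose fit fails or does not
converge are discarded and counted (never refilled, so the effective
ensemble can be smaller than 1,000); if fewer than half converge the
ensemble is rejected outright. All resampling flows from a single seed, so
runs are bit-reproducible.

## Spatial disaggregation

Inputs are co-registered lat/long grids: total stock (head per pixel),
human population, an urban flag, elevation, slope and permanent snow/ice,
plus a unit-id grid assigning pixels to admin units. All operations are
resolution-agnostic; nothing assumes the 5 arc-minute grid of the
reference datasets.

1. **Suitability mask.** Pixels above 4,750 m elevation, steeper than 40 %
   slope, urban, or under permanent snow/ice are excluded from production.
   "Above" is strict: a pixel at exactly 4,750 m remains suitable. Nodata
   in any layer makes a pixel unsuitable.
2. **Rural population.** Population on suitable, non-urban pixels; the
   ancillary layer over which extensive stock is spread.
3. **Harmonisation.** Each unit's gridded total is rescaled by a single
   factor so its pixel sum equals the unit's reported stock (idempotent;
   an error if a unit reports stock but has no gridded animals).
4. **Extensive allocation.** The unit's extensive stock
   ($P_{ext} \times$ total) is distributed proportionally to rural
   population — every rural person accounts for the same number of
   backyard animals within a unit.
5. **Commercial by difference, with overflow correction.** Commercial
   stock is total minus extensive. Where allocation exceeds the gridded
   total (rural pixels with few recorded animals), the total is raised to
   the extensive value, and the accumulated deficit is removed pro-rata
   from the unit's remaining commercial pixels. One pass suffices: the
   extensive layer is fixed and commercial values only shrink, so no new
   overflow can appear — a post-check asserts non-negativity anyway. If
   the deficit exceeds the unit's entire commercial stock the function
   errors rather than silently truncating, because conservation is the
   module's contract. Conservation is verified per unit to a relative
   $10^{-6}$ (achieved: machine precision).
6. **Pig split.** The commercial pig layer is divided pixelwise into
   semi-intensive and intensive according to the unit-level share ratio —
   semi-intensive production is not assumed to follow rural population.

Animals remain fractional throughout; rounding would break exact
conservation and is left to any export step. The per-unit ledger
(`stock_total`, the three system sums, overflow deficit and pixel count,
relative error) is emitted with every run, making the conservation claim
checkable rather than asserted.

## The synthetic world

Real inputs are multi-gigabyte global rasters; the package instead ships a
generator that reproduces the *statistical structure* the method relies
on, so every stage is testable end to end in seconds:

* GDP per capita log-uniform over 500–60,000 USD, spanning the extensive →
  intensive transition;
* stocks log-normal (meanlog $\log 2\times10^6$, sdlog 1.8), giving the
  heavy-tailed weighting the bootstrap is designed for;
* true shares from the logistic curves (chicken $\mu=-1.2, \lambda=3.9$;
  pig extensive $\mu=-0.7, \lambda=3.9, \alpha=0.9$; pig intensive
  $\mu=-0.8, \lambda=4.0, \alpha=0.95$ — placed so over 90 % of chickens
  are extensive below \$1,000 and the pig transition spans roughly
  \$1,000–30,000, and so the semi-intensive residual stays non-negative);
* observed shares for 45 % of units (comparable to the real data-mining
  coverage of 86/205 and 97/205 countries), with Gaussian noise on the
  proportion scale clipped to $[0,1]$;
* per-unit 40×40 rasters: log-normal rural population with blob-shaped
  urban cores (~8 % of pixels, 50× denser), ~5 % unsuitable terrain, true
  extensive stock proportional to rural population and true commercial
  stock in a few high-density clusters — mimicking the observed spatial
  clustering of industrial production.

What the generator does *not* emulate: real geography and neighbour
effects, the error structure of data-mined shares (which is unknown),
peri-urban gradients between city and countryside, and any correlation
between GDP and raster structure beyond the share curves. Passing recovery
tests on this world therefore demonstrates the correctness of the
machinery — curves recovered to optimizer tolerance on clean data, final
shares correlating with truth at $r \ge 0.95$, extensive patterns at
$r \ge 0.9$ within units, exact conservation — not the real-world validity
of the GDP relationship, which can only come from comparisons against
census data.

Default problem sizes (60 units, 40×40 pixels each, 1,000 bootstrap
replicates) keep a full two-species validation run around ten seconds while
leaving every statistical feature intact; they are the sizes used by the
validation script and the test suite.

## A worked example

```{r example, eval = FALSE}
w <- simulate_world(world_spec("pig", n_units = 60, noise_sd = 0.03, seed = 5))
res <- run_pipeline(pipeline_config("pig", w$countries, w$bundle, seed = 9))
res$disaggregation
#> disaggregation [pig]: 60 units, max conservation error 2.76e-16, 14019 pixels overflowed
head(res$shares[, 1:4], 3)
#>   unit_id        p_ext     p_sint     p_int
#> 1       1 5.401123e-01 0.20116152 0.2587262
#> 2       2 5.336406e-02 0.03879413 0.9078418
#> 3       3 2.628479e-06 0.02871572 0.9712817
```

The ledger in `res$disaggregation$ledger` shows, for every unit, the stock
total and the three system sums; the overflow columns report how much
commercial stock had to be re-spread. Overflowed pixels are common —
any unit whose predicted extensive share exceeds the share embedded in its
total layer overflows in pixels with no commercial animals — and are
exactly the situation the pro-rata correction exists for.

## Known limitations

* GDP per capita is the only covariate; countries with similar income but
  different agricultural histories or policies get identical predicted
  shares. Errors of this kind shift whole units, not the within-unit
  pattern, which is driven by rural population.
* The rural/urban dichotomy ignores peri-urban gradients; extensive stock
  near large cities will tend to be overestimated.
* The two pig curves are fitted independently; nothing enforces
  $P_{ext} + P_{int} \le 1$, and the residual clamp is a repair, not a
  model.
* The `as_printed` intensive form cannot predict an intensive share below
  $1 - \alpha_{int}$ even for the poorest units; use `bounded` if a zero
  floor is wanted.
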