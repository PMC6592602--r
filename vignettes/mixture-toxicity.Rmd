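---
title: "Metal mixture toxicity and population dynamics in C. elegans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal mixture toxicity and population dynamics in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nematox)
```

## Scope

`nematox` analyses toxicity experiments in which *C. elegans* is
exposed to Zn, Cu and Cd singly and in mixtures, at two organisational
levels: short-term adult mortality (24–48 h) and multi-generation
population growth in liquid culture (10–12 days). This vignette is the
package's account of the models it implements, the parameters that
matter, the numerical choices, and what its synthetic-data generator
can and cannot stand in for.

## Dose–response model

All graded effects are modelled by the two-parameter log-logistic

$$y(c) = 100\,\frac{(c/EC_{50})^{\beta}}{1 + (c/EC_{50})^{\beta}},$$

with `y` a percentage in [0, 100), `EC50` in mg/L and `β` a
dimensionless slope on the log-concentration scale. Concentrations are
carried on a metal-ion basis (the bundled LC table's mg/L↔mM pairs are
consistent with the atomic masses Zn 65.38, Cu 63.546, Cd
112.414 g/mol, not salt masses); mg/L is the canonical internal unit
and conversions happen at the boundary via `convert_concentration()`.

Two fitting routes exist. `fit_two_point()` solves the two-parameter
curve exactly through two (concentration, effect) points — the natural
construction when only two LC levels are reported, as for Cu and Cd
(LC5 and LC20). `fit_loglogistic()` minimises squared effect residuals
over `(log10 EC50, log10 β)`; the log parameterisation enforces
positivity without constrained optimisation, and a small Nelder–Mead
multistart around the two-point fit through the extreme doses guards
against local minima. With exactly two interior points the least-squares
fit reproduces the exact construction. The five bundled Zn levels turn
out to be mutually consistent with a single curve (EC50 ≈ 51.7 mg/L,
β ≈ 0.818, residual SS ≈ 1e-6), so the two routes agree for every
bundled metal. Reported spreads in LC tables are carried as annotation
only; confidence intervals on LC estimates are out of scope.

## Mixture models and interaction classification

Two reference models predict the effect of a mixture with component
concentrations $c_i$:

* **Concentration Addition** (shared mode of action): the effect $y$
  solves $\sum_i c_i / [EC_{50,i} (y/(100-y))^{1/\beta_i}] = 1$. The
  left side is strictly decreasing in $y$, so the root is unique;
  `predict_ca()` finds it by bisection on the bracket
  $[10^{-9}, 100-10^{-9}]$ percent with $10^{-10}$ absolute tolerance —
  deterministic, no randomness. Each component uses its own slope
  ($1/\beta_i$ in the exponent), the standard generalisation that
  reduces correctly to the single curve at $n = 1$ and preserves sham
  additivity (a compound mixed with itself predicts the undivided
  dose's effect); a strict shared-slope mode (`shared_beta`) is
  available for the reading in which one β is common to all components.
* **Independent Action** (unrelated modes of action): survival
  probabilities multiply,
  $y = 100[1 - \prod_i (1 + (c_i/EC_{50,i})^{\beta_i})^{-1}]$, in
  closed form.

Observed replicate effects are compared against each model's predicted
constant by the one-sample Wilcoxon signed-rank test: zero differences
are discarded (classic zero handling), the exact null distribution is
used whenever the absolute differences are untied (so with six
informative replicates all on one side the one-sided p is exactly
1/64 = 0.015625), and direction is established by two one-sided tests
at level α each. The call is *synergistic* only when observed effects
are significantly above **both** predictions, *antagonistic* only when
significantly below both; discordant directions collapse to
*additive*. Classification is done per time point (24 h and 48 h
separately), and no multiplicity correction is applied across the Zn
levels of a mixture series — each mixture is reported on its own, which
matches how such series are usually tabulated; users needing family-wise
control can adjust the returned p-values.

## Population endpoints and dilution bookkeeping

Long assays keep counts tractable by transferring wells to fresh medium
every 36 h and splitting them in two (a 64-fold cumulative reduction by
day 10); fast-growing control wells are stepped up to 2048-fold by day
10 (`lc20_control_schedule()`). `cumulative_dilution_factor()` is the
running product of split divisors, and counted abundances are
multiplied by it (`reconstruct_population()`) before endpoint
computation — reconstructed populations reach the 10^4–10^6 range that
the heavy dilution implies. A flag allows operating on raw counts
instead.

Three endpoints summarise a population series: the trapezoid-rule area
under the population-vs-time curve (via `pracma::trapz`), the maximum
population attained, and the end population. The default integrand is
`log10(N + 1)`: the log scale reflects multiplicative growth, and the
pseudo-count keeps extinct wells (N = 0, which Cd-exposed populations
reach) finite; base and transform are switchable. Ties for the maximum
are broken by the earliest day, reading "maximum attained during the
exposure" as first attainment.

Group comparisons follow standard practice: one-way fixed-effects ANOVA
with Tukey HSD over all pairs and Dunnett many-to-one comparisons
against the control (single-step multivariate-t adjustment via
`multcomp`); Kruskal–Wallis with tie correction plus pairwise rank-sum
tests, Bonferroni-multiplied and capped at 1, for mortality series.
Body-length trends are summarised by per-treatment ordinary
least-squares slopes (mm/day) with slope differences estimated from the
day × treatment interaction of a two-treatment regression. Repeated
measures within wells are thereby treated as independent — a deliberate
simplification: a random-intercept mixed model would be the fuller
treatment of the within-well correlation, but the fixed-effects
slopes-and-contrasts scheme keeps every quantity closed-form and is
what the package tests validate. Degenerate inputs are defined rather
than left to error: all-identical observations yield F = 0 (or H = 0)
with all p-values 1.

## The population simulator

`simulate_population()` advances a single well on a 1 h time step with
six classes: egg, L1–L4, adult. Defaults, chosen once as realistic for
20 °C liquid culture:

| parameter | default | rationale |
|---|---|---|
| stage durations (h) | egg 14, L1 16, L2 12, L3 12, L4 18 | 72 h egg-to-adult, development through four larval stages in ~3 days |
| maturation lag | 24 h | newly molted adults first grow to the ~1.06 mm egg-laying size; with development this gives a 3–4 day generation time |
| fecundity | 50 eggs/adult/day over a 4-day fertile window | of the order of the ~250–300 self-fertilised brood; keeps multi-generation control wells in the observed 10^4–10^6 range |
| post-fertile lifespan | 12 days | adults live on 10–15 days after reproduction |
| stage lengths (mm) | 0.05, 0.25, 0.37, 0.50, 0.65, 1.06→1.5 | 0.37 mm at first molt, 1.06 mm at egg-laying onset, adults up to 1.5 mm |
| stage sensitivity | egg 0.2, L1 2, L2 1.8, L3 1.5, L4 1.2, adult 1 | larvae are more metal-sensitive than adults; eggs are shell-protected; adult = 1 keeps the LC tables (determined on adults) unscaled |
| founders | 10 adults/well | the standard inoculum |

Lethality enters as a constant per-hour hazard
`h = −log(1 − y/100)/24` reproducing the 24 h mortality `y(c)` of the
exposure; per hour each individual dies with probability
`1 − exp(−h·s)` with `s` its stage sensitivity. Mixture hazards combine
by rule: `IA` adds single-compound hazards (competing risks — survival
over the window is exactly the IA product), `CA` uses the hazard
reproducing the CA effect of the instantaneous mixture, and
`protective_zn_cd` scales Cd's effective concentration by the U-shaped
factor `g(z)` of `zn_protection_factor()` while Zn's own hazard acts in
full. `g` is a smooth product of a protection-onset saturation
(half-maximal at the Zn LC5) and an overload roll-off (Hill steepness 4
around 1 mM Zn ≈ the Zn LC60), normalised so its minimum is
`g_min = 0.25` near the Zn LC40 — a phenomenological encoding of
Zn-inducible detoxification (cdf-2-like transporter induction) that
saturates at high Zn; it is not a toxicokinetic model.

Sub-lethal effects share the lethal dose scale: with `y` the
24 h-equivalent mortality of the exposure, stage durations are
multiplied by `1 + 3·y/100` and fecundity by `max(0, 1 − 3·y/100)`.
The multipliers are declared assumptions (no quantitative
development/fecundity dose–response was available to fit); their
defaults make ~20 %-lethal exposures produce roughly one new generation
before the population declines, the qualitative pattern seen in such
assays. Transfers subsample every cohort binomially with probability
`1/divisor`; founder adults are tracked separately so founder mortality
is available at 24 h intervals; body-length samples take up to 20 of
the largest individuals per day (mimicking the post-larval measurement
protocol) with 0.03 mm measurement noise. A `deterministic` flag
replaces every draw by its expectation — useful for closed-form checks
such as the day-4 egg budget 10 + 10·5·4 = 210 under zero exposure.

Not modelled: dauer arrest, males, internal hatching, bacterial food
dynamics (food is assumed unlimited), toxicokinetics and tissue
burdens. Simulated wells therefore validate the *analysis chain* —
dilution bookkeeping, endpoint computation, fitting, prediction and
classification recover what the generator put in — and emulate the
statistical structure of the real assays (counts, replicate noise,
founder cohorts, schedules); they are not calibrated reproductions of
any particular measured data set, and passing tests on them does not
certify the biology of real wells.

## Validation problem sizes and numerical choices

The test suite and the acceptance script work at sizes chosen to make
the statistical checks sharp: parameter recovery simulates 24 h
mortality at the five bundled Zn doses with 1000 animals per dose and
refits 100 replicates (the unweighted least-squares design recovers
EC50 within 10 % and β within 15 % in ~94 % of replicates — the
residual failures are the statistical limit of five doses, not
optimiser failures); the CA bisection is checked against a 0.001 %-step
grid scan on 100 random 2–3-component mixtures; trapezoid areas against
brute-force interval sums on 1000 random series at 1e-12; the ZnCd
mixture series (5 Zn levels ± LC20 Cd × 6 replicates × 48 h, 10
founders) is simulated 20 times end to end.

One honest limitation deserves emphasis. With the bundled slopes (β
below 1 for both Zn and Cd) the CA prediction for Zn + LC20-Cd mixtures
is low — 28.6 % at Zn-LC20 and 43.1 % at Zn-LC40 — while the protective
rule leaves Zn's own lethality intact, so the simulator's expected
mixture mortality (≈ 29.7 % and 46.2 % at those levels) sits at or
above CA even at full protection strength. The simulator therefore
reproduces a clear, U-shaped mortality *deficit against the IA
prediction* (≈ 6 points at Zn-LC5–LC40, shrinking below 1 point at the
Zn-overload level), but not a deficit against *both* models at
intermediate Zn; real assays that show mortality significantly below
both predictions imply mutual protection (Zn toxicity also mitigated in
the mixture), which this generator deliberately does not encode. With
six replicates of 10 founders, binomial noise (sd ≈ 15 points) further
means only large deficits could ever reach signed-rank significance.
The unit tests assert the IA-deficit signature; an end-to-end
"antagonistic against both models" recovery is not attainable under
this construction and is reported as such.

Other numerical choices: effects are percentages throughout, never
fractions; the CA solver refuses non-bracketing inputs with a named
error and returns 0 by convention for all-zero mixtures; `wilcox.test`
falls back to the normal approximation only when tied absolute
differences make the exact distribution unavailable; per-well seeds for
generated experiments are drawn once from the experiment seed, so a
fixed seed reproduces every CSV byte for byte.
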