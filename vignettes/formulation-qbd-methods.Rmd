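---
title: "Methods: Quality-by-Design development of floating minitablets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Quality-by-Design development of floating minitablets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formuqbd)
```

`formuqbd` implements, as reusable and tested code, the analysis chain used
to develop directly compressible gastroretentive (floating) minitablets:
powder scoring, constrained mixture design, multi-response optimization,
dissolution kinetics, compaction analysis, and an oral-absorption
pharmacokinetic simulation with validation metrics. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical and
design choices that were genuinely open.

## SeDeM powder scoring

The SeDeM expert system converts 12 measured powder parameters into radius
scores $r \in [0, 10]$ via fixed linear factors (e.g. Carr's index $v/5$,
cohesion index $v/20$, angle of repose $10 - v/5$). Parameters are grouped
into five incidences (dimensions, compressibility, flowability,
lubricity/stability, lubricity/dosage). Summary indices:

* **IP** — fraction of radii at or above 5;
* **IPP** — mean radius (parametric profile index);
* **IGC** — $\mathrm{IPP} \times f$, the good compression index, with the
  criterion IGC $\ge 5$ for direct-compression suitability.

**Reliability factor.** The factor $f$ corrects for the ratio of the area
of the 12-gon radar polygon to its circumscribed circle. The source study
cites but does not print it; we use the published SeDeM value for a
12-parameter diagram, $f = 0.952$, exposed as an argument of
`build_profile()`. A consequence worth knowing: a powder scoring exactly 5
on every parameter has IGC $= 4.76 < 5$.

**Clamping.** The published table gives acceptable ranges but no
out-of-range behavior; scores are clamped to $[0, 10]$ with a warning. The
bulk-density factor cell is blank in the published table; it is taken as
$10v$, like tapped density, the only reading consistent with the 0–1 g/mL
range.

**Excipient correction.** The fraction of a corrective excipient needed to
raise a deficient radius to a target $R$ (default 5) is
$CP = 100 - \frac{R_E - R}{R_E - R_P} \times 100$. The printed formula is
typeset without brackets; this parenthesization is the only one that maps
$R_P = R$ to $CP = 0$ and $R_E \to R^+$ to $CP \to 100$. When the material
is already at or above the target we return 0 rather than erroring, to
match the zero-correction limit. Published correction percentages for this
drug (e.g. 28.46% for one HPMC grade) cannot be reproduced because the
excipient radii live in unavailable supplementary material; no agreement is
claimed.

## Constrained mixture design

Three functional excipients (HPMC X1, ethylcellulose X2, sodium
bicarbonate X3) vary inside bounds 34–45 / 0–10 / 5–15 % with 41% of the
formulation fixed (drug + lubricant), so the variable total is $T = 59$%.
The feasible region is a convex polygon on the plane $\sum X_i = T$.

**Coding.** The source study never states its component coding, and its
printed cubic equations are typographically garbled (repeated `X1*X2`
terms), so no digit-level coefficient reproduction is attempted anywhere in
the package. The default is L-pseudo coding
$x_i' = (X_i - L_i)/(T - \sum_j L_j)$ — the conventional choice when lower
bounds are active, as they are here for X1 and X3 — with real proportions
($X_i/T$) as an option. The qualitative checks that *are* asserted (sign
pattern of the floating-lag-time equation: $+X_1, +X_2, -X_3$) hold under
both codings.

**I-optimality.** `i_optimal_design()` minimizes the average scaled
prediction variance $\bar v = \mathbb{E}_x[f(x)^\top M^{-1} f(x)]$ over the
region. The exact moment matrix of an irregular polytope is cumbersome, so
the expectation is a Monte-Carlo average over 2000 uniformly sampled
feasible points under a fixed seed — adequate at this dimension and fully
reproducible. The search is point exchange over a candidate set (extreme
vertices, edge midpoints, centroid, axial points) with first-improvement
sweeps in candidate-index order; ties therefore break deterministically.
Replicates are added by duplicating the support points with the highest
prediction variance, which emulates the published 16-run design (11
distinct compositions, 5 duplicated).

**Scheffé models.** Response surfaces are intercept-free Scheffé
polynomials (3/6/7/10 terms for linear, quadratic, special cubic, full
cubic). Because $\sum x_i' = 1$ absorbs the intercept, $R^2$ is reported
against the mean-corrected total sum of squares and the overall F test
uses $p - 1$ model degrees of freedom — the convention of mixture-design
software. `order = "auto"` picks the estimable order with the highest
adjusted $R^2$, mirroring the per-response mixed orders of the source
analysis. Rank deficiency raises an error naming the aliased terms rather
than silently dropping them.

## Desirability optimization

Each response is mapped to $d \in [0,1]$ by linear Derringer–Suich ramps
(shape exponents $s = t = 1$, the Design-Expert default; the study names
goals and importances but no shapes). Overall desirability is the weighted
geometric mean $D = (\prod d_i^{w_i})^{1/\sum w_i}$ with the published
importances (lag time 5, floating time 4, release responses 3). Scaling
bounds default to the observed response ranges, which is exactly what the
published constraint table lists.

An `in_range` goal contributes $d = 1$ inside its bounds and is excluded
from the weight sum while satisfied (Design-Expert behavior; strict
inclusion is a toggle). A violated `in_range` still forces $D = 0$.
Whether the published $D \approx 0.79$ included or excluded its in-range
response is unknowable from the text, so that value is treated as
qualitative only.

The optimizer is an exhaustive 0.5%-resolution grid over the two free
simplex coordinates followed by Nelder-Mead refinement; the test suite
holds it to the grid maximum within $10^{-9}$, and to brute-force vertex
enumeration in single-goal linear cases. With the refit lag/float models
the optimum lands on the ethylcellulose upper bound, consistent with the
selection of the 36.6/10/12.4 blend as optimal.

## Dissolution kinetics

Five models of cumulative release $F(t)$ (% of label): zero order $k_0 t$;
first order $100(1 - e^{-k_1 t})$; Higuchi $k_H \sqrt t$;
Korsmeyer–Peppas $k_{KP} t^n$; Hixson–Crowell $100(1 - (1 - k_{HC}t)^3)$,
clamped at 100%. Fits are least squares with closed-form linearization
starts (log-linear, square-root, log-log regressions) followed by
golden-section or Gauss-Newton refinement, so noiseless generator→fitter
round trips recover parameters to $10^{-6}$. $R^2 = 1 - SSE/SST$.

Two caveats a user should know:

* Korsmeyer–Peppas **nests** Higuchi ($n = 1/2$) and zero order
  ($n = 1$), so "the true model has the uniquely highest $R^2$" cannot
  hold against the power law on data generated from a nested model; the
  tests compare against non-nesting alternatives.
* The power law is conventionally fitted on $F \le 60\%$; the source
  study does not state that restriction, so the default fits the full
  profile and `f60 = TRUE` restricts.

**Mechanism classification** uses the Korsmeyer–Peppas exponent. The
default thresholds are 0.65/0.89 ("paper mode"), because the source labels
$n \approx 0.5$–0.62 as Fickian — inconsistent with the classical 0.45
cylinder threshold, which remains available as `mode = "standard"`.

**Swelling/erosion.** The printed formulas contradict their own symbol
legend (they would yield negative swelling); the conventional orientation
is implemented: swelling $= (W_{swollen} - W_{initial})/W_{initial}
\times 100$, erosion $= (W_{initial} - W_{remnant})/W_{initial} \times
100$.

## Heckel compaction analysis

$\ln\frac{1}{1-\rho_r} = KP + A$, with $\rho_r$ the relative density from
tablet weight and cylinder geometry, and mean yield pressure $P_y = 1/K$.
Real curves have a curved low-pressure particle-rearrangement region; the
study identifies "two regions" visually without stating its fit window, so
`fit_heckel(region = "auto")` scans all contiguous windows of at least 5
points spanning at least 40% of the pressure range and keeps the one with
the highest $R^2$. On synthetic two-phase curves (exponential rearrangement
deviation below ~20 MPa) this recovers the generating slope within 2% in at
least 95 of 100 seeds. The published $P_y \approx 157$ MPa anchors the
synthetic generator, not a numerical target: the raw compression data are
unavailable.

## Absorption-transit pharmacokinetic simulation

`simulate_plasma()` integrates a compartmental-absorption-and-transit
chain: a floating depot held in the stomach for a configurable
gastric-retention time (default 22 h, the total floating time of the
optimized blend) releasing per a user-supplied cumulative release
function; dissolved drug empties (half-time 0.25 h, fasted) into 7 serial
small-intestine compartments (total transit 3.32 h); absorption is first
order with $k_a = 2 P_{eff}/R$ (2.18 h⁻¹ from the tabulated permeability
and a 1.75 cm radius), colonic absorption scaled to 10%; disposition is
two-compartmental with the tabulated $V_c$, $K_{12}$, $K_{21}$, $CL$.
Choices that were open:

* The reference software's transit internals are proprietary; compartment
  counts and transit times use standard CAT values, exposed in
  `gi_params()`.
* The tabulated $K_{12}/K_{21}$ units ("L/h") are read as first-order rate
  constants in h⁻¹, the only dimensionally coherent interpretation.
* Body weight is not printed; it is derived as total/(per-kg) clearance,
  $7.342/0.10354 \approx 70.9$ kg, and exposed as a parameter.
* Released drug is treated as dissolved (release-rate control dominates
  for this soluble salt); a solubility cap is not applied by default.
* After the retention time, the remaining depot releases into the first
  intestinal compartment.

**Numerics.** The system is integrated with an adaptive Dormand–Prince
RK45 scheme (relative tolerance $10^{-8}$); a release jump at $t = 0$
(instantaneous bolus) is applied as an initial condition rather than
differentiated. Mass balance — gut residual plus cumulative absorbed
versus dose × fraction released — is checked at every output point and
must close to $10^{-6}$ of dose, or the simulation errors out. In the
one-compartment limit the simulator matches the closed-form oral solution
to better than 0.1%; halving the tolerance moves Cmax by far less than
0.01%.

**Validation metrics.** Fold error is defined as observed/predicted, but
the printed values (1.03, 0.98) correspond to predicted/observed; both
orientations are exposed (`reported_orientation`) and the discrepancy is
documented, not resolved. %PE is $|obs - pred|/obs \times 100$; relative
bioavailability is the dose-normalized AUC ratio. Because the
extended-release capsule carries twice the immediate-release dose, the
comparisons double the observed IR AUCs, reproducing 97.0%, 3.09/1.90%,
and 1.03/0.98 from the printed exposure values.

"Sustained release" in the acceptance checks is operationalized as a
plasma level at 24 h above 5% of Cmax together with an hours-scale Tmax:
the printed ER metrics themselves imply $C(24h)/C_{max} \approx 8\%$, so a
stricter floor would fail even the published profile. Exact reproduction
of the published Cmax (1.0958 µg/mL) is not claimed — it depends on
proprietary absorption numerics.

## Synthetic data: what it does and does not establish

Generators (`gen_*`) are bit-reproducible functions of their parameters
and a seed. They emulate: internally consistent powder records around
three archetypes (with the deficient cohesion/flow archetype anchored at
the published radii 1.42 and 2.02); Scheffé surfaces with additive
Gaussian noise at the magnitude of the published response tables (e.g.
lag-time sd ≈ 2 s); the five release models with additive noise clipped
to [0, 105]%; Heckel lines with an optional rearrangement phase; and
two-compartment oral plasma curves with proportional noise. Defaults are
the published conditions (16 runs, first-order $k_1 = 0.111$ h⁻¹,
$K = 1/157$ MPa⁻¹, the tabulated disposition).

A green round-trip test therefore establishes internal consistency of
generator and estimator under the assumed noise model — not agreement
with laboratory data, which exist only as figures and summary tables. It
does not emulate inter-laboratory variability, instrument drift,
non-Gaussian assay error, or model misspecification beyond the five
stated kinetic forms.

## Known limitations

* Published cubic release equations are garbled in the source and are not
  used as ground truth anywhere.
* Correction percentages and the IGC = 5.76 of the drug substance depend
  on unavailable supplementary data; the package reproduces the
  arithmetic, not those specific numbers.
* The absorption simulator is a transparent CAT approximation, not a
  re-implementation of any commercial product; agreement with the
  published simulated profile is qualitative (hours-scale Tmax, sustained
  24 h exposure, AUC within the printed range).
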