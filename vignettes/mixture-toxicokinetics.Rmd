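---
title: "Models and methods behind mixtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mixtk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixtk)
```

mixtk analyses in vitro toxicokinetic mixture studies of plant protection
products: cytotoxicity dose-response data of an active substance and its
surface-active co-formulants, bidirectional Caco-2 transwell transport
time series, DPH fluorescence anisotropy readings, and Pgp-Glo ATPase
plates. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, what the synthetic-data generators
emulate, and the known limitations.

## The exponential viability model and relative potency

Cytotoxicity is modelled with the four-parameter exponential model

$$y = a \, [\,c - (c - 1)\,\exp(-b\,x^{d})\,],$$

where $y$ is viability in percent of the solvent control, $x$ the
concentration in mg/L, $a$ the control level (percent), $c$ the maximum
fold change ($a c$ is the lower asymptote; $c < 1$ for a toxic effect),
$b > 0$ the potency in (mg/L)$^{-d}$ and $d > 0$ the steepness. At $x = 0$
the model equals $a$ and for $c < 1$ it decreases monotonically.

`fit_drc()` estimates the parameters by least squares on the
replicate-mean responses. The model is ill-conditioned in $(b, d)$, so
fitting is multi-start Levenberg-Marquardt: $d$ starts in
$\{0.5, 1, 2, 4\}$ crossed with $b$ starts log-spaced over six decades
scaled to the concentration range, relative tolerance $10^{-10}$ on the
parameters and sum of squares. Parameters are optimised as $\log a$,
$\log b$, $\mathrm{logit}\,c$, $\log d$, so positivity and $0 < c < 1$
hold by construction; the package targets cytotoxic declines, not
stimulatory responses, which is why $c$ is confined below 1. Compounds
whose replicate-mean response never falls 10 % below their own control
mean are refused by `fit_drc()` and excluded by `fit_drc_parallel()`:
there is no potency to estimate, and they enter the mixture bookkeeping
with a relative potency factor of 0 rather than being dropped.

`fit_drc_parallel()` fits several compounds jointly with $a$, $c$, $d$
shared and $b$ free per compound. Under this parallel-curve assumption
the dose scaling that maps the reference curve exactly onto compound
$i$'s curve is

$$\mathrm{RPF}_i = (b_i / b_{\mathrm{ref}})^{1/d},$$

the unique definition making "a dose of $i$ is equivalent to
$\mathrm{RPF}_i$ doses of the reference" exact under the model
(`rpf()`). Concentration addition then predicts the mixture response at
active-substance dose $x$ as the reference curve evaluated at the
equivalent dose $x_{eq} = \sum_i \mathrm{RPF}_i \rho_i x$, where
$\rho_i$ is the dose ratio of component $i$ to the active
(`predict_ca()`; `mixture_spec()` fixes $\rho_{\text{active}} = 1$).

### Classifying observed mixtures

Published practice judges additivity by where the observed mixture data
lie relative to the predicted curve. `classify_additivity()` codifies
that reading: the comparison is restricted to concentrations where the
predicted effect is within 10-90 % of the span from $a$ down to $a c$
(outside that window the curve is flat and residuals carry no
information); each biological replicate contributes its mean residual
(observed minus predicted viability); replicate means are tested against
0 with a one-sample t-test at $\alpha = 0.05$. Significantly negative
residuals (data left of / below the curve) give `more_than_additive`,
positive give `less_than_additive`, otherwise `additive`; with no
concentrations in the window the verdict is `indeterminate`. When the
replicate means have numerically zero spread the t-test is replaced by a
direct comparison against a tolerance of $10^{-6} a$, so noise-free data
on the curve are labelled additive rather than by sign of rounding error.

## Transport reduction

Receiver aliquots (200 µL apical, 600 µL basolateral) are removed at 2,
4, 6 and 8 h and replaced with blank medium to maintain sink conditions.
The cumulative transported amount therefore re-credits everything
removed earlier:

$$Q_k = c_k V_r + \sum_{j<k} c_j v_s \quad (\text{mg/L} \times \mu L =
\text{ng, reported in } \mu g).$$

`relative_percent()` expresses $Q_k$ relative to the measured initial
donor amount; values above 100 % are flagged as mass-balance violations.
The efflux ratio is the secretory over the absorptive percentage at the
final matched timepoint, rounded to 3 decimals to match how such values
are conventionally reported (`efflux_ratio()`). `apparent_permeability()`
computes $P_{app} = (\Delta Q/\Delta t)/(A c_0)$ with the flux taken as
the OLS slope of $Q$ versus time over all timepoints — the full 2/4/6/8 h
design rather than a two-point difference. Barrier integrity
(`barrier_qc()`) passes when TEER at 0 h and 8 h is at least 250 Ω cm²
and the FITC-dextran $P_{app}$ is at most $10^{-6}$ cm/s; these
thresholds are conventional Caco-2 acceptance values and are
configurable, and missing measurements yield "not assessed" rather than a
silent pass.

## The inferential layer

Endpoint assays (viability, anisotropy, ATPase) are analysed with a
linear mixed model: fixed treatment effect, random intercept per
biological replicate, residual at the technical-replicate level (REML,
via lme4; variance components are non-negative by construction). Many-
to-one comparisons against the control use Dunnett's multivariate-t
dependence structure (via multcomp) with residual degrees of freedom
$n - p$; the degrees-of-freedom method is a deliberate, documented
choice. When the replicate variance is estimated at its boundary the
mixed fit coincides with ordinary least squares, so a single contrast
reduces exactly to the pooled two-sample t-test. The null family-wise
error rate of this procedure, measured by simulation in the acceptance
script (1000 runs, 3 biological x 6 technical replicates, 7 treatments),
is close to the nominal 0.05.

Transport time courses are compared as curves:
`repeated_measures_compare()` fits treatment x time (time as a factor)
with a random intercept per replicate and tests each treatment's
main-effect plus interaction coefficients jointly against the reference.
The joint Wald statistic is F-scaled with residual denominator degrees
of freedom: at transwell replicate counts (3 inserts per arm) the
chi-square limit was visibly anti-conservative in null simulations,
while the F version holds the nominal rate. P-values across treatments
are Holm-adjusted (`holm_adjust()`, a thin wrapper over
`stats::p.adjust`).

## What the generators emulate

`sim_dose_response()` draws viability as model mean plus an additive
normal biological-replicate intercept (default SD 2 %) plus normal
technical-replicate residual (default SD 5 %), on the standard design of
3 biological x 6 technical replicates over 8 concentrations including
the solvent control — the replicate structure of plate-based WST-1/NRU
studies. It does not emulate plate-edge effects, heteroscedasticity at
low viability, or solvent-control drift.

`sim_transport()` is a discrete-time two-compartment model (fixed
explicit step, 0.01 h; sampling events applied instantaneously at the
scheduled times — stiff solvers are unnecessary at these rates, and the
events must be exact). Three mechanisms embody how surface-active
co-formulants alter transport:

* saturable efflux inhibition: inhibition fraction
  $i = I/(IC_{50} + I)$, efflux activity $e = 1 - i$, effective
  permeability $P(1 + \varphi e)$ secretory and $P(1 - \varphi e)$
  absorptive. With no inhibitor the efflux is fully active (net
  secretion); saturating inhibitor removes the asymmetry;
* micellar sequestration above the CMC: free fraction
  $f_u = 1/(1 + K_{mic}\max(0, S - CMC))$ multiplies the driving
  concentrations;
* parallel first-order ester hydrolysis (rate $k_h$, both compartments)
  to a metabolite transported with its own efflux weight and no
  sequestration.

Mass (parent + metabolite + removed aliquots) is conserved by
construction and checked to $<10^{-6}$ relative. Measurement noise is
multiplicative lognormal on reported concentrations only — plate readers
and LC-MS have scale-proportional error — never on the simulated state.
Defaults ($P = 10^{-5}$ cm/s, $\varphi = 0.55$, $IC_{50} = 15$ mg/L,
standard 12-well geometry) were chosen once so that the uninhibited
scenario shows an efflux ratio near 0.9 at 8 h with roughly a quarter of
the donor amount transported, and a high surfactant dose (80-120 mg/L)
drives it near 0.4 — the qualitative regime of the case studies this
package targets. The simulator is a mechanistic caricature: it has a
single lumped inhibitor/surfactant species, no paracellular pathway, no
intracellular compartment, and is not fitted to any measured time
course, so passing tests demonstrate internal consistency of the
pipeline, not predictive accuracy for real monolayers.

`sim_anisotropy()` constructs polarized intensity quadruples whose
reduction returns the target $r$ exactly at zero noise
($I_{VV} = S(1+2r)/3$, $I_{VH} = S(1-r)/(3G)$, $I_{HV} = G I_{HH}$),
with lognormal noise per intensity; the untreated-cell calibration value
is $r = 0.150$. The instrument G factor is $I_{HV}/I_{HH}$ (horizontal
excitation) by default; `anisotropy(..., g_convention = "printed")`
reproduces sources that print the transposed ratio $I_{VH}/I_{HH}$,
which is almost certainly a typographical transposition but is kept
available for exactness. Whether G is calibrated per session or fixed is
instrument practice; the reduction accepts either (an explicit `G`
overrides the convention).

`sim_atpase_plate()` encodes that luminescence reports *remaining* ATP:
orthovanadate wells (ATPase inhibited) have the highest expected RLU and
define the baseline; untreated wells consume the basal activity;
verapamil wells the stimulated activity; test wells with verapamil the
stimulated activity scaled by the remaining fraction of a Hill
inhibition curve. `atpase_delta_rlu()` inverts exactly at zero noise.

All generators fan a single user seed into independent per-stream child
seeds, so every scenario is bit-reproducible from one integer.

## Reliability of the potency estimate

A practical caution established with this package's own simulations: the
potency $b$ carries units (mg/L)$^{-d}$, so under the $(b, d)$ ridge its
*relative* error is amplified by $|\ln \mathrm{ED}_{50}|$ on the chosen
dose axis. At the case-study scale (ED$_{50} \approx 70$ mg/L) and
realistic noise (residual SD 5 %), the Cramér-Rao bound already caps the
probability of estimating $b$ within 20 % at roughly 0.5-0.65, and the
acceptance script measures about 0.65 — not an optimiser defect but an
information limit. On a dose axis where the ED$_{50}$ is near 1 the same
estimator recovers $b$ within 20 % in over 95 % of simulations, and the
scale-free ED$_{50}$ itself is reliable on any axis; both properties are
asserted in the test suite. Potency *ratios* between compounds fitted in
parallel (the quantity RPFs are built from) are unbiased and precise
(about 4 % SD per simulated study at residual SD 2 %). Conclusions that
depend on $b$ alone at an arbitrary unit scale should be drawn via
ED$_{50}$ or RPFs instead.

## Problem sizes and determinism

The packaged simulation studies use 200 runs for recovery and classifier
power, 100 for ratio recovery, 50 plates for the ATPase round trip and
1000 null runs for the family-wise error calibration — sizes at which the
binomial noise on the reported rates is a percent or two, chosen as the
package's own verification budget. Every simulated quantity in the tests
and in `scripts/acceptance.R` derives from an explicit seed; identical
seeds give bit-identical results.

## Known limitations

* The dose-response module covers declining responses only ($c < 1$);
  hormesis and stimulation are out of scope.
* The additivity verdict is a sign test on residuals in the 10-90 %
  window; it does not model dose-dependent departure shapes.
* The transport simulator's mechanisms are qualitative (see above); its
  parameters are not identifiable from the 4-point sampling schedule and
  are meant to be set, not estimated.
* Dunnett adjustment uses residual df; with very few biological
  replicates and large replicate variance this can be anti-conservative
  (Satterthwaite-type df are not implemented).
* Printed relative potency factors of the motivating case studies
  (4.895, 5.678, 9.796, 0.6797) are plausibility anchors only — the raw
  viability tables behind them are unpublished, so they cannot be
  re-derived and are not asserted anywhere.
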