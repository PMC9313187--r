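---
title: "Models and methods behind combindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind combindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combindex)
```

`combindex` analyses two kinds of plate experiment: a single drug titrated
over a log-spaced dose series, and a two-drug checkerboard in which every
pairwise dose combination (plus the zero margins) is measured. This
vignette explains the models, the estimation choices, the outlier screen,
the synthetic-data generator used for validation, and the limitations a
user should keep in mind.

## The effect scale

Everything downstream of normalisation works on the fraction affected,
$f_a = 1 - \text{signal}/\text{reference} \in [0,1]$ (so viability is
$1 - f_a$). Two references are supported: the mean of the untreated wells
(`zero_dose`; dose 0 for a single-drug plate, the $(0,0)$ cell of a grid)
or, for plates without a vehicle control, the largest per-dose mean signal
(`max_response`). With `none` the responses are taken as already being
$f_a$ values (admitting up to 5% measurement slack outside $[0,1]$).
Both ratio-based references make $f_a$ invariant to rescaling the raw
signal, so gain settings of the reader do not matter.

Values outside $[0,1]$ are clipped with a per-value flag rather than
dropped: the probabilistic combination references (Bliss, ZIP) are only
defined for effects in $[0,1]$, so the clipped value is what they consume,
while curve fitting uses the unclipped value (kept in `fa_raw`) so that
wells slightly above the control do not bias the asymptotes.

## Dose–response models

Five models are fitted side by side; all are monotone in dose over
$(0,\infty)$ and have closed-form inverses.

* **median-effect** (Chou–Talalay): $f_a = 1/(1+(D_m/D)^m)$, inverse
  $D = D_m (f_a/(1-f_a))^{1/m}$. The effect rises with dose for $m > 0$.
* **log-logistic family**: $f_a = \min + (\max-\min)/(1+(D/D_m)^m)$ with
  four free parameters, or with $\min = 0$, $\max = 1$, or both fixed.
  The effect rises with dose for $m < 0$.

Both slope conventions are kept exactly as written; the two-parameter
log-logistic and the median-effect curves are pointwise identical under
$m \mapsto -m$, which the test suite asserts to $10^{-12}$. $D_m$ (the
curve midpoint, molar) is always reported; the **absolute IC50** — the
dose with $f_a = 0.5$ — is reported separately and is only defined when
0.5 lies strictly inside the asymptote interval. For the 0–1 models the
two coincide.

### Estimation

The median-effect model is linear after the logit transform,
$\log(f_a/(1-f_a)) = m\log D - m\log D_m$, and is fitted by ordinary
least squares. Replicate values with $f_a \le 0$ or $\ge 1$ cannot enter
the logit and are excluded from this regression; surviving values are
clamped to $[10^{-6}, 1-10^{-6}]$. The log-logistic variants are fitted
by bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) on the replicate-level $(D, f_a)$ pairs — not dose
means — so replicate counts weight the objective naturally. The midpoint
is parameterised as $\log D_m$ (positivity for free), the slope is
bounded to $[-20, 20]$, free asymptotes to $[-0.5, 1.5]$. Starting
values come from the data: $D_{m,0}$ is the dose whose mean effect is
closest to the half-range, the slope sign from the observed direction,
asymptote starts from the data extremes; up to three slope magnitudes
(1×, 0.5×, 3×) are tried until the solver converges, and non-convergence
is reported via the `converged` flag rather than an error. If the free
asymptotes of the four-parameter fit cross, the curve is re-expressed in
canonical order (swap plus slope negation — the same function).

Dose-0 wells never enter a fit; they anchor normalisation only. $R^2$
is computed on the $f_a$ scale over **all** nonzero-dose replicate
points, about the grand mean, so it is comparable across models
(including the median-effect fit, whose regression may have excluded
some points); it can be negative for a fit worse than a constant and is
`NA` when the observed effects have zero variance.

## Outlier screening

Replicate anomalies are screened per dose group (and per matrix cell)
with Grubbs' test: $G = |O - \bar{x}|/s$ for the single most extreme
value, $s$ the sample standard deviation. The p-value inverts the
classical critical-value relation: with
$t = \sqrt{G^2 n(n-2)/((n-1)^2 - nG^2)}$, the two-sided p-value is
$\min(1,\; 2n\,P(T_{n-2} > t))$. The test is two-sided because an
anomalous well can deviate in either direction, and the screen iterates:
remove the flagged value while $p$ is below the user's threshold and at
least three values remain, re-testing after each removal (at most $n-2$
removals per group; groups smaller than three are skipped with a notice).
Screening operates on the normalised $f_a$ values so a single code path
serves single-drug tables and grids, and every tested iteration is
returned in an audit table.

Two numerical facts are worth knowing. First, $G$ is bounded by
$(n-1)/\sqrt{n}$, which at $n = 3$ (1.1547) sits barely above the
two-sided 5% critical value (1.1543): with triplicates the test has very
little power, and with $n = 4$ the power against even a $10\sigma$
contaminant is only about 60% — adding a fourth or fifth replicate buys
far more detection power than loosening the threshold. Second, the
$2n$-factor (Bonferroni) inversion is essentially exact against the
Monte-Carlo null of $\max|G|$ at the thresholds users work with (0.05,
0.10) — the test suite checks agreement to 0.005 — but saturates near the
attainable maximum of $G$ for $n = 3$, where deeper tail probabilities
are smaller than the formula reports.

## Combination index models

Classification is synergy for CI < 1, antagonism for CI > 1, additivity
at CI = 1; since exact equality is measure-zero on data, an optional band
$[1-\varepsilon, 1+\varepsilon]$ can widen "additive" (default
$\varepsilon = 0$, the literal rule — reports always print the CI values
so any band can be applied after the fact).

The three effect-based models compare the observed combined effect with
references built from the margin effects *at the same doses* — the
factorial grid guarantees the doses match, so no interpolation is ever
performed. The two dose–effect-based models need fitted margin curves,
and both margins must use the **same** model (enforced); `"auto"` picks
the model with the highest mean $R^2$ across the two margins. For Loewe,
the equivalent doses $A$ and $B$ invert the fitted curves at the observed
combined effect. An observed effect outside a curve's attainable range
cannot be inverted; in the default `lenient` mode it is clamped into the
range shrunk by $\delta = 10^{-4}$ and flagged (checkerboard corners
routinely exceed the single-drug asymptotes, and dropping them would
silently bias the surface summary), while `strict` mode leaves such cells
missing with a recorded reason — never silently imputed. ZIP evaluates
the fitted curves at the combination's own doses and combines them as
independent probabilities; the curve predictions are clipped to $[0,1]$
first so the union stays a probability.

Useful invariants, all asserted in the tests: the HSA and Bliss
references never exceed response additivity; every model is symmetric
under swapping the two drugs; a noiseless Bliss-independent grid scores
Bliss CI = 1 on every cell and a noiseless sham (dose-additive
self-combination) scores Loewe CI = 1; and when the fitted curves
interpolate the margins exactly, ZIP reduces to Bliss.

## The synthetic-data generator

The generator emulates a fluorescence-viability checkerboard: 7 nonzero
doses per drug at half-log spacing centred on each drug's own midpoint,
triplicate wells, and the mandatory zero margins — the dose design of a
typical validation experiment. Raw signals are
$\text{ref}\cdot(1 - f_{a,\text{true}}(D)) + N(0, \sigma\cdot\text{ref})$
with a default reference of 1000 counts and $\sigma = 0.02$ on the
$f_a$ scale — additive Gaussian noise, which is a fair first-order model
of plate readers at moderate signal. Interaction rules: Bliss-independent
surfaces combine the margin effects as independent probabilities;
dose-addition surfaces evaluate drug A's curve at the A-equivalent
combined dose $a + \rho\kappa b$ (potency ratio $\rho = D_{m,A}/D_{m,B}$,
requiring both drugs to share a curve shape, which the generator
enforces), exactly Loewe-additive at $\kappa = 1$, synergistic for
$\kappa > 1$, antagonistic for $\kappa < 1$. Perturbing *potency* rather
than effect keeps the Loewe and Bliss nulls distinguishable — essential
for testing that the five CI models disagree where they should.
Optional contamination lowers the signal of a seeded set of wells by a
chosen multiple of the noise SD (raising their apparent effect), which is
the failure mode seen in practice at low doses.

What the generator does **not** emulate: spatial plate effects (edge
evaporation, drift), heteroscedastic noise, batch effects, or deviations
from the five curve shapes. Passing the simulation-based tests therefore
shows the estimators are correct under clean assay assumptions, not that
real plates meet those assumptions.

## Validation problem sizes and numerical choices

The packaged validation runs use an 8×8 grid (49 interior cells), 200
seeded plates for parameter recovery, a $10^6$-draw Monte-Carlo null per
group size for the Grubbs p-value, 100 contaminated plates for the
screening study (with 4 replicates per dose, the smallest group size at
which Grubbs has usable power), and $10^4$ fuzzed effect triples for the
CI ordering checks. Ties in model ranking are broken by `min` rank;
equality comparisons on CI use explicit tolerances ($10^{-9}$ noiseless
Bliss, $10^{-4}$ sham Loewe, reflecting the extra inversion step).
Doses are treated as molar throughout with no unit conversion; the
configurable `dose_unit` only labels outputs. CSV writers emit
shortest-round-trip decimal representations and readers parse them with
strtod, so write→read cycles reproduce doubles bit-identically.

## Known limitations

No confidence intervals on fitted parameters or CI values (replicate-level
CI distributions are deliberately out of scope); no weighted or robust
regression; no three-drug combinations; the ZIP implementation uses
single-drug curve expectations only (no delta-surface refit); and the
outlier screen is dose-local — a systematically shifted whole curve will
not be flagged.
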