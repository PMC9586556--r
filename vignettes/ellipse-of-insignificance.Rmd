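---
title: "The ellipse of insignificance: geometric fragility analysis for 2x2 trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ellipse of insignificance: geometric fragility analysis for 2x2 trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoi)
```

## The problem

A dichotomous-outcome trial compares an experimental arm ($a$ participants
with the endpoint, $b$ without) against a control arm ($c$ with, $d$
without), $n = a+b+c+d$. Significance is usually assessed with the Pearson
chi-squared statistic

$$\chi^2 = \frac{n\,(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

declared significant at level $\alpha$ when it exceeds the upper-$\alpha$
quantile $\nu_c$ of the $\chi^2_1$ distribution. Many nominally significant
results evaporate if a handful of participants are recoded from event to
non-event — the intuition behind the classic fragility index (FI), which
recodes one arm a participant at a time under Fisher's exact test. The FI
is one-dimensional (one arm at a time), iterative, and factorial-based, so
it scales poorly and says nothing about *simultaneous* miscoding in both
arms.

This package takes the geometric route instead. Recode $x$ experimental
participants from endpoint-positive to negative and $y$ control
participants from negative to positive, giving cells
$(a-x,\; b+x,\; c+y,\; d-y)$ — row margins are untouched, so $x$ and $y$
are pure miscoding displacements. Substituting into $\chi^2 = \nu_c$ and
clearing the (positive) denominator yields a conic

$$A x^2 + B x y + C y^2 + D x + E y + F = 0,$$

which, for any table with positive margins and $0 < \nu_c < n$, is an
inclined ellipse: the **ellipse of insignificance**. Its interior is
exactly the set of displacement pairs under which the recoded table is no
longer significant. The conic value at the origin is $F$, positive exactly
when the unrecoded table is significant, which gives a cheap and exact
significance test consistent with the geometry.

## Derived quantities

* **Nearest point** $(x_e, y_e)$ of the ellipse to the origin, with length
  $f_{min}$: the smallest simultaneous two-arm recoding that erases
  significance. Since participants are whole, the integer bound is
  $d_{min} = \lfloor |x_e| + |y_e| \rfloor$.
* **Axis intercepts** $x_i$ (root of $Ax^2+Dx+F=0$ nearest the origin) and
  $y_i$ (from $Cy^2+Ey+F=0$): single-arm tolerances.
* **Tolerance fractions** $\epsilon_E = |x_i|/(a+b)$,
  $\epsilon_C = |y_i|/(c+d)$, $\epsilon_A = d_{min}/n$: the shares of each
  arm, or of the whole sample, that may be miscoded before significance is
  lost.
* **Test-implied miscoding**: if the endpoint test has sensitivity $s_n$
  and specificity $s_p$, the observed positive count relates to the true
  one by $a = a_o s_n + (a+b-a_o)(1-s_p)$, so the *guaranteed* net
  miscoding is
  $x_m = \dfrac{b(1-s_p) - a(1-s_n)}{s_n + s_p - 1}$ (and analogously
  $y_m$ in the control arm). If $(x_m, y_m)$ falls on or inside the
  ellipse, the observed significance is fully explained by the test's own
  error rates: the result is reported **not robust**.

All of this is closed-form or quartic — no factorials anywhere — so tables
with millions of participants are handled as easily as tiny ones.

## Numerical choices

The stationarity condition for the nearest point, combined with the conic
itself, is a polynomial system whose elimination is a quartic. Rather than
forming the resultant in the original (badly scaled) coefficients, the
solver:

1. normalises the six coefficients by their largest magnitude (the curve is
   unchanged; for $n \approx 10^6$ raw coefficients reach $10^{24}$);
2. translates and rotates to the principal-axis frame via the
   eigendecomposition of the quadratic-form matrix;
3. solves the classical point-to-axis-aligned-ellipse Lagrange quartic in
   the multiplier (roots via `polyroot`), which yields *all four* candidate
   boundary points; degenerate cases with the origin on a principal axis
   are enumerated directly instead;
4. maps candidates back, polishes each with three Newton steps on the
   original two-equation system, and keeps the candidate nearest the
   origin. The full candidate set is retained in the fitted object
   (`$feckup$all_roots`) for inspection.

The relative residual of both governing equations at the solution is
reported and is typically below $10^{-12}$; the validation suite requires
$10^{-9}$, and $10^{-6}$ for the million-participant stress tables.
Quadratics (axis intercepts, per-abscissa conic slices) use the
numerically stable form that avoids cancellation between $-\beta$ and the
discriminant root. Of a quadratic's two real roots the one of smallest
magnitude is reported, ties broken toward the positive,
effect-attenuating direction.

Three conventions are worth stating explicitly:

* **Boundary counts as inside** the ellipse: a displacement that lands the
  statistic exactly on $\nu_c$ removes significance.
* **$\epsilon_E$, $\epsilon_C$ use the continuous intercepts**; the
  integer-floored variants are carried as secondary fields
  (`epsilon_E_int`, `epsilon_C_int`). The continuous convention is what
  reproduces the published worked examples at printed precision.
* **Signs are preserved throughout**: positive $x$ depletes experimental
  positives, positive $y$ inflates control positives; negative solutions
  mean the attenuating direction is the opposite one. The solver does not
  constrain displacements to feasible recodes — feasibility (no negative
  recoded cell) is a *flag* on the report, not a constraint, since an
  infeasible nearest point still bounds what any feasible recoding can do.

For every table with all four margins positive, both axis crossings exist
(the displacement that zeroes the association is always on the feasible
side of the degenerate column-margin line), so the "no crossing" branch —
which would cap the arm's tolerance at 100% with an explanatory flag — is
defensive only.

## The integer polygon

Participants come in whole numbers, so the continuous ellipse can be
replaced by an integer polygon. Two dialects are implemented, because
"an integer polygon around an ellipse" admits both readings:

* `type = "outer"` (default): the convex hull of, for each integer
  abscissa the ellipse spans, the floor/ceiling of the conic's
  $y$-interval endpoints, plus the four lattice corners around densely
  sampled boundary points (sampling is proportional to the perimeter, so
  consecutive samples are well under one lattice unit apart). The result
  provably encloses the whole ellipse.
* `type = "inner"`: the convex hull of the lattice points with conic value
  $\le 0$, i.e. the integer displacements that genuinely remove
  significance — the natural membership oracle.

Vertices are returned counter-clockwise from the minimum-$x$ (then
minimum-$y$) vertex.

## The degenerate branch

A table that is not significant at $\alpha$ needs no recoding at all: the
origin is already inside the insignificance region. The fit then returns
the degenerate solution $(0,0)$, $f_{min} = d_{min} = 0$, all tolerance
fractions zero, and a flag — rather than an error — so batch runs over
mixed inputs behave sensibly. The enclosing polygon, by contrast, is
refused for non-significant tables (the region containing the origin is
unbounded in meaning, not in extent, for the polygon's purpose).

## The classic index, kept as a diagnostic

`classic_fragility_index()` implements the traditional FI: recode events
to non-events one at a time in the higher-event-rate arm (the attenuating
direction) under the two-sided Fisher exact test (conditional
hypergeometric, "sum of probabilities not exceeding the observed table's")
until $p \ge \alpha$. Hypergeometric masses are accumulated on the log
scale, so no factorial ever overflows; the exact test is guarded at
$n \le 10^5$, beyond which the chi-squared framework is the appropriate
tool anyway. Because the exact test and the chi-squared statistic disagree
for small counts, the classic index and $\lfloor|x_i|\rfloor$ can differ;
the validation suite checks they agree within 2 in at least 90% of
moderate random tables and reports (rather than fails) the residual
discordant cases. When both arms could be recoded the implementation
always recodes the attenuating arm; that choice is a documented convention
of this package.

## What the fixture generator emulates — and what it does not

`generate_fixture_tables()` draws two-arm binomial trials: arm sizes
uniform on 20–200 (or 300,000–700,000 in the `"large-n"` regime), a
control event probability uniform on 0.1–0.9, and an experimental
probability either independent (`"significant"`, rejection-sampled to
exceed the 0.05 critical value) or equal to the control one
(`"null"`, and `"borderline"`, rejection-sampled to land within about one
unit of the critical value). The `"large-n"` regime uses rate ratios of
1.01–1.3 on 5–50% baselines, the regime where geometric fragility analysis
is most useful and exact-test methods are unusable.

These are idealised trials: independent Bernoulli outcomes, no
overdispersion, no loss to follow-up, no time-to-event structure, no
informative missingness. Passing property tests on them demonstrates the
*geometry* is right — the conic classifies every feasible integer
displacement identically to the recoded chi-squared test, the nearest
point beats ten thousand sampled boundary points, tolerances shrink
monotonically as $\alpha$ tightens — not that any particular real trial
is well modelled. On real data the method inherits every caveat of the
chi-squared test itself, and dropout-related biases are out of its reach
entirely.

The validation problem sizes are: one hundred random tables scanned over
the full $41 \times 41$ displacement lattice (about 168,000 feasible
points), $10^4$ boundary samples for the optimality check, and three
stress tables with $n$ around $10^6$. These sizes keep the whole suite
comfortably under half a minute while exercising every code path; they are
stated here so they can be scaled up deliberately rather than rediscovered.

## Design choices that were genuinely open

* **Nearest-point solver route.** The elimination could be done by a
  symbolic resultant of the two conics followed by companion-matrix root
  finding. The principal-axis route chosen here solves an equivalent
  quartic but in a frame where the ellipse is axis-aligned and the
  coefficients are $O(1)$ after normalisation; it is the standard
  formulation of point-to-ellipse distance, easier to reason about in the
  degenerate on-axis cases, and measurably better conditioned for the
  $n \sim 10^6$ regime. The Newton polish on the original system is kept
  regardless, so the reported residuals refer to the exact equations, not
  the transformed ones.
* **Outer polygon as the default dialect**, since an enclosing polygon is
  the conservative statement ("every displacement inside this integer
  fence is insufficient evidence"), with the inner hull available where a
  certificate of removal is wanted.
* **Same-test defaulting**: supplying one sensitivity/specificity pair
  applies it to both arms, the common single-assay design; `sens_ctl = NA`
  restricts the characterisation to the experimental arm, in which case
  the verdict point is $(x_m, 0)$.
* **Alpha handling**: every function takes plain `alpha` and derives
  $\nu_c$ internally ($\chi^2_1$ upper quantile via `qchisq`); the fitted
  object records both.

## Limitations

Only 2x2 tables: larger layouts are refused rather than collapsed. The
analysis is built on the uncorrected Pearson statistic — no Yates
correction, no likelihood-ratio variant — because that is the statistic
whose level sets are this conic; results for small cell counts should be
read with the usual caution, and the classic exact-test index is provided
for exactly that comparison. Time-to-event endpoints, loss to follow-up
and redaction bias are outside the model. The robustness verdict treats
sensitivity and specificity as known constants; uncertainty in the test
characteristics is not propagated.

## A worked call

```{r}
fit <- eoi(113, 887, 24, 976, alpha = 0.05,
           sens_exp = 0.75, spec_exp = 0.90, sens_ctl = NA)
fit
```

```{r, fig.width = 6, fig.height = 5}
plot(fit, polygon = TRUE)
```
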