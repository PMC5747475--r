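---
title: "Multi-state modelling of kidney-waitlist trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state modelling of kidney-waitlist trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A candidate on the kidney-transplant waitlist is described at any time by
two clinically pivotal, time-varying characteristics: the calculated panel
reactive antibody percent (CPRA, the fraction of the donor pool against
which the candidate holds antibodies) and the activity status (active
candidates may receive deceased-donor offers; inactive candidates may not).
CPRA is grouped into six categories used by allocation policy — 0%, 1–79%,
80–89%, 90–94%, 95–98% and 99–100% — and crossed with the two statuses,
giving **12 transient states**. Follow-up ends in one of **4 absorbing
outcomes**: deceased-donor transplant, living-donor transplant, death or
removal for deteriorating condition, or removal for other reasons.

Every transient state communicates with every other transient state and
with every outcome, except that an inactive candidate cannot move directly
to deceased-donor transplant (ineligibility for offers). That removes 6 of
the 12 × 15 ordered pairs, leaving **174 allowed transitions**. Note that
the *probability* of deceased-donor transplant from an inactive state is
still positive — the path runs through reactivation — only the direct
*hazard* is structurally zero.

The process is treated as a Markov chain on the clock-forward time scale
(days since listing): the future depends on the past only through the
current state and the elapsed time from listing. The chain may be
time-inhomogeneous; nothing is assumed about the shape of the transition
intensities.

## Estimation

Let $Y_i(u)$ be the number of subjects occupying transient state $i$ just
before day $u$, and $dN_{ij}(u)$ the number of observed $i \to j$
transitions at $u$. The package estimates:

* **Cumulative hazards** (Nelson–Aalen):
  $\hat A_{ij}(t) = \sum_{u \le t} dN_{ij}(u) / Y_i(u)$, with the
  Greenwood-type variance increment
  $dN_{ij}(u)\,(Y_i(u) - dN_{ij}(u)) / Y_i(u)^3$ (a Poisson-type
  increment $dN_{ij}/Y_i^2$ is available as a sensitivity flag).
* **Transition probabilities** (Aalen–Johansen): the finite product
  integral
  $\hat P(s,t) = \prod_{u \in (s,t]} (I + d\hat A(u))$,
  where $d\hat A(u)$ has the Nelson–Aalen increments off-diagonal, minus
  their row sums on the diagonal, and zero rows for absorbing states. All
  transitions observed at the same day enter one factor, which keeps row
  sums exactly 1 and makes the Chapman–Kolmogorov identity
  $\hat P(s,u) = \hat P(s,t)\hat P(t,u)$ hold to machine precision.
* **Variances**: a recursive plug-in propagation per origin row. Writing
  $B = I + d\hat A(u)$ and $p$ for the origin row of $\hat P(s,u^-)$,
  $$V(u) = B^\top V(u^-) B + \sum_i p_i^2\,\mathrm{Cov}(d\hat A_{i\cdot}(u)),$$
  where the increment covariance is the multinomial one with the
  Greenwood-type scaling, and rows of $d\hat A$ are independent across
  from-states because their risk sets are disjoint at any instant. In the
  two-state reduction this reduces *algebraically* to the classical
  Greenwood formula, which the test suite verifies to `1e-12` against a
  closed form and against `survival::survfit`.

Confidence bands are symmetric normal-approximation bands truncated to
$[0,1]$ by default. Log-transformed bands
($p \exp(\pm z\,\mathrm{se}/p)$) are provided behind a flag; whether the
original analyses used linear or log bands is not determinable, so linear
— the common default of established multi-state software — was chosen.

## Censoring schemes around the policy date

The 2014-12-04 kidney allocation system (KAS) revision motivates two
follow-up schemes for earlier registrants: (i) *censor at policy*, cutting
each subject at `policy_date - listing_date` days and converting later
terminal events to censoring, isolating the pre-policy era; and (ii)
*lifted censoring*, following subjects to an administrative horizon. Both
are configuration values, not constants. Truncating the raw records
manually at the boundary reproduces the censor-at-policy fit byte for
byte (an acceptance check), and the two schemes differ only through
events after the boundary.

## Event-history conventions

Decisions taken where registry practice or the data format is silent:

* Fractional CPRA values are floored before categorization (CPRA is an
  integer percent in registry practice); values in (0, 1) map to 0%.
  Configurable breakpoints are supported.
* Same-day updates merge into one combined transition — daily resolution
  is the registry's effective granularity.
* Zero-length intervals are dropped with a warning; a terminal event
  falling exactly on the start of its interval (day 0, or the day of a
  same-day state change) is shifted by half a day so the subject
  contributes risk time.
* Missing CPRA at listing maps to 0% with a logged message.
* Subjects at risk are counted with the left-open convention
  ($t_{start} < u \le t_{stop}$), so a transition at $u$ is made by a
  subject at risk at $u$.

## The cohort simulator

Because the registry extracts behind the original analyses are available
only under a data-use agreement, the package ships a seeded Markov cohort
simulator that plays the role of the data source for development and
validation. It draws from a **piecewise-constant intensity model** on the
174 allowed transitions: holding times by inversion of the piecewise
total exit intensity, destinations proportional to rates at the jump
instant, with optional independent exponential censoring and an
administrative horizon. This family is rich enough to exercise
time-inhomogeneity while admitting an exact oracle: $P(s,t)$ is a product
of matrix exponentials of the per-piece generators
(`true_transition_probability()`, via `Matrix::expm`).

The default `scenario_registry_like()` concentrates initial states on the
two lowest CPRA categories (≈98% of registrants, mostly active), uses
modest inactivation/reactivation rates, elevates death intensity from
inactive states and varies deceased-donor rates with CPRA category. These
rates are illustrative fixtures with realistic orders of magnitude
(events per thousand subject-days), not registry estimates.

Simulated event times are continuous (fractional days) by default so that
estimator-recovery comparisons against the continuous-time oracle carry
no discretisation bias; a `day_resolution = "day"` mode rounds to whole
days to emulate registry granularity. What the simulator does *not*
emulate: covariate-dependent intensities, duration-in-state (semi-Markov)
effects, the allocation mechanism itself, and dependent censoring.
Passing recovery tests therefore validates the estimation machinery under
the model's own assumptions — they say nothing about whether real
waitlist data satisfy those assumptions.

## Validation study designs

Two homogeneous generators are fixed for the quantitative checks, chosen
by power reasoning **before** any test was run and not revisited:

* **Recovery scenario** (sup-norm comparison of $\hat P(0,365)$ with
  $e^{365Q}$ at $n = 5000$, uniform over the 12 origins): with ~417
  subjects per origin, the sup-norm error budget is dominated by the
  diagonal entries, whose binomial standard error is
  $\sqrt{p(1-p)/417}$. Total exit probability by day 365 was set to
  ≈1.2% (rates of order $10^{-5}$–$10^{-6}$/day), giving
  $\sigma \approx 0.005$ and an expected maximum over the 192 transient
  entries around $3.3\sigma \approx 0.016$, comfortably inside the 0.02
  tolerance with low seed-to-seed failure probability.
* **Coverage scenario** (pooled 95% interval coverage of the 48
  (origin, outcome) entries of $\hat P(0,365)$ across 50 replicates at
  $n = 1000$): rates of order $10^{-3}$–$10^{-4}$/day give roughly 8–25
  expected events per cell, the regime where Greenwood-based normal
  intervals are reliable. Pooled coverage lands around 93–95%.

These two goals conflict in a single design — near-exact sup-norm
recovery needs rare events, well-calibrated intervals need many — which
is why two generators are used.

Problem sizes used in the shipped tests (cohorts of 300–5000, 50
replicates at 1000, horizons of 400–1095 days) were chosen so the whole
suite completes in a few minutes while keeping every check in its
informative regime.

## Numerical choices and degenerate inputs

* Report grids are the union of observed event times and requested
  cross-section times; all curves are right-continuous step functions.
* A prediction origin beyond the last observation returns identity
  matrices with a warning.
* An event with an empty risk set is impossible by construction and
  raises an internal error rather than propagating NaN.
* Ties: simultaneous transitions (same day) share one product factor.
* The multivariate standardized difference inverts the averaged
  multinomial covariance over $k-1$ categories; a singular covariance
  falls back to an eigenvalue pseudo-inverse. The published
  standardized-difference column itself is not used as an oracle: the
  printed values (e.g. 0.0053 for a binary variable whose counts give
  0.037 by the conventional formula) are not reproducible from the
  printed counts, so only the counts and percentages are.

## Known limitations

* Estimation is purely nonparametric; covariate adjustment
  (semi-parametric transition models) is out of scope.
* The Markov assumption is maintained throughout; landmark/non-Markov
  dynamic prediction is not implemented, and dynamic predictions given a
  history reduce to conditioning on the occupied state.
* Cohort comparisons report interval overlap descriptively; no formal
  two-sample test is constructed.
* With 174 transitions, sparse cells (high-CPRA origins under realistic
  initial distributions) carry wide intervals; the validation scenarios
  use a uniform initial distribution precisely to exercise all origins.
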