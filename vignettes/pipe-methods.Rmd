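---
title: "Dual-agent dose escalation with independent beta probabilities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-agent dose escalation with independent beta probabilities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipedose)
```

## The working model

A dual-agent phase I trial doses cohorts of patients at combinations
$d_{ij}$ of two drugs, $i = 1,\dots,I$ levels of drug A and
$j = 1,\dots,J$ of drug B, and observes binary dose-limiting toxicities
(DLTs).  The design targets a *maximum tolerated contour* (MTC): the
partition of the grid separating combinations with DLT risk
$\pi_{ij} \le \theta$ from those above the target toxicity level
$\theta$.  Unlike single-agent designs that chase one maximum tolerated
dose, the whole lower frontier of the contour is of interest, and several
combinations may be recommended for phase II.

Each $\pi_{ij}$ gets an *independent* prior
$\pi_{ij} \sim \mathrm{Beta}(a_{ij}, b_{ij})$.  With a binomial
likelihood for the $x_{ij}$ DLTs in $n_{ij}$ patients treated at
$d_{ij}$, conjugacy gives the posterior
$\mathrm{Beta}(a_{ij} + x_{ij},\, b_{ij} + n_{ij} - x_{ij})$ cellwise —
no MCMC anywhere.  This is a **working model**: the independent priors do
not force monotonicity on the risks themselves.  Monotonicity enters only
through the decision layer: the estimated MTC is always one of the
*monotone* binary matrices $C$ (up-sets, i.e. $C[i,j] = 1 \Rightarrow
C[i+1,j] = C[i,j+1] = 1$), of which an $I \times J$ grid has exactly
$\binom{I+J}{I}$ (924 for $6 \times 6$).

Writing $p_{ij} = F(\theta; a_{ij}, b_{ij})$ for the posterior
probability that $d_{ij}$ is tolerable ($F$ the beta CDF), a contour is
scored by the product of independent tail probabilities
$$
w(C) \;=\; \prod_{ij} p_{ij}^{\,1 - C[i,j]} \, (1 - p_{ij})^{\,C[i,j]},
$$
the expected joint posterior gain of classifying each dose on the side
$C$ assigns it.  The modal contour $C^{(m)} = \arg\max_C w(C)$ drives
escalation; normalising $w$ over the monotone set yields a proper
distribution on candidate MTCs used for safety averaging.

```{r contours}
cs <- enumerate_contours(2, 2)
nrow(cs$heights)          # choose(4, 2)
above_mtc_probability(contour_posterior(matrix(0.5, 2, 2)))
```

## Prior elicitation

The trialist states a prior *median* DLT probability and a prior
*strength* (effective sample size $s_{ij} = a_{ij} + b_{ij}$, the number
of pseudo-patients the prior is worth) per combination.
`calibrate_beta(med, s)` solves $F(med;\, a, s - a) = 0.5$ for $a$ by
bracketed root search on $(\varepsilon, s - \varepsilon)$,
$\varepsilon = 10^{-10}\min(1, s)$: the CDF at a fixed point is
continuous and strictly monotone in $a$, so bracketing is robust even at
tiny strengths.  The root is resolved to machine precision deliberately —
several benchmark grids place medians exactly at $\theta$, making
$p_{ij}$ exactly $0.5$ and many contours *exactly* tied; a sloppier
tolerance would turn those ties into arbitrary deterministic choices
driven by solver noise.

Conventional strengths are the **weak prior** $s = 1/(IJ)$ (the whole
grid is worth one patient) and the **strong prior** $s = 1$ per
combination.  The weak prior is the default in the simulator and the
shipped configuration; the strong prior is only advisable when the
elicited surface is trusted, since mis-specified strong priors cost more
in overdosing than they gain when correct.

Partially elicited grids (doses on the believed contour at median
$\theta$, the lowest/highest combinations, single-agent margins) are
completed by `complete_median_grid()`.  The source convention only says
"interpolation"; the scheme here works on the log-odds scale, bounding
each missing cell by the largest anchor it dominates and the smallest
anchor dominating it, placing it between the bounds proportionally to
lattice distance, and finishing with an isotonic sweep over filled cells.
This guarantees values in $(0,1)$, exact preservation of anchors, and a
monotone completed grid whenever the anchors are order-consistent
(inconsistent anchors raise an elicitation error rather than being
silently averaged).

## The escalation policy

Per cohort the decision pipeline (`next_dose()`) is:

1. **Posterior and contour.**  Conjugate update, tail grid $p$, contour
   posterior, modal contour $C^{(m)}$ (ties within a $10^{-12}$ relative
   tolerance broken uniformly at random — the only unbiased choice, and
   reproducible under the trial seed), and the safety grid
   $q_{ij} = \sum_C P(C \mid \text{data})\, C[i,j]$, the probability
   that $d_{ij}$ lies above the MTC averaged over contours.  Averaging
   borrows strength: the $q_{ij}$ are dependent and monotone over the
   grid even though the $p_{ij}$ are independent.
2. **Available box.**  The dose-skipping constraint (neighbourhood: at
   most one level from the current dose per drug; non-neighbourhood: at
   most one level above *any* previously treated dose; or none)
   intersected with the safety rule $q_{ij} < \epsilon$.  An empty box
   terminates the trial — with cohorts at highly toxic grids this is the
   dominant outcome, and a terminated trial recommends no dose.
3. **Admissible doses.**  The *closest* doses to the contour are the
   maximal below-contour and minimal above-contour elements, identified
   **within the available box**.  Computing the frontier inside the box
   (rather than intersecting the global frontier with the box) matters:
   when the box straddles the contour it offers local frontier doses on
   both sides, sustaining the varied experimentation the design needs to
   avoid *rigidity*; and when the box lies entirely below the contour it
   degrades exactly to the *largest* doses of the box, reproducing the
   documented diagonal escalation of the first few cohorts.  The
   *adjacent* strategy instead admits every dose touching the contour's
   staircase curve (a superset of the closest doses), intersected with
   the box; if none falls inside, the same largest-dose fallback applies.
4. **Coherence (optional).**  Restrict to doses on the opposite side of
   the updated contour from the current dose, so a DLT steers down and a
   clean cohort steers up; if that empties the set the restriction is
   dropped.
5. **Selection.**  Sample size at a dose counts pseudo-patients:
   $s_{ij} + n_{ij}$.  `min_sample_size` doses the least-sampled
   admissible combination (ties uniform at random);
   `weighted_randomisation` draws with probability
   $\propto 1/(s_{ij} + n_{ij})$.

Rigidity — the failure mode where a curve-free design cannot move its
contour because experimentation stays on one side — is handled by
construction: a single DLT in a cohort of two at a frontier dose under a
weak prior drops that dose's tail probability below one half, making the
contour that reclassifies it strictly more probable (the ratio test in
the test suite), and the sample-size rules keep both sides of the
frontier in play.

### Recommended phase II doses

At the end of the trial the doses **closest from below** to the final
modal contour (the maximal elements of its below-set) that were
**experimented on** are recommended.  This is the literal conjunction of
the two published conditions.  The alternative reading — maximal elements
*of* the experimented below-set — never returns an empty set when
anything tolerable was tried, but it systematically recommends interior
doses as well and inflates the mean number of recommendations (2.9 vs
the benchmark 2.7 in the reproduction study); the intersection reading
matches the benchmark tables and is retained.  Consequently a trial can
recommend nothing without stopping early (its final frontier was never
dosed); this occurs in under 3% of simulated benchmark trials.

## Safety threshold

$\epsilon$ (default 0.8) is the maximum tolerated posterior probability
of sitting above the MTC.  At the start of a weak-prior trial the
monotone averaging alone pushes $q$ near 1 in the top corner of the grid
(most up-sets contain it), so the constraint already walls off the
highest combinations before any data accrue.  Lowering $\epsilon$ to 0.6
measurably reduces experimentation above the target band (a directional
property test); raising it to 1 disables the constraint.

## The simulator and what it does (not) establish

`simulate_trial()` runs the policy against a known truth grid, drawing
cohort DLT counts $\sim \mathrm{Binomial}(\text{cohort size}, \pi_{ij})$;
`simulate_many()` aggregates operating characteristics by true-toxicity
band.  Defaults mirror the benchmark protocols: the $6\times6$ study uses
$\theta = 0.30$, 20 cohorts of 2 from $d_{11}$, neighbourhood constraint,
closest/min-sample-size, weak prior with medians at the
"in agreement with prior" truths; the $4\times4$ study uses
$\theta = 0.20$, 50 cohorts of 1, weak prior (1/16) with medians at its
scenario-A truths.  Reporting conventions: experimentation percentages
are per patient treated; recommendation percentages are per selected
dose pooled over trials; the mean number of recommended doses averages
over all trials counting empty recommendations as zero; early-stopped
trials contribute their treated patients to experimentation and appear
in the "none" share.  Band edges for the $\theta = 0.30$ study sit at
0.145/0.245/0.345/0.455 (all benchmark truths are multiples of 0.005);
the $\theta$-relative study distinguishes exactly-at-$\theta$ (truths
are printed at integer percent), within 1–10 points, and beyond.

Per-trial RNG streams are derived by hashing (seed, trial index) modulo
$2^{31}-1$, so results are reproducible and independent of execution
order.  `make_scenario("random_monotone")` draws monotone truth grids
for property testing by accumulating sorted increments.

The generator emulates the idealised world of the benchmark studies:
exchangeable patients, instantaneous binary outcomes, a fixed monotone
truth, no patient heterogeneity, no late-onset toxicity, no accrual
gaps.  A green operating-characteristics test therefore establishes
fidelity of the *decision algorithm*, not clinical performance under
model violations.

## Numerical choices

* Contour scores accumulate in log space (up to 36 factors, each
  possibly far below 1); degenerate tail probabilities (0 or 1) are
  capped before the vectorised matrix product to avoid $0 \times \infty$,
  then restored to $-\infty$.
* Contours are enumerated once per grid shape as nonincreasing height
  vectors in lexicographic order (stable IDs), cached, and scored as a
  single matrix-vector product per decision.
* Modal ties: relative tolerance $10^{-12}$, broken uniformly at random.
* Safety exclusion uses the weak inequality $q \ge \epsilon$
  (conservative; the strictness is not printed in the source
  convention).
* Surface estimation across several $\theta$ levels
  (`estimate_surface()`) resolves non-nested modal contours toward the
  higher level by capping lower-level height vectors, guaranteeing the
  estimated surface is a genuine nested family.
* Grid files carry an explicit `row_order` marker (drug-B descending by
  default, the visual convention of published dose tables) so a file can
  never be silently transposed or flipped on reload.

## Known limitations

* The adjacent-strategy geometry is a formalisation of a figure that is
  not fully legible in the source; it satisfies the documented
  subset/walk-through relations but its benchmark rows are reproduced
  only qualitatively (within ~5 points), whereas the closest-strategy
  rows reproduce within Monte-Carlo tolerance.
* Correlated priors, constrained-monotone priors on the risks
  themselves, comparator parametric designs, sample-size re-estimation
  and stopping rules beyond safety-emptiness are out of scope.
* Grids beyond roughly $12 \times 12$ exceed the default contour cap
  ($10^7$); the design itself is intended for small dose grids.
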