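# pipedose

Bayesian adaptive dose escalation for **dual-agent phase I trials** using
the product of independent beta probabilities (PIPE) design: a curve-free
working model in which every dose combination carries its own independent
beta prior on the probability of a dose-limiting toxicity (DLT), and
escalation is driven by the most probable **maximum tolerated contour**
(MTC) over the dose grid.

The package is aimed at trial statisticians designing combination
phase I studies: it covers prior elicitation from median toxicity grids,
conjugate inference, per-cohort escalation decisions (with dose-skipping
and safety constraints), recommended phase II dose selection, and a
Monte-Carlo simulator for operating characteristics, plus a small CLI.

## The model

Doses of drugs A and B form an `I x J` grid; combination `d_ij` has DLT
probability `pi_ij` with prior `pi_ij ~ Beta(a_ij, b_ij)`, elicited by
solving `F(med_ij; a_ij, s_ij - a_ij) = 0.5` for a stated prior median
`med_ij` and prior effective sample size `s_ij = a_ij + b_ij`.  Binomial
DLT counts update each cell in closed form.  For a target toxicity level
`theta`, the tail probabilities `p_ij = F(theta; a_ij, b_ij)` score every
*monotone* binary partition `C` of the grid (an up-set: `C[i,j] = 1`
means "above the MTC", closed under increasing either dose) by

```
P(MTC = C | data)  ∝  prod_ij  p_ij^(1 - C[i,j]) * (1 - p_ij)^C[i,j]
```

There are `choose(I + J, I)` monotone contours; the modal one guides
escalation.  Admissible doses are those **closest** to the contour
(maximal below-contour and minimal above-contour doses) identified within
the current dose-skipping box, filtered by a safety rule that excludes
any dose whose posterior probability of lying above the MTC — averaged
over the contour distribution — reaches a threshold `epsilon` (default
0.8); among the admissible doses, the one with the smallest prior + trial
sample size is treated next (or one is drawn by inverse-sample-size
weighted randomisation).  At the end of the trial, the doses closest from
below to the final modal contour that were actually experimented on are
recommended for phase II.

## Worked example

Weak priors (effective sample size `1/36` per combination) with medians
set to the benchmark 6 x 6 "in agreement with prior" truth grid, then a
trial simulated under the harsher "asymmetric toxic" truth:

```r
library(pipedose)

spec  <- prior_spec(make_scenario("table1_s1")$truth, strength = 1/36, theta = 0.30)
prior <- calibrate_grid(spec)
prior
#> Beta hyperparameter grid (6 x 6), strengths a+b in [0.0277778, 0.0277778]

scen  <- make_scenario("table1_s3")
opts  <- design_options(theta = 0.30, cohort_size = 2, n_cohorts = 20)
trial <- simulate_trial(scen, opts, prior, seed = 42)
trial
#> Trial result: 14/40 DLTs over 20 cohorts; 3 RPII dose(s)
trial$final_contour
#> MTC contour on a 6 x 6 grid; heights (below-counts per drug-A level): 4 3 3 1 0 0
trial$rpii
#>      [,1] [,2]
#> [1,]    1    4
#> [2,]    3    3
#> [3,]    4    1
```

The trial adapted to the higher-than-expected toxicity (14/40 DLTs at a
30% target) and recommends three combinations along the estimated
contour.  Operating characteristics over many trials, binned by the true
toxicity of the doses patients actually received (columns are true-DLT
bands in percent; `mean_n_rec` is the average number of phase II doses
recommended per trial):

```r
simulate_many(scen, opts, prior, 100, seed = 42)
#> scenario   exp_0-14 exp_15-24 exp_25-34 exp_35-45 exp_46+  rec_0-14 rec_15-24 rec_25-34 rec_35-45 rec_46+  mean_n_rec
#> table1_s3  14       13        29        36        8        1        14        37        43        5        2.4
```

## Command-line interface

```sh
PIPE=$(Rscript -e 'cat(system.file("cli", "pipe.R", package = "pipedose"))')
Rscript "$PIPE" simulate --scenario table2_A \
    --config inst/extdata/study1_config.json --n-trials 100 --seed 7
Rscript "$PIPE" next --state trial_state.json --seed 7
```

`simulate` writes an operating-characteristics table; `next` reads a
saved trial state (`save_trial_state()`) and prints the modal contour,
the safety grid `q`, the admissible doses with provenance tags and the
selected next dose.

## Further reading

See the methods vignette (`vignettes/pipe-methods.Rmd`) for the model's
assumptions, the escalation policy in detail, tunable parameters,
numerical choices and known limitations.
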