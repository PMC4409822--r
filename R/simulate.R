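# Monte-Carlo trial simulator and operating-characteristics aggregation.

# derive a per-trial seed below 2^31 from (seed, trial index); a simple
# multiplicative hash keeps streams reproducible independent of order
trial_seed <- function(seed, trial) {
  as.integer((as.double(seed) * 48271 + as.double(trial) * 69621) %% 2147483647)
}

#' Simulate one PIPE trial
#'
#' Runs a complete trial under a known truth grid: cohort 1 at the start
#' dose, then for each subsequent cohort the full escalation decision
#' ([next_dose()]) on the accumulated data, stopping early if the safety
#' constraint empties the admissible box.  DLT counts are drawn
#' Binomial(cohort size, true risk at the administered dose).  At the end
#' the modal contour of the final posterior determines the recommended
#' phase II doses; early-stopped trials recommend none.
#'
#' @param scenario a [make_scenario()] truth.
#' @param options a [design_options()] (its `theta` should equal the
#'   scenario's).
#' @param prior a [beta_grid()] prior of the same shape.
#' @param seed integer seed for this trial's RNG stream; `NULL` uses the
#'   current RNG state.
#' @param cset optional pre-enumerated contour set (speed).
#' @return object of class `trial_result`: `data` ([trial_data()]),
#'   `rpii` (2-column matrix of recommended doses), `stopped_early`,
#'   `final_contour`, `cohorts_dosed`.
#' @export
simulate_trial <- function(scenario, options, prior, seed = NULL, cset = NULL) {
  stopifnot(inherits(scenario, "scenario"), inherits(options, "design_options"),
            inherits(prior, "beta_grid"))
  assert_same_shape(scenario$truth, prior$a, "truth and prior grids")
  if (!is.null(seed)) set.seed(seed)
  I <- nrow(scenario$truth); J <- ncol(scenario$truth)
  if (is.null(cset)) cset <- enumerate_contours(I, J)
  n <- x <- matrix(0L, I, J)
  hist <- vector("list", options$n_cohorts)
  dose <- options$start_dose
  stopped <- FALSE
  m <- 0L
  while (m < options$n_cohorts) {
    if (m > 0L) {
      dec <- next_dose(prior, trial_data(n, x), options, dose, cset)
      if (dec$stop) { stopped <- TRUE; break }
      dose <- dec$dose
    }
    m <- m + 1L
    dlts <- rbinom(1L, options$cohort_size, scenario$truth[dose[1L], dose[2L]])
    n[dose[1L], dose[2L]] <- n[dose[1L], dose[2L]] + options$cohort_size
    x[dose[1L], dose[2L]] <- x[dose[1L], dose[2L]] + dlts
    hist[[m]] <- data.frame(cohort = m, i = dose[1L], j = dose[2L],
                            n = options$cohort_size, x = dlts)
  }
  data <- trial_data(n, x, do.call(rbind, hist[seq_len(m)]))
  post <- update_posterior(prior, data)
  final_contour <- modal_contour(
    contour_posterior(tail_probability(post, options$theta), cset))
  rpii <- if (stopped) matrix(integer(), 0L, 2L)
          else recommend_phase2(final_contour, data)
  structure(list(data = data, rpii = rpii, stopped_early = stopped,
                 final_contour = final_contour, cohorts_dosed = m),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial result: %d/%d DLTs over %d cohorts%s; %d RPII dose(s)\n",
              sum(x$data$x), sum(x$data$n), x$cohorts_dosed,
              if (x$stopped_early) " (stopped early for safety)" else "",
              nrow(x$rpii)))
  invisible(x)
}

#' Simulate many trials and aggregate operating characteristics
#'
#' Runs `n_trials` independent trials (per-trial RNG streams hashed from
#' `seed` and the trial index) and aggregates experimentation and
#' recommendation percentages by true-toxicity band.
#'
#' Experimentation percentages use patients actually treated as the
#' denominator; recommendation percentages are per selected dose (all
#' recommended doses across trials pooled).  `none_pct` is the share of
#' trials recommending no dose, and `untreated_pct` the share of planned
#' patients never enrolled because of early stopping.
#'
#' @param scenario a [make_scenario()] truth.
#' @param options a [design_options()].
#' @param prior a [beta_grid()] prior.
#' @param n_trials number of simulated trials.
#' @param seed master seed.
#' @param style `"study1"` or `"study2"` band layout.
#' @return object of class `pipe_oc` with elements `experimentation_pct`,
#'   `recommendation_pct` (named vectors over bands), `none_pct`,
#'   `untreated_pct`, `mean_n_recommended`, `stopped_pct`, `n_trials`,
#'   plus the per-band patient and dose counts.
#' @export
simulate_many <- function(scenario, options, prior, n_trials, seed = 1L,
                          style = c("study1", "study2")) {
  style <- match.arg(style)
  stopifnot(n_trials >= 1L)
  I <- nrow(scenario$truth); J <- ncol(scenario$truth)
  cset <- enumerate_contours(I, J)
  band_of <- matrix(band_classify(as.vector(scenario$truth), style,
                                  theta = scenario$theta), I, J)
  labels <- if (style == "study1") toxicity_bands("study1")$label
            else c("at_theta", "within_10", "over_10")
  pat <- rec <- setNames(numeric(length(labels)), labels)
  n_rec_total <- 0; n_none <- 0L; n_stopped <- 0L; treated <- 0
  for (t in seq_len(n_trials)) {
    res <- simulate_trial(scenario, options, prior,
                          seed = trial_seed(seed, t), cset = cset)
    tb <- tapply(as.vector(res$data$n), as.vector(band_of), sum)
    pat[names(tb)] <- pat[names(tb)] + ifelse(is.na(tb), 0, tb)
    treated <- treated + sum(res$data$n)
    if (res$stopped_early) n_stopped <- n_stopped + 1L
    k <- nrow(res$rpii)
    n_rec_total <- n_rec_total + k
    if (k == 0L) n_none <- n_none + 1L
    else {
      rb <- band_of[res$rpii]
      for (lab in rb) rec[lab] <- rec[lab] + 1
    }
  }
  planned <- n_trials * options$cohort_size * options$n_cohorts
  structure(list(
    experimentation_pct = 100 * pat / treated,
    recommendation_pct = if (n_rec_total > 0) 100 * rec / n_rec_total
                         else rec,
    none_pct = 100 * n_none / n_trials,
    untreated_pct = 100 * (planned - treated) / planned,
    mean_n_recommended = n_rec_total / n_trials,
    stopped_pct = 100 * n_stopped / n_trials,
    patients_by_band = pat, recommended_by_band = rec,
    n_trials = n_trials, style = style,
    scenario = scenario$name, theta = scenario$theta),
    class = "pipe_oc")
}

#' @export
print.pipe_oc <- function(x, ...) {
  cat(render_oc_table(x))
  invisible(x)
}
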