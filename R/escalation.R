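# Escalation policy: from a modal contour plus trial state to the next
# dose.  Admissible doses come from the contour geometry (closest or
# adjacent), then pass through dose-skipping, safety and coherence
# filters; a "largest dose" fallback handles the early-trial case where
# the constraint box has not yet reached the contour.

#' Design options for a PIPE trial
#'
#' @param theta target toxicity level in (0, 1).
#' @param epsilon safety threshold in (0, 1\]: doses whose posterior
#'   probability of lying above the MTC reaches `epsilon` are excluded
#'   (default 0.8).
#' @param cohort_size patients per cohort.
#' @param n_cohorts planned number of cohorts.
#' @param strategy `"closest"` (maximal-below and minimal-above doses) or
#'   `"adjacent"` (all doses touching the contour's staircase curve).
#' @param selection `"min_sample_size"` (smallest prior-plus-observed
#'   sample size, random among ties) or `"weighted_randomisation"`
#'   (probability proportional to inverse sample size).
#' @param constraint dose-skipping rule: `"neighbourhood"` (within one
#'   level of the current dose in each drug), `"non_neighbourhood"`
#'   (within one level above any previously administered dose) or
#'   `"none"`.
#' @param coherence if `TRUE`, restrict admissible doses to the opposite
#'   side of the updated contour from the current dose, so DLTs lead to
#'   de-escalation and non-DLTs to escalation.
#' @param start_dose integer pair (i, j) for the first cohort
#'   (default the lowest combination, c(1, 1)).
#' @param seed integer RNG seed used by the simulator and CLI.
#' @return object of class `design_options`.
#' @export
design_options <- function(theta,
                           epsilon = 0.8,
                           cohort_size = 2L,
                           n_cohorts = 20L,
                           strategy = c("closest", "adjacent"),
                           selection = c("min_sample_size", "weighted_randomisation"),
                           constraint = c("neighbourhood", "non_neighbourhood", "none"),
                           coherence = FALSE,
                           start_dose = c(1L, 1L),
                           seed = 1L) {
  strategy <- match.arg(strategy)
  selection <- match.arg(selection)
  constraint <- match.arg(constraint)
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)", call. = FALSE)
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must be in (0, 1]", call. = FALSE)
  if (cohort_size < 1 || n_cohorts < 1)
    stop("cohort_size and n_cohorts must be positive", call. = FALSE)
  if (length(start_dose) != 2L || any(start_dose < 1))
    stop("start_dose must be a pair of positive dose indices", call. = FALSE)
  structure(list(theta = theta, epsilon = epsilon,
                 cohort_size = as.integer(cohort_size),
                 n_cohorts = as.integer(n_cohorts),
                 strategy = strategy, selection = selection,
                 constraint = constraint, coherence = isTRUE(coherence),
                 start_dose = as.integer(start_dose), seed = as.integer(seed)),
            class = "design_options")
}

#' @export
print.design_options <- function(x, ...) {
  cat(sprintf(paste0("PIPE design: theta = %g, epsilon = %g, %d cohorts of %d\n",
                     "  strategy = %s, selection = %s, constraint = %s, ",
                     "coherence = %s, start = (%d, %d)\n"),
              x$theta, x$epsilon, x$n_cohorts, x$cohort_size, x$strategy,
              x$selection, x$constraint, x$coherence,
              x$start_dose[1L], x$start_dose[2L]))
  invisible(x)
}

#' Partition the dose grid by a contour
#'
#' @param contour a `pipe_contour`.
#' @return list with `below` and `above`: 2-column (i, j) matrices giving
#'   a disjoint exhaustive partition of the grid.
#' @export
partition <- function(contour) {
  stopifnot(inherits(contour, "pipe_contour"))
  list(below = mask_to_cells(contour$above == 0L),
       above = mask_to_cells(contour$above == 1L))
}

# build an admissible-set object: cells matrix + provenance tags
admissible_set <- function(cells, provenance) {
  structure(list(doses = cells, provenance = provenance),
            class = "admissible_set")
}

#' @export
print.admissible_set <- function(x, ...) {
  if (nrow(x$doses) == 0L) { cat("Admissible set: empty\n"); return(invisible(x)) }
  cat("Admissible doses:\n")
  for (k in seq_len(nrow(x$doses)))
    cat(sprintf("  (%d, %d)  [%s]\n", x$doses[k, 1L], x$doses[k, 2L],
                x$provenance[k]))
  invisible(x)
}

#' Doses closest to the contour in toxicity
#'
#' The closest doses are the maximal elements (componentwise order) of
#' the below-contour set together with the minimal elements of the
#' above-contour set: under monotonicity they dominate every other dose
#' on their side.  When `within` is supplied, the maximal/minimal
#' elements are computed inside that restricted set of doses — the
#' closest doses "identified given the current constraint".  For a
#' one-sided restricted set this reduces to the largest (or, above the
#' contour, smallest) doses of the set, i.e. the diagonal-escalation
#' fallback; such doses are tagged `largest_fallback`.
#'
#' @param contour a `pipe_contour`.
#' @param within optional 2-column (i, j) matrix restricting the search
#'   (e.g. the dose-skipping box after safety filtering); default the
#'   whole grid.
#' @return an `admissible_set` with provenance `closest_below` /
#'   `closest_above` / `largest_fallback`.
#' @export
closest_doses <- function(contour, within = NULL) {
  if (is.null(within)) {
    parts <- partition(contour)
    lo <- maximal_cells(parts$below)
    hi <- minimal_cells(parts$above)
  } else {
    ab <- contour$above[within] == 1L
    lo <- maximal_cells(within[!ab, , drop = FALSE])
    hi <- minimal_cells(within[ab, , drop = FALSE])
  }
  tags <- c(rep("closest_below", nrow(lo)), rep("closest_above", nrow(hi)))
  if (!is.null(within) && (nrow(lo) == 0L || nrow(hi) == 0L))
    tags <- rep("largest_fallback", length(tags))
  admissible_set(rbind(lo, hi), tags)
}

#' Doses adjacent to the contour's staircase curve
#'
#' Draws the contour as a step function across the full grid width: a
#' horizontal segment at height `h[i]` over drug-A column i, joined by
#' vertical drops where the height changes.  Every cell with at least one
#' edge on that curve is adjacent.  Always a superset of
#' [closest_doses()].
#'
#' @param contour a `pipe_contour`.
#' @return an `admissible_set`; closest doses keep their closest tags,
#'   the remainder are tagged `adjacent_only`.
#' @export
adjacent_doses <- function(contour) {
  h <- contour$heights
  I <- length(h); J <- ncol(contour$above)
  adj <- matrix(FALSE, I, J)
  for (i in seq_len(I)) {
    # cells touching the horizontal segment of column i
    if (h[i] >= 1L) adj[i, h[i]] <- TRUE
    if (h[i] < J)  adj[i, h[i] + 1L] <- TRUE
    # vertical drop between columns i and i+1
    if (i < I && h[i] > h[i + 1L]) {
      jr <- (h[i + 1L] + 1L):h[i]
      adj[i, jr] <- TRUE
      adj[i + 1L, jr] <- TRUE
    }
  }
  cells <- mask_to_cells(adj)
  cl <- closest_doses(contour)
  tags <- setNames(cl$provenance, cell_key(cl$doses))[cell_key(cells)]
  tags[is.na(tags)] <- "adjacent_only"
  admissible_set(cells, unname(tags))
}

#' Neighbourhood dose-skipping constraint
#'
#' Restricts a candidate set to doses at most one level away from the
#' currently experimented dose in each drug.
#'
#' @param cells 2-column (i, j) matrix of candidate doses.
#' @param current_dose integer pair (i, j).
#' @return the restricted cell matrix.
#' @export
apply_neighbourhood_constraint <- function(cells, current_dose) {
  keep <- abs(cells[, 1L] - current_dose[1L]) <= 1L &
          abs(cells[, 2L] - current_dose[2L]) <= 1L
  cells[keep, , drop = FALSE]
}

#' Non-neighbourhood dose-skipping constraint
#'
#' Restricts to doses at most one level higher (in either or both drugs)
#' than *some* previously administered dose combination; no lower bound,
#' so de-escalation anywhere below is always permitted.
#'
#' @param cells 2-column (i, j) matrix of candidate doses.
#' @param history_doses 2-column (i, j) matrix of all previously
#'   administered dose combinations.
#' @return the restricted cell matrix.
#' @export
apply_non_neighbourhood_constraint <- function(cells, history_doses) {
  if (nrow(history_doses) == 0L) stop("history must be nonempty", call. = FALSE)
  keep <- vapply(seq_len(nrow(cells)), function(k)
    any(cells[k, 1L] <= history_doses[, 1L] + 1L &
        cells[k, 2L] <= history_doses[, 2L] + 1L), logical(1L))
  cells[keep, , drop = FALSE]
}

#' Safety constraint
#'
#' Removes doses whose posterior probability of lying above the MTC,
#' averaged over the contour distribution, reaches the threshold
#' \eqn{\epsilon}.  An empty result signals that the trial should stop:
#' emptiness is an outcome for the caller, not an error.
#'
#' @param cells 2-column (i, j) matrix of candidate doses.
#' @param q numeric I x J matrix from [above_mtc_probability()].
#' @param epsilon threshold in (0, 1\]; exclusion uses `q >= epsilon`.
#' @return the restricted cell matrix (possibly empty).
#' @export
apply_safety_constraint <- function(cells, q, epsilon) {
  if (nrow(cells) == 0L) return(cells)
  cells[q[cells] < epsilon, , drop = FALSE]
}

#' Coherence filter
#'
#' Keeps only doses on the opposite side of the (updated) contour from
#' the current dose: if the current dose sits below the contour only
#' above-contour doses remain, and vice versa.  With the contour adapting
#' to the latest outcome this makes escalation follow non-DLTs and
#' de-escalation follow DLTs.
#'
#' @param cells 2-column (i, j) candidate matrix.
#' @param contour the updated modal `pipe_contour`.
#' @param current_dose integer pair (i, j).
#' @return the restricted cell matrix (possibly empty; callers fall
#'   through to the fallback rule on emptiness).
#' @export
apply_coherence <- function(cells, contour, current_dose) {
  if (nrow(cells) == 0L) return(cells)
  cur_above <- contour$above[current_dose[1L], current_dose[2L]] == 1L
  want_above <- !cur_above
  keep <- (contour$above[cells] == 1L) == want_above
  cells[keep, , drop = FALSE]
}

#' Largest-dose fallback
#'
#' Used when no strategy (closest/adjacent) dose survives the constraints
#' but the constrained box itself is nonempty — typically early in a
#' trial, when the neighbourhood box has not yet reached the contour.
#' If the box contains below-contour doses, the largest (maximal) of them
#' are taken, giving diagonal escalation; if the whole box lies above the
#' contour, the minimal doses are taken instead (forced de-escalation).
#'
#' @param cells 2-column (i, j) matrix: the constrained, safety-filtered
#'   candidate box (nonempty).
#' @param contour the modal `pipe_contour`.
#' @return an `admissible_set` tagged `largest_fallback`.
#' @export
fallback_largest <- function(cells, contour) {
  stopifnot(nrow(cells) > 0L)
  below <- cells[contour$above[cells] == 0L, , drop = FALSE]
  picked <- if (nrow(below) > 0L) maximal_cells(below) else minimal_cells(cells)
  admissible_set(picked, rep("largest_fallback", nrow(picked)))
}

#' Select one dose from an admissible set
#'
#' Sample size at a dose counts both pseudo-patients from the prior and
#' patients treated: \eqn{a_{ij} + b_{ij} + n_{ij}}.  The
#' `min_sample_size` rule takes the admissible dose with the smallest
#' sample size, choosing uniformly at random among ties; the
#' `weighted_randomisation` rule draws one admissible dose with
#' probability proportional to the inverse sample size.  Both promote
#' varied experimentation around the contour.
#'
#' @param aset an `admissible_set` (nonempty).
#' @param prior a [beta_grid()] prior.
#' @param data a [trial_data()].
#' @param rule `"min_sample_size"` or `"weighted_randomisation"`.
#' @return integer pair (i, j).
#' @export
select_dose <- function(aset, prior, data,
                        rule = c("min_sample_size", "weighted_randomisation")) {
  rule <- match.arg(rule)
  cells <- aset$doses
  if (nrow(cells) == 0L) stop("cannot select from an empty admissible set",
                              call. = FALSE)
  ss <- (prior$a + prior$b + data$n)[cells]
  k <- if (rule == "min_sample_size") {
    ties <- which(ss <= min(ss) * (1 + 1e-12))
    if (length(ties) == 1L) ties else ties[sample.int(length(ties), 1L)]
  } else {
    w <- 1 / ss
    sample.int(nrow(cells), 1L, prob = w / sum(w))
  }
  cells[k, ]
}

#' Recommended phase II doses
#'
#' After the final cohort, the doses recommended for phase II are the
#' combinations closest from below to the final contour (the maximal
#' elements of its below-set) that were experimented on during the
#' trial.  Doses above the contour are never recommended — without a
#' safety constraint their upper toxicity risk is unbounded.  An empty
#' set (the below-frontier was never experimented, or the trial stopped
#' early for safety) is the "recommend none" outcome.
#'
#' @param final_contour the end-of-trial modal `pipe_contour`.
#' @param data final [trial_data()].
#' @return 2-column (i, j) matrix, an antichain; zero rows means no
#'   recommendation.
#' @export
recommend_phase2 <- function(final_contour, data) {
  stopifnot(inherits(final_contour, "pipe_contour"), inherits(data, "trial_data"))
  frontier <- maximal_cells(mask_to_cells(final_contour$above == 0L))
  frontier[data$n[frontier] > 0L, , drop = FALSE]
}

#' One escalation decision
#'
#' Runs the full per-cohort decision pipeline: conjugate posterior,
#' contour posterior, modal contour, above-MTC safety probabilities;
#' then the dose-skipping constraint and safety constraint define the
#' available box (emptiness stops the trial); the strategy set (closest
#' or adjacent doses, identified within that box) gives the candidates;
#' coherence optionally restricts them; and the selection rule picks the
#' dose.  When no adjacent dose falls inside the box, or the box lies
#' entirely on one side of the contour, the candidates degrade to the
#' largest (below) or smallest (above) doses of the box — the
#' diagonal-escalation fallback.  Randomised steps (modal ties,
#' selection ties, weighted randomisation) use R's global RNG; seed it
#' for reproducibility.
#'
#' @param prior a [beta_grid()] prior.
#' @param data a [trial_data()] (all cohorts observed so far).
#' @param options a [design_options()].
#' @param current_dose dose of the current (latest) cohort, integer pair.
#' @param cset optional pre-enumerated contour set (speed).
#' @return list with `dose` (integer pair or `NULL` when the trial must
#'   stop), `stop` flag, `contour`, `q`, `admissible` (the
#'   `admissible_set` offered to the selection rule) and `posterior`.
#' @export
next_dose <- function(prior, data, options, current_dose, cset = NULL) {
  stopifnot(inherits(options, "design_options"))
  post <- update_posterior(prior, data)
  p <- tail_probability(post, options$theta)
  dist <- contour_posterior(p, cset)
  contour <- modal_contour(dist)
  q <- above_mtc_probability(dist)
  I <- nrow(p); J <- ncol(p)

  all_cells <- mask_to_cells(matrix(TRUE, I, J))
  box <- switch(options$constraint,
    neighbourhood = apply_neighbourhood_constraint(all_cells, current_dose),
    non_neighbourhood = {
      hist_doses <- unique(as.matrix(data$history[, c("i", "j")]))
      if (nrow(hist_doses) == 0L) hist_doses <- matrix(current_dose, 1L)
      apply_non_neighbourhood_constraint(all_cells, hist_doses)
    },
    none = all_cells)
  avail <- apply_safety_constraint(box, q, options$epsilon)
  if (nrow(avail) == 0L)
    return(list(dose = NULL, stop = TRUE, contour = contour, q = q,
                admissible = admissible_set(avail, character()),
                posterior = post))

  aset <- if (options$strategy == "closest") {
    closest_doses(contour, within = avail)
  } else {
    adj <- adjacent_doses(contour)
    keep <- cell_key(adj$doses) %in% cell_key(avail)
    if (any(keep)) admissible_set(adj$doses[keep, , drop = FALSE],
                                  adj$provenance[keep])
    else closest_doses(contour, within = avail)  # one-sided box: largest
  }
  if (options$coherence) {
    coh <- apply_coherence(aset$doses, contour, current_dose)
    if (nrow(coh) > 0L) {
      keep <- cell_key(aset$doses) %in% cell_key(coh)
      aset <- admissible_set(aset$doses[keep, , drop = FALSE],
                             aset$provenance[keep])
    }
  }
  dose <- select_dose(aset, prior, data, options$selection)
  list(dose = dose, stop = FALSE, contour = contour, q = q,
       admissible = aset, posterior = post)
}
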