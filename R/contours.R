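# Posterior updating and monotonic-contour inference.  A candidate MTC is
# a monotone partition (up-set) of the I x J dose lattice: a binary matrix
# `above` with above[i,j] = 1 meaning DLT risk > theta, closed under
# increasing either dose index.  Each contour is equivalently encoded by
# its height vector h, with h[i] = number of below-contour cells in drug-A
# column i; the up-set property is exactly "h nonincreasing in i", so the
# number of contours is choose(I+J, I).

#' Trial data: patients and DLTs per dose combination
#'
#' @param n,x integer I x J matrices of patients treated and DLTs observed
#'   at each dose combination; `0 <= x <= n` cellwise.
#' @param history optional data frame recording the dosing history, one
#'   row per cohort, with columns `cohort`, `i`, `j`, `n`, `x`.  When
#'   supplied it must aggregate exactly to the `n` and `x` grids.
#' @return an object of class `trial_data`.
#' @export
trial_data <- function(n, x, history = NULL) {
  n <- as.matrix(n); x <- as.matrix(x)
  assert_same_shape(n, x, "patient and DLT grids")
  if (any(n < 0) || any(x < 0) || any(x > n) || any(n != round(n)) || any(x != round(x)))
    stop("need integer grids with 0 <= x_ij <= n_ij", call. = FALSE)
  if (is.null(history)) {
    history <- data.frame(cohort = integer(), i = integer(), j = integer(),
                          n = integer(), x = integer())
  } else {
    history <- as.data.frame(history)
    stopifnot(all(c("cohort", "i", "j", "n", "x") %in% names(history)))
    nh <- xh <- matrix(0L, nrow(n), ncol(n))
    for (r in seq_len(nrow(history))) {
      nh[history$i[r], history$j[r]] <- nh[history$i[r], history$j[r]] + history$n[r]
      xh[history$i[r], history$j[r]] <- xh[history$i[r], history$j[r]] + history$x[r]
    }
    if (any(nh != n) || any(xh != x))
      stop("history does not aggregate to the n/x grids", call. = FALSE)
  }
  structure(list(n = n, x = x, history = history), class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial data: %d patients, %d DLTs over a %d x %d grid (%d cohorts)\n",
              sum(x$n), sum(x$x), nrow(x$n), ncol(x$n),
              if (nrow(x$history)) max(x$history$cohort) else 0L))
  invisible(x)
}

# Empty trial data for a given grid shape.
empty_trial_data <- function(I, J) {
  trial_data(matrix(0L, I, J), matrix(0L, I, J))
}

#' Conjugate posterior update of a beta grid
#'
#' Independent beta priors with binomial DLT counts give beta posteriors
#' in closed form: \eqn{a' = a + x}, \eqn{b' = b + (n - x)} cellwise.
#'
#' @param prior a [beta_grid()].
#' @param data a [trial_data()] of the same shape.
#' @return the posterior [beta_grid()].
#' @export
update_posterior <- function(prior, data) {
  stopifnot(inherits(prior, "beta_grid"), inherits(data, "trial_data"))
  assert_same_shape(prior$a, data$n, "prior and data grids")
  beta_grid(prior$a + data$x, prior$b + (data$n - data$x))
}

#' Posterior probability that each dose combination is tolerable
#'
#' Computes \eqn{p_{ij} = F(\theta; a_{ij}, b_{ij})}, the beta CDF at the
#' target toxicity level: the probability that the DLT risk at \eqn{d_{ij}}
#' is at or below \eqn{\theta}.
#'
#' @param post a [beta_grid()] (prior or posterior).
#' @param theta target toxicity level in (0, 1).
#' @return numeric I x J matrix of tail probabilities in \[0, 1\].
#' @export
tail_probability <- function(post, theta) {
  stopifnot(inherits(post, "beta_grid"))
  if (theta <= 0 || theta >= 1)
    stop("theta must lie strictly in (0, 1)", call. = FALSE)
  matrix(pbeta(theta, post$a, post$b), nrow(post$a), ncol(post$a))
}

#' Construct a contour from its height vector
#'
#' @param heights integer vector of length I; `heights[i]` is the number
#'   of below-contour cells in drug-A column i.  Must be nonincreasing
#'   (the up-set property) with entries in 0..J.
#' @param J number of drug B levels.
#' @return object of class `pipe_contour` with elements `above`
#'   (binary I x J matrix) and `heights`.
#' @export
contour_from_heights <- function(heights, J) {
  heights <- as.integer(heights)
  I <- length(heights)
  if (any(heights < 0L) || any(heights > J))
    stop("heights must lie in 0..J", call. = FALSE)
  if (I > 1L && any(diff(heights) > 0L))
    stop("heights must be nonincreasing in the drug-A index (up-set property)",
         call. = FALSE)
  above <- matrix(0L, I, J)
  for (i in seq_len(I)) if (heights[i] < J) above[i, (heights[i] + 1L):J] <- 1L
  structure(list(above = above, heights = heights), class = "pipe_contour")
}

#' Construct a contour from its binary above-matrix
#'
#' @param above binary I x J matrix, 1 = DLT risk above theta.  Must be an
#'   up-set: `above[i,j] = 1` implies `above[i+1,j] = 1` and
#'   `above[i,j+1] = 1`.
#' @return object of class `pipe_contour`.
#' @export
contour_from_matrix <- function(above) {
  above <- as.matrix(above)
  storage.mode(above) <- "integer"
  if (!all(above %in% c(0L, 1L)))
    stop("contour matrix must be binary", call. = FALSE)
  heights <- apply(above, 1L, function(row) sum(row == 0L))
  # validate: each column's below-cells must be a prefix, heights nonincreasing
  cand <- contour_from_heights(heights, ncol(above))
  if (!identical(cand$above, above))
    stop("matrix is not a monotone contour (up-set property violated)",
         call. = FALSE)
  cand
}

#' @export
print.pipe_contour <- function(x, ...) {
  cat(sprintf("MTC contour on a %d x %d grid; heights (below-counts per drug-A level): %s\n",
              nrow(x$above), ncol(x$above), paste(x$heights, collapse = " ")))
  invisible(x)
}

#' @export
format.pipe_contour <- function(x, ...) paste(x$heights, collapse = "-")

# cache of enumerated height matrices per (I, J)
.contour_cache <- new.env(parent = emptyenv())

# All nonincreasing height vectors of length I with entries in 0..J,
# generated in lexicographic order (stable contour IDs).  Returned as an
# n_contours x I integer matrix.
enumerate_heights <- function(I, J) {
  key <- paste(I, J, sep = "x")
  if (!is.null(.contour_cache[[key]])) return(.contour_cache[[key]])
  rec <- function(len, maxh) {
    if (len == 0L) return(matrix(integer(), 1L, 0L))
    out <- lapply(0L:maxh, function(h) {
      sub <- rec(len - 1L, h)
      cbind(rep(h, nrow(sub)), sub)
    })
    do.call(rbind, out)
  }
  hmat <- rec(I, J)
  storage.mode(hmat) <- "integer"
  .contour_cache[[key]] <- hmat
  hmat
}

# above-matrix of every contour, flattened column-major to a
# n_contours x (I*J) binary matrix (cell order: as.vector of the I x J grid).
enumerate_above <- function(I, J) {
  key <- paste("A", I, J, sep = "x")
  if (!is.null(.contour_cache[[key]])) return(.contour_cache[[key]])
  hmat <- enumerate_heights(I, J)
  ncont <- nrow(hmat)
  A <- matrix(0L, ncont, I * J)
  for (j in seq_len(J)) {
    # cell (i, j) is above iff h_i < j
    A[, (j - 1L) * I + seq_len(I)] <- (hmat < j) + 0L
  }
  .contour_cache[[key]] <- A
  A
}

#' Enumerate all monotonic MTC candidates for an I x J dose grid
#'
#' Generates every monotone partition of the lattice exactly once, in a
#' stable lexicographic order of height vectors.  There are
#' \eqn{\binom{I+J}{I}} of them.
#'
#' @param I,J numbers of dose levels of drugs A and B.
#' @param max_contours refuse enumeration beyond this many contours
#'   (guards memory; default 1e7).
#' @return object of class `contour_set`: list with `I`, `J`, `heights`
#'   (n x I integer matrix) and `above` (n x (I*J) binary matrix,
#'   column-major cell order).
#' @export
#' @examples
#' nrow(enumerate_contours(2, 2)$heights)  # 6
enumerate_contours <- function(I, J, max_contours = 1e7) {
  stopifnot(I >= 1L, J >= 1L)
  ncont <- choose(I + J, I)
  if (ncont > max_contours)
    stop(sprintf("grid %d x %d has %.0f monotone contours, above the cap of %.0f",
                 I, J, ncont, max_contours), call. = FALSE)
  structure(list(I = I, J = J,
                 heights = enumerate_heights(I, J),
                 above = enumerate_above(I, J)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("Set of %d monotone contours on a %d x %d grid\n",
              nrow(x$heights), x$I, x$J))
  invisible(x)
}

# extract contour s from a contour_set
contour_at <- function(cset, s) contour_from_heights(cset$heights[s, ], cset$J)

#' Log unnormalised posterior probability of one contour
#'
#' The score of contour \eqn{C} given tail probabilities \eqn{p_{ij}} is
#' the product of independent beta tail probabilities
#' \eqn{\prod_{ij} p_{ij}^{1 - C[i,j]} (1 - p_{ij})^{C[i,j]}},
#' accumulated in log space.  `-Inf` is returned when a factor is zero.
#'
#' @param p numeric I x J matrix of tail probabilities (see
#'   [tail_probability()]).
#' @param contour a `pipe_contour`.
#' @return scalar log unnormalised probability.
#' @export
contour_log_probability <- function(p, contour) {
  stopifnot(inherits(contour, "pipe_contour"))
  assert_same_shape(p, contour$above, "tail grid and contour")
  ab <- contour$above == 1L
  sum(log(ifelse(ab, 1 - p, p)))
}

#' Posterior distribution over all monotone contours
#'
#' Scores every monotone contour by its product of independent beta tail
#' probabilities and normalises over the monotone set only, giving a
#' proper distribution on candidate MTCs.
#'
#' @param p numeric I x J matrix of tail probabilities.
#' @param cset optional pre-enumerated [enumerate_contours()] result for
#'   the same shape (reused across cohorts for speed).
#' @return object of class `contour_dist`: list with the `contour_set`,
#'   `log_weights` (unnormalised) and `prob` (normalised, sums to 1).
#' @export
contour_posterior <- function(p, cset = NULL) {
  p <- as.matrix(p)
  if (any(p < 0 | p > 1)) stop("tail probabilities must lie in [0, 1]", call. = FALSE)
  I <- nrow(p); J <- ncol(p)
  if (is.null(cset)) cset <- enumerate_contours(I, J)
  stopifnot(cset$I == I, cset$J == J)
  lp <- log(as.vector(p))          # used when cell below (above = 0)
  lq <- log1p(-as.vector(p))       # used when cell above
  # log weight = sum_below log p + sum_above log(1-p).  Degenerate cells
  # (p exactly 0 or 1) give -Inf factors, which would poison the matrix
  # product with 0 * Inf = NaN; cap them far below any attainable finite
  # log weight (|log p| <= ~745 per cell) and restore -Inf afterwards.
  cap <- -1e13
  lw <- as.vector(cset$above %*% (pmax(lq, cap) - pmax(lp, cap))) +
    sum(pmax(lp, cap))
  lw[lw < -1e11] <- -Inf
  if (all(is.infinite(lw)))
    stop("degenerate contour posterior: every contour has probability zero",
         call. = FALSE)
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[is.na(w)] <- 0
  structure(list(cset = cset, log_weights = lw, prob = w / sum(w)),
            class = "contour_dist")
}

#' @export
print.contour_dist <- function(x, ...) {
  s <- which.max(x$prob)
  cat(sprintf("Posterior over %d monotone contours; modal heights %s (prob %.3f)\n",
              length(x$prob), paste(x$cset$heights[s, ], collapse = " "),
              x$prob[s]))
  invisible(x)
}

#' Most probable MTC contour
#'
#' Returns the contour maximising the posterior contour probability (the
#' expected joint gain).  Ties within a relative tolerance of 1e-12 are
#' broken uniformly at random, so pass a seeded RNG state for
#' reproducibility.
#'
#' @param dist a [contour_posterior()] result.
#' @return the modal `pipe_contour`.
#' @export
modal_contour <- function(dist) {
  stopifnot(inherits(dist, "contour_dist"))
  top <- max(dist$prob)
  cand <- which(dist$prob >= top * (1 - 1e-12))
  s <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  contour_at(dist$cset, s)
}

#' Probability that each dose combination lies above the MTC
#'
#' Averages the above-contour indicator over the posterior distribution of
#' monotone contours: \eqn{q_{ij} = \sum_s P(C_s | Y) \, C_s[i,j]}.  This
#' borrows strength across the grid (the \eqn{q_{ij}} are dependent even
#' though the \eqn{p_{ij}} are independent) and drives the safety
#' constraint.
#'
#' @param dist a [contour_posterior()] result.
#' @return numeric I x J matrix `q`, monotone nondecreasing in both dose
#'   indices.
#' @export
above_mtc_probability <- function(dist) {
  stopifnot(inherits(dist, "contour_dist"))
  q <- as.vector(dist$prob %*% dist$cset$above)
  matrix(q, dist$cset$I, dist$cset$J)
}

#' Most likely dose-toxicity surface across several target levels
#'
#' Estimates the modal MTC at each of several target toxicity levels and
#' enforces nesting: the above-contour set must shrink as \eqn{\theta}
#' grows.  Violations (possible because each level's modal contour is
#' estimated separately) are resolved toward the higher-\eqn{\theta}
#' contour, i.e. the lower level's above-set is enlarged to contain it.
#'
#' @param post a [beta_grid()] posterior.
#' @param theta_list strictly increasing vector of levels in (0, 1).
#' @return list of `list(theta = , contour = )` in the order given.
#' @export
estimate_surface <- function(post, theta_list) {
  stopifnot(inherits(post, "beta_grid"))
  if (is.unsorted(theta_list, strictly = TRUE) ||
      any(theta_list <= 0 | theta_list >= 1))
    stop("theta_list must be strictly increasing within (0, 1)", call. = FALSE)
  I <- nrow(post$a); J <- ncol(post$a)
  cset <- enumerate_contours(I, J)
  hs <- lapply(theta_list, function(th)
    modal_contour(contour_posterior(tail_probability(post, th), cset))$heights)
  # nesting: heights (below-counts) must be nondecreasing with theta;
  # sweep from the highest level down, capping each level's heights
  for (k in rev(seq_along(hs))[-1L]) hs[[k]] <- pmin(hs[[k]], hs[[k + 1L]])
  lapply(seq_along(theta_list), function(k)
    list(theta = theta_list[k], contour = contour_from_heights(hs[[k]], J)))
}
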