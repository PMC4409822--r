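# Prior elicitation: turn a grid of prior median DLT probabilities plus
# per-dose prior strengths (effective sample sizes a + b) into beta
# hyperparameters, one independent Beta(a_ij, b_ij) per dose combination.

#' Prior specification for a dual-agent dose grid
#'
#' Holds the elicited prior median DLT probability and prior strength
#' (effective sample size, \eqn{a_{ij} + b_{ij}}) for every dose
#' combination, plus the target toxicity level \eqn{\theta}.  Medians may
#' contain `NA` for combinations the trialist did not elicit; use
#' [complete_median_grid()] to fill them by interpolation before
#' calibration.
#'
#' @param median_grid numeric I x J matrix of prior median DLT
#'   probabilities, entries in (0, 1) or `NA` (rows = drug A levels
#'   ascending, columns = drug B levels ascending).
#' @param strength numeric scalar or I x J matrix of positive prior
#'   effective sample sizes.  The conventional choices are a weak prior
#'   `1/(I*J)` and a strong prior `1` per combination.
#' @param theta target toxicity level in (0, 1).
#' @return an object of class `prior_spec`.
#' @export
#' @examples
#' prior_spec(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2), strength = 1/4, theta = 0.3)
prior_spec <- function(median_grid, strength, theta) {
  median_grid <- as.matrix(median_grid)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("theta must be a single probability strictly in (0, 1)", call. = FALSE)
  spec <- vals_ok <- median_grid[!is.na(median_grid)]
  if (length(vals_ok) == 0L)
    stop("median_grid must specify at least some entries", call. = FALSE)
  if (any(vals_ok <= 0 | vals_ok >= 1))
    stop("specified prior medians must be strictly in (0, 1)", call. = FALSE)
  if (length(strength) == 1L)
    strength <- matrix(strength, nrow(median_grid), ncol(median_grid))
  strength <- as.matrix(strength)
  assert_same_shape(median_grid, strength, "median and strength grids")
  if (any(!is.finite(strength)) || any(strength <= 0))
    stop("prior strengths must all be positive and finite", call. = FALSE)
  structure(list(median_grid = median_grid, strength = strength, theta = theta),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior specification: %d x %d dose grid, theta = %g\n",
              nrow(x$median_grid), ncol(x$median_grid), x$theta))
  cat(sprintf("  medians specified: %d / %d; strength range [%g, %g]\n",
              sum(!is.na(x$median_grid)), length(x$median_grid),
              min(x$strength), max(x$strength)))
  invisible(x)
}

#' Grid of beta hyperparameters
#'
#' Container for per-dose-combination beta shape parameters, used both for
#' priors and (after conjugate updating) posteriors.
#'
#' @param a,b numeric I x J matrices of positive shape parameters.
#' @return an object of class `beta_grid` with elements `a` and `b`.
#' @export
beta_grid <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_same_shape(a, b, "beta parameter grids")
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("beta shape parameters must all be positive and finite", call. = FALSE)
  structure(list(a = a, b = b), class = "beta_grid")
}

#' @export
print.beta_grid <- function(x, ...) {
  cat(sprintf("Beta hyperparameter grid (%d x %d), strengths a+b in [%g, %g]\n",
              nrow(x$a), ncol(x$a), min(x$a + x$b), max(x$a + x$b)))
  invisible(x)
}

#' Calibrate one beta prior to a stated median and strength
#'
#' Solves \eqn{F(med; a, s - a) = 0.5} for the first shape parameter
#' \eqn{a}, where \eqn{F} is the beta CDF and \eqn{s = a + b} is the prior
#' effective sample size, so that the returned Beta(\eqn{a}, \eqn{s - a})
#' distribution has median `med` and strength `s`.  \eqn{F(med; a, s-a)}
#' is continuous and strictly monotone in \eqn{a}, so a bracketed root
#' search on \eqn{(\epsilon, s - \epsilon)} is robust even at very small
#' strengths such as \eqn{1/36}.
#'
#' @param med desired prior median DLT probability, strictly in (0, 1).
#' @param s prior effective sample size (\eqn{a + b}), positive.
#' @return named numeric vector `c(a = , b = )` with `a + b == s`.
#' @export
#' @examples
#' calibrate_beta(0.3, 1)   # approximately Beta(0.39, 0.61)
#' calibrate_beta(0.5, 2)   # exactly Beta(1, 1)
calibrate_beta <- function(med, s) {
  if (!is.numeric(med) || length(med) != 1L || is.na(med) || med <= 0 || med >= 1)
    stop("med must be a single probability strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0 || !is.finite(s))
    stop("s must be a single positive finite prior strength", call. = FALSE)
  if (med == 0.5) return(c(a = s / 2, b = s / 2))  # symmetry
  eps <- 1e-10 * min(1, s)
  g <- function(a) pbeta(med, a, s - a) - 0.5
  # g is decreasing in a (larger a pushes mass upward); bracket endpoints
  # straddle zero because the median tends to 0 (resp. 1) as a -> 0 (s).
  root <- uniroot(g, lower = eps, upper = s - eps, tol = 1e-12)$root
  c(a = root, b = s - root)
}

#' Fill unspecified prior medians by monotone lattice interpolation
#'
#' Completes a partially elicited median grid.  The trialist typically
#' specifies medians only at anchor combinations (the lowest and highest
#' combinations, doses believed to sit on the MTC at \eqn{\theta}, and
#' single-agent doses with historical data).  Missing entries are filled
#' on the log-odds scale: each missing cell is bounded below by the
#' largest anchor it dominates and above by the smallest anchor dominating
#' it, and placed between the two bounds in proportion to lattice (L1)
#' distance.  A final isotonic sweep over filled cells guarantees the
#' completed grid is nondecreasing in both dose indices whenever the
#' anchors themselves are order-consistent.
#'
#' @param spec a [prior_spec()] whose `median_grid` may contain `NA`.
#' @return a `prior_spec` with a complete, monotone `median_grid`;
#'   specified entries are returned unchanged.  Idempotent on complete
#'   grids.
#' @export
complete_median_grid <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  m <- spec$median_grid
  anchors <- mask_to_cells(!is.na(m))
  # order-consistency of the elicited entries themselves
  for (k in seq_len(nrow(anchors))) {
    ak <- anchors[k, ]
    dom <- anchors[, 1L] >= ak[1L] & anchors[, 2L] >= ak[2L]
    if (any(m[anchors[dom, , drop = FALSE]] < m[ak[1L], ak[2L]]))
      stop("elicited medians are inconsistent with monotonicity; ",
           "cannot interpolate", call. = FALSE)
  }
  if (!anyNA(m)) return(spec)
  lo <- qlogis(min(m, na.rm = TRUE))
  hi <- qlogis(max(m, na.rm = TRUE))
  lodds <- qlogis(m)
  filled <- lodds
  miss <- mask_to_cells(is.na(m))
  for (k in seq_len(nrow(miss))) {
    i <- miss[k, 1L]; j <- miss[k, 2L]
    below <- anchors[, 1L] <= i & anchors[, 2L] <= j
    above <- anchors[, 1L] >= i & anchors[, 2L] >= j
    d1 <- abs(anchors[, 1L] - i) + abs(anchors[, 2L] - j)
    L <- if (any(below)) max(lodds[anchors[below, , drop = FALSE]]) else lo
    U <- if (any(above)) min(lodds[anchors[above, , drop = FALSE]]) else hi
    dL <- if (any(below)) min(d1[below]) else Inf
    dU <- if (any(above)) min(d1[above]) else Inf
    filled[i, j] <-
      if (is.infinite(dL) && is.infinite(dU)) (L + U) / 2
      else if (is.infinite(dL)) U
      else if (is.infinite(dU)) L
      else (dU * L + dL * U) / (dL + dU)
  }
  # isotonic repair restricted to filled (non-anchor) cells: bounded above
  # by the dominating anchors, so this never pushes past an elicited value
  is_anchor <- !is.na(m)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (is_anchor[i, j]) next
    if (i > 1L) filled[i, j] <- max(filled[i, j], filled[i - 1L, j])
    if (j > 1L) filled[i, j] <- max(filled[i, j], filled[i, j - 1L])
  }
  out <- plogis(filled)
  out[is_anchor] <- m[is_anchor]
  if (!is_monotone_grid(out))
    stop("interpolated medians violate monotonicity of the elicited entries",
         call. = FALSE)
  prior_spec(out, spec$strength, spec$theta)
}

#' Calibrate a full beta-hyperparameter grid from a prior specification
#'
#' Applies [calibrate_beta()] to every dose combination of a complete
#' prior specification.
#'
#' @param spec a complete [prior_spec()] (no `NA` medians; see
#'   [complete_median_grid()]).
#' @return a [beta_grid()] whose per-cell strength `a + b` equals the
#'   requested strength exactly and whose beta median matches the
#'   requested median to within 1e-6.
#' @export
#' @examples
#' sp <- prior_spec(matrix(0.3, 2, 2), strength = 1/4, theta = 0.3)
#' calibrate_grid(sp)
calibrate_grid <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  m <- spec$median_grid
  if (anyNA(m))
    stop("median grid has unspecified entries; call complete_median_grid() first",
         call. = FALSE)
  a <- b <- m * NA_real_
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ab <- tryCatch(calibrate_beta(m[i, j], spec$strength[i, j]),
                   error = function(e)
                     stop(sprintf("dose combination (%d, %d): %s",
                                  i, j, conditionMessage(e)), call. = FALSE))
    a[i, j] <- ab[["a"]]; b[i, j] <- ab[["b"]]
  }
  beta_grid(a, b)
}
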