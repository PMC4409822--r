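# True-toxicity scenarios for operating-characteristics studies.  The
# shipped fixtures are the published benchmark grids for the two
# simulation studies: four 6x6 scenarios at theta = 0.30 (in agreement
# with prior / toxic / asymmetric toxic / flat) and two 4x4 scenarios at
# theta = 0.20.  Grids are stored in the package convention: rows = drug A
# levels ascending, columns = drug B levels ascending.

# 6x6 study-1 grids.  Printed sources lay rows out as drug B descending;
# transcribed here as drug B ascending columns after transposition.
.study1_truth <- local({
  # rows as printed (drug B = 0.95 down to 0.2), columns drug A ascending
  s1 <- rbind(c(0.23, 0.27, 0.30, 0.36, 0.44, 0.49),
              c(0.18, 0.21, 0.26, 0.30, 0.39, 0.44),
              c(0.11, 0.14, 0.18, 0.23, 0.30, 0.36),
              c(0.06, 0.09, 0.14, 0.18, 0.26, 0.30),
              c(0.03, 0.05, 0.09, 0.13, 0.21, 0.27),
              c(0.02, 0.03, 0.06, 0.10, 0.18, 0.23))
  s2 <- rbind(c(0.23, 0.30, 0.45, 0.50, 0.55, 0.60),
              c(0.18, 0.21, 0.30, 0.45, 0.50, 0.55),
              c(0.11, 0.14, 0.18, 0.30, 0.45, 0.50),
              c(0.06, 0.09, 0.14, 0.18, 0.30, 0.45),
              c(0.03, 0.05, 0.09, 0.13, 0.21, 0.30),
              c(0.02, 0.03, 0.06, 0.10, 0.18, 0.23))
  s3 <- rbind(c(0.30, 0.38, 0.48, 0.58, 0.68, 0.78),
              c(0.22, 0.30, 0.40, 0.50, 0.60, 0.70),
              c(0.17, 0.25, 0.35, 0.45, 0.50, 0.60),
              c(0.12, 0.20, 0.30, 0.40, 0.45, 0.55),
              c(0.06, 0.14, 0.24, 0.34, 0.39, 0.49),
              c(0.02, 0.10, 0.20, 0.30, 0.35, 0.45))
  s4 <- rbind(c(0.265, 0.295, 0.325, 0.355, 0.385, 0.415),
              c(0.250, 0.280, 0.310, 0.340, 0.370, 0.400),
              c(0.235, 0.265, 0.295, 0.325, 0.355, 0.385),
              c(0.220, 0.250, 0.280, 0.310, 0.340, 0.370),
              c(0.205, 0.235, 0.265, 0.295, 0.325, 0.355),
              c(0.190, 0.220, 0.250, 0.280, 0.310, 0.340))
  # printed layout -> internal: reverse rows (drug B ascending), transpose
  lapply(list(s1 = s1, s2 = s2, s3 = s3, s4 = s4),
         function(m) t(m[nrow(m):1L, ]))
})

# 4x4 study-2 grids, printed as percentages with rows = drug B ascending
.study2_truth <- local({
  A <- rbind(c( 4,  8, 12, 16),
             c(10, 14, 18, 22),
             c(16, 20, 24, 28),
             c(22, 26, 30, 34)) / 100
  E <- rbind(c( 8, 18, 28, 29),
             c( 9, 19, 29, 30),
             c(10, 20, 30, 31),
             c(11, 21, 31, 41)) / 100
  lapply(list(A = A, E = E), t)  # rows were drug B; transpose to drug A rows
})

#' Toxicity-band definitions
#'
#' Study-1 reporting bins true DLT probabilities into five bands around
#' theta = 0.30, with edges at 0.145/0.245/0.345/0.455 (all benchmark
#' truths are multiples of 0.005, so the edges are unambiguous).  Study-2
#' reporting is relative to theta: exactly at theta, within 1-10
#' percentage points, or more than 10 points away.
#'
#' @param style `"study1"` or `"study2"`.
#' @param theta target toxicity level (needed for `"study2"`).
#' @return data frame with columns `label`, `lower`, `upper` (study 1,
#'   half-open \[lower, upper) except the last which is closed) or
#'   `label` rows for study-2 relative bands.
#' @export
toxicity_bands <- function(style = c("study1", "study2"), theta = NULL) {
  style <- match.arg(style)
  if (style == "study1")
    data.frame(label = c("0-14", "15-24", "25-34", "35-45", "46+"),
               lower = c(0, 0.145, 0.245, 0.345, 0.455),
               upper = c(0.145, 0.245, 0.345, 0.455, 1))
  else {
    if (is.null(theta)) stop("study2 bands need theta", call. = FALSE)
    data.frame(label = c("at_theta", "within_10", "over_10"),
               stringsAsFactors = FALSE)
  }
}

#' Classify a true toxicity probability into a reporting band
#'
#' @param truth_value true DLT probability (vectorised).
#' @param style `"study1"` or `"study2"`.
#' @param theta target level, required for `"study2"`.
#' @return character vector of band labels.
#' @export
#' @examples
#' band_classify(c(0.30, 0.45, 0.48), "study1")
#' band_classify(0.34, "study2", theta = 0.20)   # ">10%" band
band_classify <- function(truth_value, style = c("study1", "study2"),
                          theta = NULL) {
  style <- match.arg(style)
  if (style == "study1") {
    b <- toxicity_bands("study1")
    idx <- findInterval(truth_value, c(b$lower, 1 + 1e-9))
    if (any(idx < 1L | idx > nrow(b)))
      stop("true toxicity values must lie in (0, 1)", call. = FALSE)
    b$label[idx]
  } else {
    if (is.null(theta)) stop("study2 bands need theta", call. = FALSE)
    d <- abs(truth_value - theta)
    ifelse(d <= 1e-9, "at_theta", ifelse(d <= 0.10 + 1e-9, "within_10", "over_10"))
  }
}

#' Build a true-toxicity scenario
#'
#' Named fixtures reproduce the benchmark grids exactly;
#' `"random_monotone"` draws a grid guaranteed monotone in both indices
#' by accumulating sorted increments, for property testing.
#'
#' @param kind one of `"table1_s1"` ... `"table1_s4"` (6x6, theta 0.30),
#'   `"table2_A"`, `"table2_E"` (4x4, theta 0.20), or
#'   `"random_monotone"`.
#' @param I,J grid shape for `"random_monotone"` (default 4 x 4).
#' @param pi_range range of true probabilities for `"random_monotone"`.
#' @param theta target level; defaults to the fixture's published level,
#'   or 0.30 for random grids.
#' @return object of class `scenario`: list with `truth` (I x J matrix,
#'   drug A rows ascending), `theta`, `name`.
#' @export
#' @examples
#' make_scenario("table1_s1")$truth[1, 1]  # 0.02
make_scenario <- function(kind, I = 4L, J = 4L, pi_range = c(0.02, 0.6),
                          theta = NULL) {
  truth <- switch(kind,
    table1_s1 = .study1_truth$s1, table1_s2 = .study1_truth$s2,
    table1_s3 = .study1_truth$s3, table1_s4 = .study1_truth$s4,
    table2_A = .study2_truth$A, table2_E = .study2_truth$E,
    random_monotone = {
      inc <- matrix(runif(I * J), I, J)
      cum <- t(apply(apply(inc, 2L, cumsum), 1L, cumsum))
      lo <- pi_range[1L]; hi <- pi_range[2L]
      lo + (hi - lo) * (cum - min(cum)) / (max(cum) - min(cum) + 1e-12)
    },
    stop(sprintf("unknown scenario kind '%s'", kind), call. = FALSE))
  if (is.null(theta))
    theta <- if (kind %in% c("table2_A", "table2_E")) 0.20 else 0.30
  if (!is_monotone_grid(truth))
    stop("scenario truth grid must be monotone in both dose indices",
         call. = FALSE)
  structure(list(truth = truth, theta = theta, name = kind),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d x %d truth grid, theta = %g, risks %g-%g\n",
              x$name, nrow(x$truth), ncol(x$truth), x$theta,
              min(x$truth), max(x$truth)))
  invisible(x)
}
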