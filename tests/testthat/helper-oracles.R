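# Independent oracles used across the suite.  These deliberately avoid
# the package's own lattice machinery: up-sets are found by filtering all
# 2^(I*J) binary matrices, and products are accumulated directly.

# every binary I x J matrix, as a list
all_binary_matrices <- function(I, J) {
  n <- I * J
  lapply(seq_len(2^n) - 1L, function(k)
    matrix(as.integer(intToBits(k)[seq_len(n)]), I, J))
}

# up-set check straight from the definition
is_up_set <- function(m) {
  I <- nrow(m); J <- ncol(m)
  for (i in seq_len(I)) for (j in seq_len(J)) if (m[i, j] == 1L) {
    if (i < I && m[i + 1L, j] != 1L) return(FALSE)
    if (j < J && m[i, j + 1L] != 1L) return(FALSE)
  }
  TRUE
}

brute_force_contours <- function(I, J)
  Filter(is_up_set, all_binary_matrices(I, J))

# direct product score of one binary matrix given a tail grid
brute_product <- function(p, m) prod(ifelse(m == 1L, 1 - p, p))

# random monotone probability grid (independent of make_scenario)
random_monotone_grid <- function(I, J, lo = 0.05, hi = 0.6) {
  g <- matrix(sort(runif(I * J, lo, hi)), I, J)  # sorted fill is monotone
  g
}

# heights key for contour identity checks
hkey <- function(contour) paste(contour$heights, collapse = "-")

# standard study fixtures used by several files
study1_prior <- function(strength = 1 / 36) {
  s1 <- make_scenario("table1_s1")
  calibrate_grid(prior_spec(s1$truth, strength, 0.30))
}
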