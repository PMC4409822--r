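# Internal helpers shared across modules.  Grid convention throughout:
# matrices are I x J with row i = drug A level (ascending) and column
# j = drug B level (ascending), so grid[i, j] refers to combination d_ij
# and toxicity is assumed nondecreasing in both indices.

# Is a numeric matrix nondecreasing in both indices?
is_monotone_grid <- function(m, strict = FALSE, tol = 0) {
  cmp <- if (strict) function(d) all(d > tol) else function(d) all(d >= -tol)
  ok_rows <- nrow(m) < 2L || cmp(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  ok_cols <- ncol(m) < 2L || cmp(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  ok_rows && ok_cols
}

assert_same_shape <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# Maximal elements of a set of lattice points under the componentwise
# partial order.  `cells` is a 2-column matrix of (i, j) pairs.
maximal_cells <- function(cells) {
  if (nrow(cells) == 0L) return(cells)
  keep <- vapply(seq_len(nrow(cells)), function(k) {
    dom <- cells[, 1L] >= cells[k, 1L] & cells[, 2L] >= cells[k, 2L]
    dom[k] <- FALSE
    !any(dom)
  }, logical(1L))
  cells[keep, , drop = FALSE]
}

minimal_cells <- function(cells) {
  if (nrow(cells) == 0L) return(cells)
  keep <- vapply(seq_len(nrow(cells)), function(k) {
    dom <- cells[, 1L] <= cells[k, 1L] & cells[, 2L] <= cells[k, 2L]
    dom[k] <- FALSE
    !any(dom)
  }, logical(1L))
  cells[keep, , drop = FALSE]
}

# Logical I x J mask -> 2-column (i, j) matrix, row-major over i then j.
mask_to_cells <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- NULL
  w[order(w[, 1L], w[, 2L]), , drop = FALSE]
}

cells_to_mask <- function(cells, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  if (nrow(cells)) m[cells] <- TRUE
  m
}

cell_key <- function(cells) paste(cells[, 1L], cells[, 2L], sep = ",")
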