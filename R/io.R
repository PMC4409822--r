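# Grid file I/O, configuration, trial-state persistence and report
# rendering.  Grid CSVs are written with rows = drug B levels descending
# by default (the visual convention of published dose-combination tables,
# highest drug-B row on top) with an explicit row_order marker so files
# cannot be silently transposed or flipped on reload.

#' Write a dose-combination grid to CSV
#'
#' @param grid numeric I x J matrix in the package convention (rows =
#'   drug A ascending, columns = drug B ascending).
#' @param path output file.
#' @param row_order `"descending"` (default: file rows are drug B from
#'   highest to lowest) or `"ascending"`.
#' @export
write_grid_csv <- function(grid, path, row_order = c("descending", "ascending")) {
  row_order <- match.arg(row_order)
  I <- nrow(grid); J <- ncol(grid)
  jb <- if (row_order == "descending") J:1L else 1L:J
  out <- data.frame(drugB = jb)
  for (i in seq_len(I)) out[[paste0("A", i)]] <- grid[i, jb]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# row_order=%s", row_order), con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a dose-combination grid from CSV
#'
#' Accepts files written by [write_grid_csv()]; the `row_order` header
#' comment (or argument) controls whether file rows are drug B descending
#' or ascending.  Blank cells become `NA` (unspecified medians).
#'
#' @param path input file.
#' @param row_order override when the file lacks a `# row_order=` header.
#' @return numeric I x J matrix in the package convention.
#' @export
read_grid_csv <- function(path, row_order = NULL) {
  first <- readLines(path, n = 1L)
  has_marker <- grepl("^#\\s*row_order=", first)
  if (has_marker) {
    marker <- sub("^#\\s*row_order=", "", trimws(first))
    if (!is.null(row_order) && !identical(row_order, marker))
      stop(sprintf("file declares row_order=%s but %s was requested",
                   marker, row_order), call. = FALSE)
    row_order <- marker
  } else if (is.null(row_order)) row_order <- "descending"
  if (!row_order %in% c("descending", "ascending"))
    stop("row_order must be 'descending' or 'ascending'", call. = FALSE)
  df <- read.csv(path, comment.char = "#")
  jb <- df$drugB
  acol <- grep("^A[0-9]+$", names(df), value = TRUE)
  I <- length(acol); J <- nrow(df)
  grid <- matrix(NA_real_, I, J)
  for (i in seq_len(I)) grid[i, jb] <- df[[paste0("A", i)]]
  grid
}

#' Load a design configuration (and optional prior spec) from JSON
#'
#' The configuration file is a single JSON object.  Recognised keys:
#' `theta` (required), `epsilon`, `cohort_size`, `n_cohorts`, `strategy`,
#' `selection`, `constraint`, `coherence`, `start_dose`, `seed`, and
#' optionally `median_grid_file` / `strength` (or `strength_grid_file`)
#' plus `row_order` for the prior elicitation.  Omitted design keys get
#' the conventional defaults (epsilon 0.8, cohorts of 2 x 20,
#' neighbourhood constraint, closest strategy, minimum-sample-size
#' selection, start at the lowest combination).
#'
#' @param path JSON file.
#' @param base_dir directory against which relative grid-file paths are
#'   resolved (default: the config file's directory).
#' @return list with `options` ([design_options()]) and `prior_spec`
#'   (a [prior_spec()] or `NULL` when no prior files are referenced).
#' @export
load_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$theta))
    stop("config error: field 'theta' is required", call. = FALSE)
  num1 <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (is.null(v)) return(NULL)
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      stop(sprintf("config error: field '%s' must be a number in [%g, %g]",
                   field, lo, hi), call. = FALSE)
    v
  }
  opts <- design_options(
    theta = num1("theta", 1e-9, 1 - 1e-9),
    epsilon = num1("epsilon", 1e-9, 1) %||% 0.8,
    cohort_size = num1("cohort_size", 1, Inf) %||% 2L,
    n_cohorts = num1("n_cohorts", 1, Inf) %||% 20L,
    strategy = cfg$strategy %||% "closest",
    selection = cfg$selection %||% "min_sample_size",
    constraint = cfg$constraint %||% "neighbourhood",
    coherence = cfg$coherence %||% FALSE,
    start_dose = unlist(cfg$start_dose) %||% c(1L, 1L),
    seed = num1("seed", -2^31, 2^31) %||% 1L)
  spec <- NULL
  if (!is.null(cfg$median_grid_file)) {
    mg <- read_grid_csv(file.path(base_dir, cfg$median_grid_file),
                        row_order = cfg$row_order)
    strength <- if (!is.null(cfg$strength_grid_file))
      read_grid_csv(file.path(base_dir, cfg$strength_grid_file),
                    row_order = cfg$row_order)
    else cfg$strength %||% (1 / length(mg))
    spec <- prior_spec(mg, strength, opts$theta)
  }
  list(options = opts, prior_spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load trial state
#'
#' Persists everything needed to resume a trial and reproduce its
#' remaining decisions: prior hyperparameters, per-dose counts, cohort
#' history, design options and the master seed.  JSON, round-trip exact
#' for integer counts and to full double precision for hyperparameters.
#'
#' @param prior a [beta_grid()].
#' @param data a [trial_data()].
#' @param options a [design_options()].
#' @param path file to write / read.
#' @return `save_trial_state`: the path, invisibly.  `load_trial_state`:
#'   list with `prior`, `data`, `options`.
#' @export
save_trial_state <- function(prior, data, options, path) {
  state <- list(
    a = prior$a, b = prior$b, n = data$n, x = data$x,
    history = data$history,
    options = unclass(options))
  jsonlite::write_json(state, path, digits = NA)
  invisible(path)
}

#' @rdname save_trial_state
#' @export
load_trial_state <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  dimfix <- function(m) if (is.matrix(m)) m else as.matrix(m)
  prior <- beta_grid(dimfix(st$a), dimfix(st$b))
  hist <- if (length(st$history) && nrow(as.data.frame(st$history)))
    as.data.frame(st$history) else NULL
  data <- trial_data(dimfix(st$n), dimfix(st$x), hist)
  o <- st$options
  options <- design_options(theta = o$theta, epsilon = o$epsilon,
                            cohort_size = o$cohort_size,
                            n_cohorts = o$n_cohorts, strategy = o$strategy,
                            selection = o$selection, constraint = o$constraint,
                            coherence = o$coherence, start_dose = o$start_dose,
                            seed = o$seed)
  list(prior = prior, data = data, options = options)
}

#' Render an operating-characteristics table
#'
#' Formats a [simulate_many()] result in the published table layouts:
#' study 1 gives five experimentation and five recommendation band
#' percentages plus the mean number of recommended doses (11 numeric
#' columns); study 2 gives at-theta / within-10 / over-10 / none columns
#' for recommendation and experimentation (8 numeric columns).
#' Percentages are rounded to integers at render time only; the mean
#' count keeps one decimal.
#'
#' @param oc a `pipe_oc` object.
#' @param style override the OC's own band style.
#' @return a single character string (the table, newline-terminated).
#' @export
render_oc_table <- function(oc, style = oc$style) {
  stopifnot(inherits(oc, "pipe_oc"))
  if (oc$n_trials < 1L) stop("cannot render a zero-trial OC", call. = FALSE)
  if (style != oc$style)
    stop("OC was aggregated under a different band style", call. = FALSE)
  fmt_row <- function(vals) paste(vals, collapse = "\t")
  if (style == "study1") {
    labs <- toxicity_bands("study1")$label
    header <- fmt_row(c("scenario", paste0("exp_", labs), paste0("rec_", labs),
                        "mean_n_rec"))
    row <- fmt_row(c(oc$scenario,
                     round(oc$experimentation_pct[labs]),
                     round(oc$recommendation_pct[labs]),
                     sprintf("%.1f", oc$mean_n_recommended)))
  } else {
    labs <- c("at_theta", "within_10", "over_10")
    header <- fmt_row(c("scenario", paste0("rec_", labs), "rec_none",
                        paste0("exp_", labs), "exp_none"))
    row <- fmt_row(c(oc$scenario,
                     round(oc$recommendation_pct[labs]), round(oc$none_pct),
                     round(oc$experimentation_pct[labs]),
                     round(oc$untreated_pct)))
  }
  paste0(header, "\n", row, "\n")
}
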