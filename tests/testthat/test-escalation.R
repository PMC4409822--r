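test_that("partition splits the grid by the contour", {
  allbelow <- contour_from_heights(c(2L, 2L), 2)
  pr <- partition(allbelow)
  expect_identical(nrow(pr$below), 4L)
  expect_identical(nrow(pr$above), 0L)
  allabove <- contour_from_heights(c(0L, 0L), 2)
  expect_identical(nrow(partition(allabove)$above), 4L)
  top <- contour_from_heights(c(2L, 1L), 2)
  expect_identical(nrow(partition(top)$below), 3L)
})

test_that("closest doses are maximal-below plus minimal-above", {
  top <- contour_from_heights(c(2L, 1L), 2)   # only (2,2) above
  cl <- closest_doses(top)
  expect_setequal(pipedose:::cell_key(cl$doses), c("1,2", "2,1", "2,2"))
  expect_setequal(cl$provenance[pipedose:::cell_key(cl$doses) == "2,2"],
                  "closest_above")

  allbelow <- closest_doses(contour_from_heights(c(3L, 3L, 3L), 3))
  expect_identical(pipedose:::cell_key(allbelow$doses), "3,3")

  c33 <- contour_from_heights(c(3L, 3L, 2L), 3)  # only (3,3) above
  expect_setequal(pipedose:::cell_key(closest_doses(c33)$doses),
                  c("2,3", "3,2", "3,3"))
})

test_that("closest within a restricted box identifies the local frontier", {
  c33 <- contour_from_heights(c(3L, 3L, 2L), 3)
  # box on both sides of the contour: local maximal-below + minimal-above
  box <- pipedose:::mask_to_cells(
    cells_ok <- matrix(c(FALSE, FALSE, FALSE,
                         TRUE, TRUE, TRUE,
                         TRUE, TRUE, TRUE), 3, 3, byrow = TRUE))
  w <- closest_doses(c33, within = box)
  expect_setequal(pipedose:::cell_key(w$doses), c("2,3", "3,2", "3,3"))
  expect_true(all(w$provenance != "largest_fallback"))
  # one-sided box degrades to the largest doses, tagged as fallback
  lowbox <- pipedose:::mask_to_cells(matrix(c(TRUE, TRUE, FALSE,
                                              TRUE, TRUE, FALSE,
                                              FALSE, FALSE, FALSE),
                                            3, 3, byrow = TRUE))
  f <- closest_doses(c33, within = lowbox)
  expect_identical(pipedose:::cell_key(f$doses), "2,2")
  expect_identical(f$provenance, "largest_fallback")
})

test_that("adjacent doses trace the staircase curve", {
  c33 <- contour_from_heights(c(3L, 3L, 2L), 3)
  expect_setequal(pipedose:::cell_key(adjacent_doses(c33)$doses),
                  c("1,3", "2,3", "3,2", "3,3"))
  top <- contour_from_heights(c(2L, 1L), 2)
  expect_setequal(pipedose:::cell_key(adjacent_doses(top)$doses),
                  pipedose:::cell_key(closest_doses(top)$doses))
})

test_that("closest is a subset of adjacent over exhaustive contours", {
  for (I in 2:4) for (J in 2:4) {
    cs <- enumerate_contours(I, J)
    for (s in seq_len(nrow(cs$heights))) {
      ct <- contour_from_heights(cs$heights[s, ], J)
      cl <- pipedose:::cell_key(closest_doses(ct)$doses)
      ad <- pipedose:::cell_key(adjacent_doses(ct)$doses)
      expect_true(all(cl %in% ad),
                  label = sprintf("%dx%d contour %s", I, J, hkey(ct)))
    }
  }
})

test_that("closest-below doses dominate their below-contour chains", {
  set.seed(5)
  truth <- random_monotone_grid(3, 3)
  cs <- enumerate_contours(3, 3)
  for (s in seq_len(nrow(cs$heights))) {
    ct <- contour_from_heights(cs$heights[s, ], 3)
    below <- pipedose:::mask_to_cells(ct$above == 0L)
    for (k in seq_len(nrow(pipedose:::maximal_cells(below)))) {
      mx <- pipedose:::maximal_cells(below)[k, ]
      dominated <- below[below[, 1] <= mx[1] & below[, 2] <= mx[2], ,
                         drop = FALSE]
      expect_true(all(truth[dominated] <= truth[mx[1], mx[2]]))
    }
  }
})

test_that("dose-skipping constraints clip to the documented boxes", {
  all6 <- pipedose:::mask_to_cells(matrix(TRUE, 6, 6))
  b11 <- apply_neighbourhood_constraint(all6, c(1, 1))
  expect_setequal(pipedose:::cell_key(b11), c("1,1", "1,2", "2,1", "2,2"))
  b22 <- apply_neighbourhood_constraint(all6, c(2, 2))
  expect_identical(nrow(b22), 9L)
  expect_true(all(b22 >= 1 & b22 <= 3))
  corner <- apply_neighbourhood_constraint(all6, c(6, 6))
  expect_setequal(pipedose:::cell_key(corner), c("5,5", "5,6", "6,5", "6,6"))

  hist <- rbind(c(1, 1), c(1, 2), c(2, 1))
  nn <- apply_non_neighbourhood_constraint(all6, hist)
  want <- unique(rbind(
    expand.grid(i = 1:2, j = 1:3),     # one up from (1,2)
    expand.grid(i = 1:3, j = 1:2)))    # one up from (2,1)
  expect_setequal(pipedose:::cell_key(nn),
                  paste(want$i, want$j, sep = ","))
  # growing the history never shrinks the constrained set
  nn2 <- apply_non_neighbourhood_constraint(all6, rbind(hist, c(2, 2)))
  expect_true(all(pipedose:::cell_key(nn) %in% pipedose:::cell_key(nn2)))
  expect_error(apply_non_neighbourhood_constraint(all6, hist[0, , drop = FALSE]),
               "nonempty")
})

test_that("safety constraint excludes doses at or past epsilon", {
  q <- above_mtc_probability(contour_posterior(matrix(0.5, 2, 2)))
  all4 <- pipedose:::mask_to_cells(matrix(TRUE, 2, 2))
  kept <- apply_safety_constraint(all4, q, 0.8)
  expect_setequal(pipedose:::cell_key(kept), c("1,1", "1,2", "2,1"))
  expect_identical(nrow(apply_safety_constraint(all4, q, 1.0)), 4L)
  expect_identical(nrow(apply_safety_constraint(all4, q, 1e-6)), 0L)
  # intersection filters commute
  box <- apply_neighbourhood_constraint(all4, c(2, 2))
  a <- apply_safety_constraint(box, q, 0.8)
  b <- apply_neighbourhood_constraint(apply_safety_constraint(all4, q, 0.8),
                                      c(2, 2))
  expect_setequal(pipedose:::cell_key(a), pipedose:::cell_key(b))
})

test_that("coherence keeps the opposite side of the contour", {
  top <- contour_from_heights(c(2L, 1L), 2)   # (2,2) above
  cells <- pipedose:::mask_to_cells(matrix(TRUE, 2, 2))
  from_below <- apply_coherence(cells, top, c(1, 1))
  expect_identical(pipedose:::cell_key(from_below), "2,2")
  from_above <- apply_coherence(cells, top, c(2, 2))
  expect_setequal(pipedose:::cell_key(from_above), c("1,1", "1,2", "2,1"))
  expect_identical(nrow(apply_coherence(cells[0, , drop = FALSE], top, c(1, 1))),
                   0L)
})

test_that("fallback takes the largest below doses, else the smallest", {
  ct <- contour_from_heights(c(6L, 6L, 6L, 3L, 3L, 2L), 6)
  box <- pipedose:::mask_to_cells(
    {m <- matrix(FALSE, 6, 6); m[1:2, 1:2] <- TRUE; m})
  f <- fallback_largest(box, ct)
  expect_identical(pipedose:::cell_key(f$doses), "2,2")
  expect_identical(f$provenance, "largest_fallback")
  # box entirely above: minimal elements, forced de-escalation
  allabove <- contour_from_heights(rep(0L, 6), 6)
  f2 <- fallback_largest(box, allabove)
  expect_identical(pipedose:::cell_key(f2$doses), "1,1")
})

test_that("selection rules follow the sample-size semantics", {
  prior <- beta_grid(matrix(0.5, 2, 2), matrix(0.5, 2, 2))  # strength 1 each
  data <- trial_data(matrix(c(0L, 2L, 2L, 0L), 2, 2), matrix(0L, 2, 2))
  aset <- pipedose:::admissible_set(rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2)),
                                    rep("closest_below", 4))
  # sizes: (1,1)=1, (2,1)=3, (1,2)=3, (2,2)=1 -> min rule picks a size-1 dose
  set.seed(3)
  picks <- replicate(200, paste(select_dose(aset, prior, data,
                                            "min_sample_size"), collapse = ","))
  expect_setequal(unique(picks), c("1,1", "2,2"))
  expect_gt(min(table(picks)), 50)   # both ties actually drawn

  # weighted randomisation: P proportional to 1/size -> 0.75 / 0.25
  two <- pipedose:::admissible_set(rbind(c(1, 1), c(2, 1)),
                                   rep("closest_below", 2))
  set.seed(4)
  w <- replicate(4000, paste(select_dose(two, prior, data,
                                         "weighted_randomisation"),
                             collapse = ","))
  expect_equal(mean(w == "1,1"), 0.75, tolerance = 0.03)

  single <- pipedose:::admissible_set(rbind(c(2, 2)), "closest_below")
  expect_identical(select_dose(single, prior, data, "min_sample_size"),
                   c(2, 2))
  expect_error(select_dose(pipedose:::admissible_set(aset$doses[0, , drop = FALSE],
                                                     character()),
                           prior, data), "empty")
})

test_that("phase II recommendation intersects the frontier with experimentation", {
  ct <- contour_from_heights(c(2L, 1L), 2)   # frontier below: (1,2), (2,1)
  n <- matrix(c(2L, 2L, 2L, 0L), 2, 2)       # experimented: (1,1),(2,1),(1,2)
  td <- trial_data(n, matrix(0L, 2, 2))
  rp <- recommend_phase2(ct, td)
  expect_setequal(pipedose:::cell_key(rp), c("1,2", "2,1"))
  # recommendations form an antichain
  for (k in seq_len(nrow(rp))) {
    dom <- rp[, 1] >= rp[k, 1] & rp[, 2] >= rp[k, 2]; dom[k] <- FALSE
    expect_false(any(dom))
  }
  # all experimented doses above the contour -> none
  allabove <- contour_from_heights(c(0L, 0L), 2)
  expect_identical(nrow(recommend_phase2(allabove, td)), 0L)
  # unexperimented frontier -> none
  n2 <- matrix(c(2L, 0L, 0L, 0L), 2, 2)
  expect_identical(nrow(recommend_phase2(ct, trial_data(n2, matrix(0L, 2, 2)))),
                   0L)
})

test_that("next_dose stops when the safe box empties and otherwise doses", {
  prior <- calibrate_grid(prior_spec(matrix(0.3, 2, 2), 1/4, 0.3))
  # overwhelming toxicity everywhere -> every dose past epsilon
  d <- trial_data(matrix(10L, 2, 2), matrix(10L, 2, 2))
  opt <- design_options(theta = 0.3, cohort_size = 2, n_cohorts = 5)
  dec <- next_dose(prior, d, opt, c(1, 1))
  expect_true(dec$stop)
  expect_null(dec$dose)
  # clean data: escalation proceeds within the neighbourhood box
  d0 <- trial_data(matrix(c(2L, 0L, 0L, 0L), 2, 2), matrix(0L, 2, 2))
  set.seed(8)
  dec2 <- next_dose(prior, d0, opt, c(1, 1))
  expect_false(dec2$stop)
  expect_true(all(dec2$dose >= 1 & dec2$dose <= 2))
})

test_that("coherent decisions never escalate after a DLT nor de-escalate after none", {
  scen <- make_scenario("table1_s1")
  prior <- study1_prior()
  opt <- design_options(theta = 0.3, coherence = TRUE)
  cset <- enumerate_contours(6, 6)
  checked <- 0L
  for (t in 1:20) {
    set.seed(pipedose:::trial_seed(17, t))
    n <- x <- matrix(0L, 6, 6); dose <- c(1L, 1L); last_dlts <- 0L
    for (m in 1:20) {
      if (m > 1) {
        dec <- next_dose(prior, trial_data(n, x), opt, dose, cset)
        if (dec$stop) break
        if (last_dlts >= 1L)
          expect_false(all(dec$dose > dose))   # no joint escalation after DLT
        else
          expect_false(all(dec$dose < dose))   # no joint de-escalation after none
        checked <- checked + 1L
        dose <- dec$dose
      }
      last_dlts <- rbinom(1L, 2L, scen$truth[dose[1], dose[2]])
      n[dose[1], dose[2]] <- n[dose[1], dose[2]] + 2L
      x[dose[1], dose[2]] <- x[dose[1], dose[2]] + last_dlts
    }
  }
  expect_gt(checked, 300L)
})
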