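test_that("pairing fraction counts persistently formed pairs", {
  # fully formed duplex: every frame, every pair at reference
  full <- fake_series(matrix(1, 20, 6))
  expect_equal(pairing_fraction(full, 20), 1)
  # fully separated strands
  apart <- fake_series(matrix(0, 20, 6))
  expect_equal(pairing_fraction(apart, 20), 0)
  # 3 of 6 pairs persist
  half <- fake_series(cbind(matrix(1, 20, 3), matrix(0, 20, 3)))
  expect_equal(pairing_fraction(half, 20), 0.5)
  expect_error(pairing_fraction(full, 1000), "outside")
})

test_that("persistence requires the full trailing window", {
  vals <- matrix(1, 20, 2)
  vals[10, 1] <- 0          # single-frame dip of pair 1
  s <- fake_series(vals)
  expect_equal(pairing_fraction(s, 10), 0.5)   # dip frame: pair 1 out
  expect_equal(pairing_fraction(s, 12), 0.5)   # still inside the window
  expect_equal(pairing_fraction(s, 15), 1)     # window re-filled
})

test_that("disruption detection needs sustained loss of all pairs", {
  never <- fake_series(matrix(1, 30, 4))
  expect_true(is.na(detect_disruption(never)))
  # clean break at frame 11 (time 11)
  vals <- rbind(matrix(1, 10, 4), matrix(0, 20, 4))
  expect_equal(detect_disruption(fake_series(vals)), 11)
  # single-frame dip below threshold is not a disruption
  dip <- matrix(1, 30, 4)
  dip[15, ] <- 0
  expect_true(is.na(detect_disruption(fake_series(dip))))
})

test_that("pre-break profiles average and normalize per pair", {
  # constant full pairing until an instant break at frame 21
  vals <- rbind(matrix(1, 20, 6), matrix(0, 10, 6))
  s <- fake_series(vals)
  prof <- prebreak_profile(s, window = 10)
  expect_equal(unname(prof), rep(1, 6))
  # ends released one window before the break, center held
  vals2 <- rbind(matrix(1, 20, 6), matrix(0, 10, 6))
  vals2[11:20, c(1, 6)] <- 0
  s2 <- fake_series(vals2)
  prof2 <- prebreak_profile(s2, window = 9, t_disrupt = 20)
  expect_equal(unname(prof2[c(1, 6)]), c(0, 0))
  expect_equal(unname(prof2[3]), 1)
  # window shrinks with a warning when the break is early
  vals3 <- rbind(matrix(1, 3, 6), matrix(0, 10, 6))
  expect_warning(prebreak_profile(fake_series(vals3), window = 50),
                 "shrinking")
})

test_that("profiles of permuted series are the same permutation", {
  set.seed(2)
  vals <- rbind(matrix(runif(60, 0.5, 1), 10, 6), matrix(0, 8, 6))
  perm <- c(3, 1, 6, 2, 4, 5)
  p1 <- prebreak_profile(fake_series(vals), window = 5, t_disrupt = 10)
  p2 <- prebreak_profile(fake_series(vals[, perm]), window = 5,
                         t_disrupt = 10)
  expect_equal(unname(p2), unname(p1)[perm])
})

test_that("raising the persistence threshold never raises the fraction", {
  set.seed(6)
  vals <- matrix(runif(120, 0, 1), 20, 6)
  s <- fake_series(vals)
  f <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    pairing_fraction(s, 20, theta_on = th), numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("pairing values are invariant to rigid motion and near reference at the ideal start", {
  sysd <- make_duplex_system(hexamer_duplex())
  pv <- pairing_values(sysd$coords0, sysd)
  expect_true(all(pv > 0.9))
  moved <- rigid_motion(sysd$coords0, seed = 4)
  expect_equal(pairing_values(moved, sysd), pv, tolerance = 1e-9)
})

test_that("melt scan bookkeeping flags undisrupted runs and errors when none disrupt", {
  sysd <- make_duplex_system(hexamer_duplex())
  # far below melting: no disruption
  expect_error(melt_scan(sysd, 150, 1, steps = 30000),
               "longer runs or higher temperatures")
  # far above: everything disrupts
  ms <- melt_scan(sysd, 500, 1:2, steps = 60000, window = 20)
  expect_true(all(!is.na(ms$results$disruption_time)))
  expect_equal(dim(ms$profiles), c(2L, 6L))
  expect_true(all(ms$average_profile >= 0 & ms$average_profile <= 1))
})

test_that("anneal classification distinguishes an intact duplex from separated strands", {
  sysd <- make_duplex_system(hexamer_duplex())
  # scenario 3 re-anneals quickly at 300 K
  ar <- anneal_run(sysd, 3, steps = 120000, seed = 2, sample_stride = 200)
  expect_equal(ar$outcome, "full")
  expect_false(is.na(ar$time_to_anneal))
  expect_true(ar$nucleation_pair %in% 1:6)
  expect_equal(names(ar$formation_times), sysd$topology$pair_labels)
})
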