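test_that("the bias potential matches a brute-force Gaussian sum", {
  mp <- metad_params(sigma = c(0.05, 0.1))
  h0 <- hills(sigma = c(0.05, 0.1), gamma = 30, cv_names = c("a", "b"))
  expect_equal(bias_value(h0, c(0.3, 0.2)), 0)
  expect_equal(bias_gradient(h0, c(0.3, 0.2)), matrix(0, 1, 2))
  h1 <- deposit_hill(h0, c(0.3, 0.2), mp, time = 1)
  expect_equal(bias_value(h1, c(0.3, 0.2)), 2.5)   # height at own center
  # 50 random hills vs direct summation
  set.seed(8)
  cen <- cbind(runif(50), runif(50))
  W <- runif(50, 0.5, 2.5)
  h50 <- hills(1:50, cen, W, sigma = c(0.05, 0.1), gamma = 30,
               cv_names = c("a", "b"))
  for (i in 1:10) {
    s <- runif(2)
    direct <- sum(W * exp(-((s[1] - cen[, 1])^2 / (2 * 0.05^2) +
                              (s[2] - cen[, 2])^2 / (2 * 0.1^2))))
    expect_equal(bias_value(h50, s), direct, tolerance = 1e-12)
    # gradient vs numerical differentiation of the direct sum
    eps <- 1e-7
    g <- bias_gradient(h50, s)
    for (d in 1:2) {
      sp <- s; sm <- s; sp[d] <- sp[d] + eps; sm[d] <- sm[d] - eps
      expect_equal(g[1, d],
                   (bias_value(h50, sp) - bias_value(h50, sm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("well-tempered deposition decays heights as prescribed", {
  mp <- metad_params(W0 = 2.5, sigma = 0.01, gamma = 30, temperature = 300)
  h <- hills(sigma = 0.01, gamma = 30, cv_names = "x")
  h <- deposit_hill(h, 0, mp, time = 1)
  expect_identical(h$height[1], 2.5)               # V = 0 gives W0 exactly
  # stack hills at one point until V = kB (gamma-1) T, then W = W0/e
  kBdT <- kB_kJmol() * 29 * 300
  hmany <- hills(1, matrix(0), kBdT, sigma = 5, gamma = 30, cv_names = "x")
  h2 <- deposit_hill(hmany, 0, mp, time = 2)
  expect_equal(h2$height[2], 2.5 * exp(-1), tolerance = 1e-6)
  # gamma -> infinity: standard metadynamics, heights constant
  mp_inf <- metad_params(W0 = 2.5, sigma = 0.01, gamma = 1e12)
  h3 <- deposit_hill(hmany, 0, mp_inf, time = 2)
  expect_equal(h3$height[2], 2.5, tolerance = 1e-9)
  expect_error(metad_params(gamma = 1), "gamma")
})

test_that("fes_from_hills reconstructs the closed-form single-hill surface", {
  mp <- metad_params(sigma = 0.02, gamma = 30)
  edges <- list(seq(-0.5, 0.5, length.out = 401))
  h0 <- hills(sigma = 0.02, gamma = 30, cv_names = "x")
  f0 <- fes_from_hills(h0, edges, mp)
  expect_true(all(f0$F == 0))                       # empty hills: flat zero
  h1 <- hills(1, matrix(0.1), 2.0, sigma = 0.02, gamma = 30, cv_names = "x")
  f1 <- fes_from_hills(h1, edges, mp)
  expect_equal(min(f1$F), 0)
  i_cen <- which.min(abs(f1$mids[[1]] - 0.1))
  expect_equal(f1$F[i_cen], 0, tolerance = 1e-6)    # min at the center
  # far field reaches (gamma/(gamma-1)) W up to the half-bin offset of
  # the hill center from the nearest grid center
  expect_equal(f1$F[1L], 30 / 29 * 2.0, tolerance = 5e-3)
})

test_that("unit conversion uses the exact thermochemical factor", {
  f <- fes_grid(list(0:2), c(4.184, 0), units = "kJ/mol")
  fk <- convert_units(f, "kcal/mol")
  expect_equal(fk$F, c(1, 0))
  expect_equal(convert_units(fk, "kJ/mol")$F, f$F, tolerance = 1e-12)
  expect_equal(min(fk$F), 0)
})

test_that("zero-height hills reproduce the unbiased trajectory", {
  pot <- analytic_potential("double_well_1d", h = 10, a = 0.5, c = 0)
  mp0 <- metad_params(W0 = 0, sigma = 0.01, gamma = 30)
  biased <- run_wtmetad(pot, mp0, steps = 20000, seed = 5, dt = 0.005,
                        friction = 10, sample_stride = 20)
  plain <- run_wtmetad(pot, metad_params(W0 = 1e-300, sigma = 0.01),
                       steps = 20000, seed = 5, dt = 0.005, friction = 10,
                       sample_stride = 20)
  expect_equal(biased$cvs$x1, plain$cvs$x1, tolerance = 1e-12)
  expect_true(all(biased$cvs$bias == 0))
})

test_that("biased runs cross the barrier that traps unbiased dynamics", {
  # 18 kJ/mol barrier (~7 kT): unbiased dynamics stays in one well at
  # this seed and length; the bias produces hundreds of transitions
  pot <- analytic_potential("double_well_1d", h = 18, a = 0.5, c = 3)
  mp <- metad_params(W0 = 2.5, sigma = 0.01, gamma = 30)
  biased <- run_wtmetad(pot, mp, steps = 300000, seed = 3, dt = 0.005,
                        friction = 10, sample_stride = 50)
  crossings <- function(x) sum(abs(diff(sign(x))) > 0)
  unbiased <- run_wtmetad(pot, metad_params(W0 = 1e-300, sigma = 0.01),
                          steps = 300000, seed = 3, dt = 0.005,
                          friction = 10, sample_stride = 50)
  expect_gt(crossings(biased$cvs$x1), 50)
  expect_equal(crossings(unbiased$cvs$x1), 0)       # one-well trapping
})

test_that("hill heights are bounded by W0 and monotone at fine grid cells", {
  pot <- analytic_potential("double_well_1d", h = 15, a = 0.5, c = 3)
  mp <- metad_params(W0 = 2.5, sigma = 0.01, gamma = 30)
  run <- run_wtmetad(pot, mp, steps = 400000, seed = 2, dt = 0.005,
                     friction = 10, sample_stride = 50)
  h <- run$hills
  expect_identical(h$height[1], 2.5)
  expect_true(all(h$height > 0 & h$height <= 2.5))
  cell <- round(h$x1 / (0.01 / 8))
  for (cl in unique(cell)) {
    w <- h$height[cell == cl]
    if (length(w) > 1) expect_true(all(diff(w) <= 1e-9))
  }
})

test_that("reweighting with zero bias is a plain histogram", {
  set.seed(4)
  x <- rnorm(4000)
  x <- x[abs(x) < 3]
  cvs <- data.frame(time = seq_along(x), x = x, bias = 0)
  h0 <- hills(sigma = 0.1, gamma = 30, cv_names = "x")
  edges <- list(seq(-3, 3, length.out = 31))
  rw <- reweight_fes(cvs, h0, "x", edges, metad_params(sigma = 0.1))
  counts <- hist(cvs$x, breaks = edges[[1]], plot = FALSE)$counts
  Fref <- -kB_kJmol() * 300 * log(counts / sum(counts))
  Fref <- Fref - min(Fref[is.finite(Fref)])
  expect_equal(rw$F, Fref, tolerance = 1e-9)
})

test_that("hills and FES files round-trip through their text dialects", {
  set.seed(9)
  h <- hills(1:20, cbind(runif(20), runif(20)), runif(20, 0.1, 2.5),
             sigma = c(0.05, 0.1), gamma = 30, cv_names = c("ht", "stk"))
  path <- tempfile()
  write_hills(h, path)
  h2 <- read_hills(path)
  expect_equal(attr(h2, "cv_names"), c("ht", "stk"))
  expect_equal(attr(h2, "sigma"), c(0.05, 0.1))
  expect_equal(h2$height, h$height, tolerance = 1e-6)
  expect_equal(bias_value(h2, c(0.5, 0.5)), bias_value(h, c(0.5, 0.5)),
               tolerance = 1e-5)
})
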