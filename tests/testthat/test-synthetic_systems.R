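test_that("single-strand systems have 4 sites per monomer and gamma terms only when asked", {
  sys <- make_ss_system("GAACTC", "pna")
  expect_equal(sys$n_sites, 24L)
  expect_null(sys$torsions)
  sysg <- make_ss_system("GAACTC", "gamma_pna")
  expect_equal(sysg$n_sites, 24L)
  expect_gt(nrow(sysg$torsions), 0)          # torsional bias terms present
  expect_equal(nrow(sysg$bonds), nrow(sys$bonds))  # same bonded topology
  # kappa_gamma = 0 reproduces the unmodified model exactly
  sys0 <- make_ss_system("GAACTC", "gamma_pna", cg_params(kappa_gamma = 0))
  expect_null(sys0$torsions)
  expect_equal(cg_energy(sys0)$energy, cg_energy(sys)$energy)
  expect_error(make_ss_system("GAXCTC", "pna"), "invalid base")
})

test_that("the ideal-helix start beats random coils energetically", {
  sys <- make_ss_system("GAACTC", "pna")
  e0 <- cg_energy(sys)$energy
  expect_true(is.finite(e0))
  coils <- vapply(1:100, function(sd)
    cg_energy(sys, random_coil(sys, seed = sd))$energy, numeric(1))
  expect_lt(e0, mean(coils))
})

test_that("duplex systems carry 15 H-bond units split 7 + 8", {
  dx <- hexamer_duplex()
  sysd <- make_duplex_system(dx)
  expect_equal(nrow(sysd$hb_pairs), 6L)
  expect_equal(sum(sysd$hb_w), 15)
  expect_equal(sum(sysd$hb_w[1:3]), 7)
  expect_equal(sum(sysd$hb_w[4:6]), 8)
  sys1 <- make_duplex_system(build_duplex("G", "C"))
  expect_equal(nrow(sys1$hb_pairs), 1L)
  expect_equal(sys1$hb_w, 3L)
})

test_that("pairing energy at the ideal geometry is -15 eps_hb within switching tolerance", {
  sysd <- make_duplex_system(hexamer_duplex())
  p <- sysd$params
  # total energy difference when the pairing wells are switched off
  p0 <- p; p0$eps_hb <- 0
  sys0 <- sysd; sys0$params <- p0
  e_pair <- cg_energy(sysd)$energy - cg_energy(sys0)$energy
  expect_lt(abs(e_pair + 15 * p$eps_hb), 0.05 * 15 * p$eps_hb)
})

test_that("distorted duplex scenarios have the stated geometry", {
  sysd <- make_duplex_system(hexamer_duplex())
  pair_d <- function(conf) {
    vapply(seq_len(6), function(p) {
      ca <- colMeans(conf[sysd$plane_sites[sysd$hb_pairs[p, 1], ], ])
      cb <- colMeans(conf[sysd$plane_sites[sysd$hb_pairs[p, 2], ], ])
      sqrt(sum((ca - cb)^2))
    }, numeric(1))
  }
  # scenario 3: uniform separation in the 0.5-0.6 nm band, bases facing
  d3 <- pair_d(make_distorted_duplex(sysd, 3))
  expect_true(all(d3 >= 0.5 & d3 <= 0.6))
  # scenarios 1/2: exactly one pair within pairing range (C- / N-side)
  d1 <- pair_d(make_distorted_duplex(sysd, 1))
  expect_equal(sum(d1 < 0.3), 1L)
  expect_lt(d1[6], 0.3)
  d2 <- pair_d(make_distorted_duplex(sysd, 2))
  expect_equal(sum(d2 < 0.3), 1L)
  expect_lt(d2[1], 0.3)
  # scenario 4: central pairs closest, termini far
  d4 <- pair_d(make_distorted_duplex(sysd, 4))
  expect_true(all(d4[c(3, 4)] < d4[c(1, 6)]))
  # scenario 5: no pairing at t = 0
  conf5 <- make_distorted_duplex(sysd, 5, seed = 3)
  expect_equal(sum(pairing_values(conf5, sysd) >
                     0.5 * pairing_values(sysd$coords0, sysd)), 0L)
  expect_error(make_distorted_duplex(sysd, 9), "unknown scenario")
})

test_that("simulation runs are reproducible and stay at temperature", {
  sys <- make_ss_system("GAACTC", "pna")
  r1 <- run_md(sys, 20000, temperature = 300, seed = 7)
  r2 <- run_md(sys, 20000, temperature = 300, seed = 7)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  expect_identical(r1$cvs, r2$cvs)
  # kinetic temperature estimate within 5%
  Tins <- mean(r1$cvs$ekin) * 2 / (3 * sys$n_sites * kB_kJmol())
  expect_lt(abs(Tins - 300) / 300, 0.05)
})

test_that("a zero-temperature quench from the minimum is stationary", {
  sys <- make_ss_system("GAAC", "pna")
  mini <- minimize_energy(sys, steps = 4000, step_size = 2e-4,
                          max_disp = 0.005)
  r <- run_md(sys, 2000, temperature = 0, seed = 1, conf = mini,
              sample_stride = 100)
  drift <- max(abs(frame_coords(r$trajectory, n_frames(r$trajectory)) - mini))
  expect_lt(drift, 0.02)
})

test_that("mean bond length matches the rest length at low temperature", {
  sys <- make_ss_system("GAAC", "pna")
  r <- run_md(sys, 50000, temperature = 50, seed = 3, sample_stride = 50)
  b <- sys$bonds[1, ]
  d <- sqrt(colSums((r$trajectory$frames[b[1], , ] -
                       r$trajectory$frames[b[2], , ])^2))
  se <- sd(d) / sqrt(length(d) / 20)   # generous autocorrelation factor
  expect_lt(abs(mean(d) - b[3]), 3 * se + 0.002)
})

test_that("the frictionless integrator conserves energy at halved time step", {
  sys <- make_ss_system("GAACTC", "pna")
  mini <- minimize_energy(sys, steps = 3000, step_size = 2e-4,
                          max_disp = 0.005)
  set.seed(42)
  conf <- mini + matrix(rnorm(length(mini), sd = 0.002), ncol = 3)
  r <- run_md(sys, 10000, temperature = 0, seed = 1, friction = 0,
              dt = sys$params$dt / 2, conf = conf, sample_stride = 10)
  etot <- r$cvs$epot + r$cvs$ekin
  expect_lt((max(etot) - min(etot)) / abs(etot[1]), 1e-4)
})

test_that("divergent dynamics abort with a diagnostic", {
  sys <- make_ss_system("GAAC", "pna")
  expect_error(run_md(sys, 5000, temperature = 300, seed = 1, dt = 0.5),
               "divergence")
})

test_that("quadrature FES oracles behave on the benchmark potentials", {
  e <- list(seq(-1, 1, length.out = 201))
  # symmetric double well: basins balance exactly
  ps <- analytic_potential("double_well_1d", h = 15, a = 0.5, c = 0)
  expect_equal(fes_basin_delta(fes_by_quadrature(ps, 300, e), 300), 0,
               tolerance = 1e-12)
  # tilted well: two quadrature resolutions agree
  pt <- analytic_potential("double_well_1d", h = 15, a = 0.5, c = 3)
  d1 <- fes_basin_delta(fes_by_quadrature(pt, 300, e, subdiv = 10), 300)
  d2 <- fes_basin_delta(fes_by_quadrature(pt, 300, e, subdiv = 40), 300)
  expect_equal(d1, d2, tolerance = 1e-8)
  expect_lt(d1, 0)   # tilt favours the left basin
  # harmonic well: parabolic FES with the input curvature
  ph <- analytic_potential("harmonic", k = 100)
  fq <- fes_by_quadrature(ph, 300, list(seq(-0.3, 0.3, length.out = 121)))
  fit <- lm(fq$F ~ I(fq$mids[[1]]^2))
  expect_equal(unname(2 * coef(fit)[2]), 100, tolerance = 0.01)
  expect_equal(min(fq$F), 0)
})

test_that("gamma-biased strands stack sequentially more than unmodified ones", {
  sp <- make_ss_system("GAACTC", "pna")
  sg <- make_ss_system("GAACTC", "gamma_pna")
  wins <- 0L
  for (sd in 1:10) {
    r0 <- run_md(sp, 60000, temperature = 300, seed = sd,
                 store_frames = FALSE)
    r1 <- run_md(sg, 60000, temperature = 300, seed = sd,
                 store_frames = FALSE)
    n <- nrow(r0$cvs)
    sel <- seq(n %/% 2, n)
    wins <- wins + (mean(r1$cvs$sstk[sel]) >= mean(r0$cvs$sstk[sel]))
  }
  expect_gte(wins, 8L)
})
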