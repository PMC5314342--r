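# independent brute-force oracles, written from the definitions
oracle_switch <- function(r, r0, n, m) (1 - (r / r0)^n) / (1 - (r / r0)^m)
oracle_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])
oracle_pair <- function(conf, topo, i, j, r0 = 0.4, n = 6, m = 12) {
  cen <- function(i) colMeans(conf[topo$plane_sites[i, ], ])
  nrm <- function(i) {
    p <- conf[topo$plane_sites[i, ], ]
    w <- oracle_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    w / sqrt(sum(w^2))
  }
  d <- sqrt(sum((cen(i) - cen(j))^2))
  oracle_switch(d, r0, n, m) * sum(nrm(i) * nrm(j))^2
}

test_that("the rational switch has the contract limits and monotonicity", {
  sp <- switching_params(0.4, 6, 12)
  expect_equal(switch_value(0.4, sp), 0.5)            # n/m continuity limit
  expect_equal(switch_value(0, sp), 1)
  expect_lt(switch_value(4, sp), 1e-6)
  r <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(switch_value(r, sp)) < 0))     # strictly decreasing
  # smooth through the r = r0 guard band: local slope n(n-m)/(2m)/r0
  rr <- 0.4 + c(-2e-6, -1e-7, 0, 1e-7, 2e-6)
  expect_true(all(abs(diff(switch_value(rr, sp)) + 3.75 * diff(rr)) < 1e-9))
  expect_error(switching_params(0.4, 6, 6))
  expect_error(switching_params(0.4, 5, 12))
})

test_that("head-to-tail distance matches a mass-weighted COM oracle", {
  sys <- make_ss_system("GAACTC", "pna")
  topo <- sys$topology
  # coincident first/last monomer COMs
  conf <- sys$coords0
  conf[monomer_sites(topo, 6), ] <- conf[monomer_sites(topo, 1), ]
  expect_equal(ht_distance(conf, topo), 0)
  # two point-monomer strand at distance 2.1
  st2 <- strand_topology("GA", "pna")
  c2 <- matrix(0, 8, 3)
  c2[5:8, 3] <- 2.1
  expect_equal(ht_distance(c2, st2), 2.1)
  expect_error(ht_distance(c2, strand_topology("G", "pna")), ">= 2")
  # oracle on random conformations
  set.seed(3)
  for (i in 1:5) {
    conf <- perturbed_conf(sys, sd = 0.3, seed = i)
    com <- function(idx) colSums(conf[idx, ] * 1) / length(idx)
    d <- sqrt(sum((com(monomer_sites(topo, 1)) -
                     com(monomer_sites(topo, 6)))^2))
    expect_equal(ht_distance(conf, topo), d, tolerance = 1e-12)
  }
})

test_that("pair stacking has the limit-case values", {
  # two parallel coplanar-normal triangles stacked at small distance
  tri <- rbind(c(0.1, 0, 0), c(-0.05, 0.0866, 0), c(-0.05, -0.0866, 0))
  st2 <- strand_topology("GA", "pna")
  mk <- function(d, rot = diag(3)) {
    conf <- matrix(0, 8, 3)
    conf[2:4, ] <- tri
    conf[6:8, ] <- tri %*% t(rot)
    conf[6:8, 3] <- conf[6:8, 3] + d
    conf
  }
  sp <- switching_params(0.4, 6, 12)
  expect_equal(pair_stacking(mk(1e-4), st2, 1, 2, sp), 1, tolerance = 1e-6)
  # perpendicular planes: rotate the second triangle 90 degrees about x
  rot90 <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  expect_equal(pair_stacking(mk(0.2, rot90), st2, 1, 2, sp), 0,
               tolerance = 1e-12)
  # at d = r0 with parallel planes: the continuity limit n/m
  expect_equal(pair_stacking(mk(0.4), st2, 1, 2, sp), 0.5)
  expect_error(pair_stacking(mk(0.2), st2, 1, 1, sp), "differ")
})

test_that("stk equals the brute-force double loop and decomposes exactly", {
  sys <- make_ss_system("GAACTC", "pna")
  topo <- sys$topology
  set.seed(11)
  for (i in 1:5) {
    conf <- perturbed_conf(sys, sd = 0.15, seed = i)
    brute <- 0
    for (a in 1:5) for (b in (a + 1):6)
      brute <- brute + oracle_pair(conf, topo, a, b)
    expect_equal(stk(conf, topo), brute, tolerance = 1e-12)
    expect_equal(stk(conf, topo),
                 sstk(conf, topo) + nstk(conf, topo), tolerance = 1e-12)
  }
  # ideal helix: sequential contacts dominate
  expect_lt(nstk(sys$coords0, topo), 0.3)
  expect_equal(sstk(sys$coords0, topo), stk(sys$coords0, topo),
               tolerance = 0.1)
})

test_that("a head-to-tail folded conformation has non-sequential stacking only", {
  sys <- make_ss_system("GAACTC", "pna")
  topo <- sys$topology
  conf <- sys$coords0
  # move the last base plane right on top of the first, far from base 5
  shift <- conf[topo$plane_sites[1, ], ] - conf[topo$plane_sites[6, ], ]
  conf[monomer_sites(topo, 6), ] <-
    sweep(conf[monomer_sites(topo, 6), ], 2, shift[1, ] + c(0, 0, 0.25), "+")
  conf[monomer_sites(topo, 5), 3] <- conf[monomer_sites(topo, 5), 3] + 3
  conf[monomer_sites(topo, 4), 3] <- conf[monomer_sites(topo, 4), 3] + 6
  expect_gt(nstk(conf, topo), 0.3)
  expect_gt(nstk(conf, topo), sstk(conf, topo))
})

test_that("coordination sums the per-pair switch values", {
  sp <- switching_params(0.3, 6, 12)
  conf <- rbind(c(0, 0, 0), c(0, 0, 1e-5), c(0, 0, 5), c(0, 0, 5 + 1e-5),
                c(0, 0, 0.25), c(0, 0, 10))
  pairs <- rbind(c(1, 2), c(3, 4))
  expect_equal(coordination(conf, pairs, sp), 2, tolerance = 1e-6)
  expect_lt(coordination(conf, rbind(c(1, 6)), sp), 1e-6)
  mixed <- rbind(c(1, 2), c(1, 5), c(1, 6), c(2, 5))
  d <- sqrt(rowSums((conf[mixed[, 1], ] - conf[mixed[, 2], ])^2))
  expect_equal(coordination(conf, mixed, sp),
               sum((1 - (d / 0.3)^6) / (1 - (d / 0.3)^12)),
               tolerance = 1e-12)
  expect_error(coordination(conf, matrix(0L, 0, 2), sp), "empty")
})

test_that("dihedral follows the IUPAC convention with a vector oracle", {
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0), c(1, -1, 0))
  expect_equal(dihedral(cis, 1:4), 0)
  trans <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0), c(-1, -1, 0))
  expect_equal(dihedral(trans, 1:4), 180)
  collinear <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(1, 0, 3))
  expect_error(dihedral(collinear, 1:4), "collinear")
  # tabulated geometry vs an independent vector-algebra computation
  set.seed(5)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- oracle_cross(b1, b2); n2 <- oracle_cross(b2, b3)
    ang <- atan2(sum(oracle_cross(n1, n2) * b2) / sqrt(sum(b2^2)),
                 sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    expect_equal(dihedral(p, 1:4), ang, tolerance = 1e-9)
  }
})

test_that("all CVs are invariant under rigid motions", {
  sys <- make_ss_system("GAACTC", "pna")
  topo <- sys$topology
  conf <- perturbed_conf(sys, sd = 0.1, seed = 9)
  pairs <- rbind(c(1, 9), c(2, 20))
  for (i in 1:5) {
    moved <- rigid_motion(conf, seed = i)
    expect_equal(ht_distance(moved, topo), ht_distance(conf, topo),
                 tolerance = 1e-9)
    expect_equal(stk(moved, topo), stk(conf, topo), tolerance = 1e-9)
    expect_equal(sstk(moved, topo), sstk(conf, topo), tolerance = 1e-9)
    expect_equal(coordination(moved, pairs), coordination(conf, pairs),
                 tolerance = 1e-9)
    expect_equal(dihedral(moved, c(1, 5, 9, 13)),
                 dihedral(conf, c(1, 5, 9, 13)), tolerance = 1e-7)
  }
})

test_that("pair stacking is symmetric and non-increasing in distance", {
  sys <- make_ss_system("GAACTC", "pna")
  topo <- sys$topology
  conf <- sys$coords0
  expect_equal(pair_stacking(conf, topo, 2, 5),
               pair_stacking(conf, topo, 5, 2), tolerance = 1e-14)
  # slide base 2 away along z at fixed parallel orientation
  vals <- vapply(seq(0, 1.5, by = 0.05), function(dz) {
    c2 <- conf
    c2[monomer_sites(topo, 2), 3] <- c2[monomer_sites(topo, 2), 3] + dz
    pair_stacking(c2, topo, 1, 2)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("cv_series covers the trivial contracts", {
  sys <- make_ss_system("GAAC", "pna")
  tr1 <- trajectory(array(sys$coords0, c(16, 3, 1)), dt = 2)
  s1 <- cv_series(tr1, sys$topology, cvs = character(0))
  expect_equal(names(s1), "time")
  expect_equal(nrow(s1), 1L)
  s2 <- cv_series(tr1, sys$topology)
  expect_equal(nrow(s2), 1L)
  tr3 <- trajectory(array(rep(sys$coords0, 3), c(16, 3, 3)), dt = 1)
  s3 <- cv_series(tr3, sys$topology, cvs = c("ht", "stk", "nstk"))
  expect_equal(s3$stk, rep(s3$stk[1], 3))
  expect_equal(s3$ht, rep(s3$ht[1], 3))
  expect_error(cv_series(tr3, sys$topology, cvs = c("ht", "ht")),
               "duplicate")
  expect_error(cv_series(tr3, sys$topology, cvs = "bogus"), "unknown")
})
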