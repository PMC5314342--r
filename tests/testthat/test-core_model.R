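test_that("Watson-Crick partner map is an involution with correct H-bond counts", {
  for (b in c("A", "C", "G", "T", "U")) {
    p <- wc_partner(b)
    back <- wc_partner(p)
    # T and U both pair A; A's canonical partner is written T
    expect_true(back == b || (b %in% c("T", "U") && back %in% c("T", "U")))
  }
  expect_equal(hbond_count(c("G", "C")), c(3L, 3L))
  expect_equal(hbond_count(c("A", "T", "U")), c(2L, 2L, 2L))
  expect_error(nucleobase_info("X"), "invalid base")
})

test_that("build_duplex pairs the printed hexamer sequences antiparallel", {
  dx <- hexamer_duplex()
  expect_equal(dx$n_pairs, 6L)
  # pair 1: PNA G (N-term) against the RNA base at the 3' end (C)
  expect_equal(dx$pair_map[1, ], c(pna = 1L, rna = 6L))
  expect_equal(dx$pair_labels,
               c("G:C", "A:U", "A:U", "C:G", "T:A", "C:G"))
  expect_equal(dx$strand_b$sequence, c("G", "A", "G", "U", "U", "C"))
  expect_true(all(dx$pair_hbonds %in% 2:3))
})

test_that("build_duplex validates lengths, complementarity and alphabet", {
  dx1 <- build_duplex("G", "C")
  expect_equal(dx1$pair_hbonds, 3L)
  expect_error(build_duplex("GA", "GA"), "non-complementary")
  expect_error(build_duplex("GAA", "GA"), "length mismatch")
  expect_error(build_duplex("GX", "AC"), "invalid base")
})

test_that("duplex with any valid sequence and its reverse complement builds", {
  set.seed(42)
  for (i in 1:25) {
    L <- sample(2:12, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    expect_no_error(build_duplex(s, revcomp(s, "rna")))
  }
})

test_that("half H-bond totals match the hexamer bookkeeping (7 + 8)", {
  dx <- hexamer_duplex()
  expect_identical(half_hbond_total(dx, "first"), 7L)
  expect_identical(half_hbond_total(dx, "second"), 8L)
  expect_identical(half_hbond_total(build_duplex("GC", "GC"), "first"), 3L)
  expect_error(half_hbond_total(build_duplex("GAC", "GUC"), "first"),
               "even-length")
})

test_that("half totals always sum to the total over all pairs", {
  set.seed(7)
  for (i in 1:20) {
    L <- 2 * sample(1:6, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    dx <- build_duplex(s, revcomp(s, "rna"))
    expect_identical(half_hbond_total(dx, "first") +
                       half_hbond_total(dx, "second"),
                     sum(dx$pair_hbonds))
  }
})

test_that("counterion count neutralizes the RNA backbone charge", {
  expect_identical(counterion_count(hexamer_duplex()), 5L)
  expect_identical(counterion_count(strand_topology("GAACTC", "pna")), 0L)
  expect_identical(counterion_count(strand_topology("GAACUCGGAACU", "rna")),
                   11L)
})

test_that("strand topology bookkeeping is contiguous with 4 sites per monomer", {
  st <- strand_topology("GAGTTC", "rna")
  expect_equal(st$sequence, c("G", "A", "G", "U", "U", "C"))  # T -> U
  expect_equal(st$n_sites, 24L)
  all_sites <- sort(unlist(lapply(1:6, function(i) monomer_sites(st, i))))
  expect_equal(all_sites, 1:24)
  expect_equal(st$formal_charge, c(0L, rep(-1L, 5L)))
})

test_that("conformation and trajectory constructors validate their input", {
  expect_error(conformation(matrix(c(1, NA, 3), 1, 3)), "non-finite")
  expect_error(conformation(matrix(1, 2, 2)), "n x 3")
  cf <- conformation(matrix(0, 4, 3), box = c(5, 5, 5))
  expect_equal(attr(cf, "box"), c(5, 5, 5))
  expect_error(trajectory(array(0, c(4, 3, 2)), dt = 0), "dt > 0")
  tr <- trajectory(array(0, c(4, 3, 3)), dt = 0.5, temperature = 300,
                   seed = 1L)
  expect_equal(n_frames(tr), 3L)
  expect_equal(frame_times(tr), c(0.5, 1, 1.5))
})
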