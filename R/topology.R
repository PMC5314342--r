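## Strand and duplex topologies.
##
## Coarse-grained site layout: 4 sites per monomer, laid out contiguously —
## site 1 is the backbone bead, sites 2:4 are the base-plane triplet (three
## beads spanning the aromatic plane).  The base center is the centroid of
## the triplet.  Indices are 1-based in R; the C++ engine converts.

#' Build a single-strand topology
#'
#' @param seq Base string (e.g. `"GAACTC"`), read N-terminus to C-terminus
#'   for PNA and 5' to 3' for RNA.
#' @param kind One of `"pna"`, `"gamma_pna"`, `"rna"`.  For `"rna"` any T
#'   in the input is normalized to U; for the PNA kinds U is normalized to
#'   T.  `"gamma_pna"` shares the PNA alphabet and differs only by the
#'   backbone torsional bias applied when a simulation system is built.
#' @return An object of class `"strand_topology"`: a list with the
#'   sequence, termini labels, per-monomer site bookkeeping
#'   (`backbone_site`, `plane_sites` L x 3 matrix, `base_center_sites`),
#'   per-monomer formal charges and `n_sites`.
#' @export
#' @examples
#' st <- strand_topology("GAACTC", "pna")
#' st$n_sites       # 24
#' strand_topology("GAGTTC", "rna")$sequence  # T normalized to U
strand_topology <- function(seq, kind = c("pna", "gamma_pna", "rna")) {
  kind <- match.arg(kind)
  s <- .split_seq(seq)
  bad <- setdiff(s, .base_alphabet)
  if (length(bad) > 0L)
    stop("invalid base code(s): ", paste(unique(bad), collapse = ", "))
  if (kind == "rna") s[s == "T"] <- "U" else s[s == "U"] <- "T"
  L <- length(s)
  if (L < 1L) stop("empty sequence")
  base0 <- 4L * (seq_len(L) - 1L)
  charges <- if (kind == "rna") c(0L, rep(-1L, L - 1L)) else rep(0L, L)
  out <- list(
    kind = kind,
    sequence = s,
    termini = if (kind == "rna") c("5'", "3'") else c("N-term", "C-term"),
    backbone_site = base0 + 1L,
    plane_sites = cbind(base0 + 2L, base0 + 3L, base0 + 4L),
    base_center_sites = cbind(base0 + 2L, base0 + 3L, base0 + 4L),
    formal_charge = charges,
    n_monomers = L,
    n_sites = 4L * L
  )
  class(out) <- "strand_topology"
  out
}

#' @export
print.strand_topology <- function(x, ...) {
  cat(sprintf("strand_topology: %s %s-%s-%s, %d monomers, %d sites\n",
              x$kind, x$termini[1], paste(x$sequence, collapse = ""),
              x$termini[2], x$n_monomers, x$n_sites))
  invisible(x)
}

#' Sites belonging to one monomer
#' @param topo A `strand_topology` or `duplex_topology`.
#' @param i Monomer index (1-based; for a duplex, counted over PNA then
#'   RNA monomers).
#' @return Integer vector of site indices (backbone bead first).
#' @export
monomer_sites <- function(topo, i) {
  if (inherits(topo, "duplex_topology")) {
    La <- topo$strand_a$n_monomers
    if (i <= La) return(monomer_sites(topo$strand_a, i))
    return(topo$strand_a$n_sites + monomer_sites(topo$strand_b, i - La))
  }
  stopifnot(i >= 1L, i <= topo$n_monomers)
  c(topo$backbone_site[i], topo$plane_sites[i, ])
}

#' Build an antiparallel PNA:RNA duplex topology
#'
#' Pairs the PNA strand (read N-terminus to C-terminus) against the RNA
#' strand (given 5' to 3') in antiparallel orientation: PNA position i
#' from the N-terminus pairs RNA position i counted from the 3' end.
#' Every pair must be Watson-Crick complementary (T and U are equivalent
#' partners of A).
#'
#' @param pna_seq PNA base string, N- to C-terminus.
#' @param rna_seq RNA base string, 5' to 3' (T accepted and normalized
#'   to U).
#' @return An object of class `"duplex_topology"`: strand topologies
#'   `strand_a` (PNA) and `strand_b` (RNA), a `pair_map` (L x 2 matrix of
#'   1-based positions, column 1 PNA from N-term, column 2 RNA position in
#'   5'->3' numbering), per-pair `pair_hbonds` and `pair_labels`
#'   (`"PNAbase:RNAbase"`), and site bookkeeping with the RNA sites
#'   offset after the PNA sites.
#' @export
#' @examples
#' dx <- build_duplex("GAACTC", "GAGTTC")
#' dx$pair_labels       # "G:C" "A:U" ...
#' sum(dx$pair_hbonds)  # 15
build_duplex <- function(pna_seq, rna_seq) {
  a <- strand_topology(pna_seq, "pna")
  b <- strand_topology(rna_seq, "rna")
  L <- a$n_monomers
  if (b$n_monomers != L)
    stop(sprintf("length mismatch: PNA has %d bases, RNA has %d",
                 L, b$n_monomers))
  ## antiparallel: PNA i (from N-term) pairs RNA position L-i+1 (5'->3')
  pair_map <- cbind(pna = seq_len(L), rna = rev(seq_len(L)))
  pa <- a$sequence[pair_map[, 1]]
  pb <- b$sequence[pair_map[, 2]]
  ok <- .is_wc_pair(pa, pb)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop(sprintf(
      "non-complementary pair at position %d (0-based %d): PNA %s vs RNA %s",
      i, i - 1L, pa[i], pb[i]))
  }
  out <- list(
    strand_a = a, strand_b = b,
    pair_map = pair_map,
    pair_hbonds = hbond_count(pa),
    pair_labels = paste0(pa, ":", pb),
    n_pairs = L,
    n_sites = a$n_sites + b$n_sites
  )
  class(out) <- "duplex_topology"
  out
}

#' @export
print.duplex_topology <- function(x, ...) {
  cat(sprintf("duplex_topology: PNA N-%s-C : RNA 3'-%s-5', %d pairs (%s)\n",
              paste(x$strand_a$sequence, collapse = ""),
              paste(rev(x$strand_b$sequence), collapse = ""),
              x$n_pairs, paste(x$pair_labels, collapse = " ")))
  invisible(x)
}

#' Total Watson-Crick hydrogen bonds in one half of a duplex
#'
#' Splits an even-length duplex at its midpoint, counting pairs from the
#' PNA N-terminus, and sums the canonical H-bond multiplicities (3 for
#' G:C, 2 for A:T/U) over the requested half.  For the GAACTC:RNA hexamer
#' the halves carry 7 and 8 H-bonds.
#'
#' @param duplex A `duplex_topology`.
#' @param half `"first"` (N-terminal half) or `"second"` (C-terminal).
#' @return Integer H-bond total.
#' @export
#' @examples
#' dx <- build_duplex("GAACTC", "GAGTTC")
#' half_hbond_total(dx, "first")   # 7
#' half_hbond_total(dx, "second")  # 8
half_hbond_total <- function(duplex, half = c("first", "second")) {
  stopifnot(inherits(duplex, "duplex_topology"))
  half <- match.arg(half)
  L <- duplex$n_pairs
  if (L %% 2L != 0L)
    stop("half_hbond_total requires an even-length duplex")
  idx <- if (half == "first") seq_len(L %/% 2L) else (L %/% 2L + 1L):L
  sum(duplex$pair_hbonds[idx])
}

#' Monovalent counterions needed to neutralize a system
#'
#' PNA backbones are uncharged; an RNA strand of length n carries n-1
#' phosphodiester charges.  The count equals minus the summed formal
#' charge, matching the five sodium ions of the hexamer PNA:RNA duplex.
#'
#' @param x A `strand_topology` or `duplex_topology`.
#' @return Integer count of monovalent cations.
#' @export
#' @examples
#' counterion_count(build_duplex("GAACTC", "GAGTTC"))  # 5
#' counterion_count(strand_topology("GAACTC", "pna"))  # 0
counterion_count <- function(x) {
  q <- if (inherits(x, "duplex_topology"))
    sum(x$strand_a$formal_charge) + sum(x$strand_b$formal_charge)
  else sum(x$formal_charge)
  as.integer(-q)
}

#' Construct a conformation
#'
#' @param coords Numeric n_sites x 3 matrix of coordinates in nm.
#' @param box Optional orthorhombic box lengths (nm, length 3).
#' @return The coordinate matrix with class `"conformation"` and optional
#'   `box` attribute.  All coordinates must be finite.
#' @export
conformation <- function(coords, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(box)) {
    stopifnot(length(box) == 3L, all(box > 0))
    attr(coords, "box") <- as.numeric(box)
  }
  class(coords) <- c("conformation", class(coords))
  coords
}

#' Construct a trajectory
#'
#' @param frames 3-D numeric array, `n_sites x 3 x n_frames` (nm), or a
#'   list of conformations with a common site count.
#' @param dt Time between stored frames, ps (> 0).
#' @param temperature Temperature label, K.
#' @param seed Integer seed that produced the trajectory (provenance).
#' @return An object of class `"cg_trajectory"`.
#' @export
trajectory <- function(frames, dt, temperature = NA_real_, seed = NA_integer_) {
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1L]]), 3L, length(frames)))
  stopifnot(length(dim(frames)) == 3L, dim(frames)[2L] == 3L,
            dim(frames)[3L] >= 1L, dt > 0)
  structure(list(frames = frames, dt = dt, temperature = temperature,
                 seed = seed),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames x %d sites, dt = %g ps, T = %s K\n",
              dim(x$frames)[3L], dim(x$frames)[1L], x$dt,
              format(x$temperature)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3L]

#' Extract one frame of a trajectory
#' @param traj A `cg_trajectory`.
#' @param i Frame index (1-based).
#' @return An `n_sites x 3` coordinate matrix (nm).
#' @export
frame_coords <- function(traj, i) traj$frames[, , i]

#' Times of the stored frames
#' @param traj A `cg_trajectory`.
#' @return Numeric vector of frame times in ps (first frame at `dt`).
#' @export
frame_times <- function(traj) seq_len(n_frames(traj)) * traj$dt
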