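## Collective variables: head-to-tail distance, base stacking and its
## sequential / non-sequential decomposition, coordination, dihedrals.

#' Rational switching function parameters
#'
#' The switch is `f(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with even
#' `m > n`; it is 1 at r = 0, strictly decreasing, `n/m` at r = r0
#' (continuity limit) and 0 at infinity.
#'
#' @param r0 Reference distance, nm (> 0).
#' @param n,m Even integer exponents, `m > n > 0`.
#' @return An object of class `"switching_params"`.
#' @export
#' @examples
#' sp <- switching_params(0.4, 6, 12)
#' switch_value(0.4, sp)  # exactly n/m = 0.5
switching_params <- function(r0 = 0.4, n = 6L, m = 12L) {
  stopifnot(r0 > 0, n > 0, m > n, n %% 2 == 0, m %% 2 == 0)
  structure(list(r0 = r0, n = as.integer(n), m = as.integer(m)),
            class = "switching_params")
}

#' Evaluate the rational switching function
#'
#' @param r Numeric vector of distances (nm), non-negative.
#' @param sp A [switching_params()] object.
#' @param deriv If `TRUE`, return `df/dr` instead of `f`.
#' @return Numeric vector, same length as `r`.
#' @export
switch_value <- function(r, sp, deriv = FALSE) {
  x <- r / sp$r0
  n <- sp$n; m <- sp$m
  out <- numeric(length(x))
  near <- abs(x - 1) < 1e-6
  if (any(near)) {
    u <- x[near] - 1
    out[near] <- if (deriv) n * (n - m) / (2 * m) / sp$r0
                 else n / m + n * (n - m) / (2 * m) * u
  }
  if (any(!near)) {
    xf <- x[!near]
    xn <- xf^n; xm <- xf^m
    out[!near] <- if (deriv)
      (-n * xf^(n - 1) * (1 - xm) + m * xf^(m - 1) * (1 - xn)) /
        (1 - xm)^2 / sp$r0
    else (1 - xn) / (1 - xm)
  }
  out
}

.com <- function(coords, idx, w = NULL) {
  m <- coords[idx, , drop = FALSE]
  if (is.null(w)) colMeans(m) else colSums(m * w) / sum(w)
}

#' Head-to-tail distance of a strand
#'
#' Euclidean distance between the centers of mass of the first and last
#' monomers' sites (equal site masses).  Distinguishes folded from
#' extended single-strand conformations.
#'
#' @param conf `n_sites x 3` coordinate matrix (nm).
#' @param topo A `strand_topology`.
#' @return Distance in nm.
#' @export
ht_distance <- function(conf, topo) {
  if (topo$n_monomers < 2L) stop("head-to-tail needs >= 2 monomers")
  a <- .com(conf, monomer_sites(topo, 1L))
  b <- .com(conf, monomer_sites(topo, topo$n_monomers))
  sqrt(sum((a - b)^2))
}

.plane_geometry <- function(conf, topo, i) {
  p <- conf[topo$plane_sites[i, ], , drop = FALSE]
  centroid <- colMeans(p)
  w <- .cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  nw <- sqrt(sum(w^2))
  if (nw < 1e-10) stop(sprintf("degenerate (collinear) base-plane triplet for base %d", i))
  list(centroid = centroid, normal = w / nw)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Stacking score of one base pair
#'
#' `s_ij = f(d_ij) * cos^2(theta_ij)` with `d_ij` the distance between the
#' base-plane centroids, `theta_ij` the angle between the plane unit
#' normals (from the plane triplets) and `f` the rational switch.  The
#' squared cosine makes the score face-agnostic and differentiable; the
#' score is in [0, 1] and symmetric in (i, j).
#'
#' @param conf Coordinate matrix (nm).
#' @param topo A `strand_topology` (or `duplex_topology`, with bases
#'   numbered over PNA then RNA monomers).
#' @param i,j Base indices, `i != j`.
#' @param sp Switching parameters; default `r0 = 0.4` nm, `n = 6`,
#'   `m = 12`.
#' @return Dimensionless score in [0, 1].
#' @export
pair_stacking <- function(conf, topo, i, j, sp = switching_params(0.4, 6, 12)) {
  if (i == j) stop("i and j must differ")
  if (inherits(topo, "duplex_topology")) topo <- .flatten_duplex_bases(topo)
  gi <- .plane_geometry(conf, topo, i)
  gj <- .plane_geometry(conf, topo, j)
  d <- sqrt(sum((gi$centroid - gj$centroid)^2))
  ct <- sum(gi$normal * gj$normal)
  switch_value(d, sp) * ct^2
}

## view a duplex as one strand-like base list for stacking bookkeeping
.flatten_duplex_bases <- function(dx) {
  list(n_monomers = dx$strand_a$n_monomers + dx$strand_b$n_monomers,
       plane_sites = rbind(dx$strand_a$plane_sites,
                           dx$strand_a$n_sites + dx$strand_b$plane_sites))
}

#' Total, sequential and non-sequential stacking
#'
#' `stk` sums the pair stacking score over all unordered base pairs of the
#' strand (sequential pairs included); `sstk` restricts the sum to
#' sequential pairs (j = i + 1); `nstk = stk - sstk`.
#'
#' @inheritParams pair_stacking
#' @return A single numeric value.
#' @export
#' @examples
#' sys <- make_ss_system("GAACTC", "pna")
#' stk(sys$coords0, sys$topology)
stk <- function(conf, topo, sp = switching_params(0.4, 6, 12)) {
  L <- if (inherits(topo, "duplex_topology"))
    .flatten_duplex_bases(topo)$n_monomers else topo$n_monomers
  if (L < 2L) stop("stacking needs >= 2 bases")
  tot <- 0
  for (i in seq_len(L - 1L))
    for (j in (i + 1L):L)
      tot <- tot + pair_stacking(conf, topo, i, j, sp)
  tot
}

#' @rdname stk
#' @export
sstk <- function(conf, topo, sp = switching_params(0.4, 6, 12)) {
  L <- if (inherits(topo, "duplex_topology"))
    .flatten_duplex_bases(topo)$n_monomers else topo$n_monomers
  if (L < 2L) stop("stacking needs >= 2 bases")
  tot <- 0
  for (i in seq_len(L - 1L))
    tot <- tot + pair_stacking(conf, topo, i, i + 1L, sp)
  tot
}

#' @rdname stk
#' @export
nstk <- function(conf, topo, sp = switching_params(0.4, 6, 12)) {
  stk(conf, topo, sp) - sstk(conf, topo, sp)
}

#' Coordination number over a list of site pairs
#'
#' Smooth contact count: the rational switch of the inter-site distance,
#' summed over the given pairs.  Used as a differentiable hydrogen-bond
#' count between paired bases.
#'
#' @param conf Coordinate matrix (nm).
#' @param site_pairs Two-column integer matrix of 1-based site indices.
#' @param sp Switching parameters; default `r0 = 0.3` nm, `n = 6`,
#'   `m = 12`.
#' @return Dimensionless coordination value.
#' @export
coordination <- function(conf, site_pairs, sp = switching_params(0.3, 6, 12)) {
  site_pairs <- matrix(as.integer(site_pairs), ncol = 2L)
  if (nrow(site_pairs) == 0L) stop("empty site pair list")
  d <- sqrt(rowSums((conf[site_pairs[, 1L], , drop = FALSE] -
                     conf[site_pairs[, 2L], , drop = FALSE])^2))
  sum(switch_value(d, sp))
}

#' Signed dihedral angle of four sites
#'
#' IUPAC convention: 0 degrees for the planar cis (eclipsed) arrangement,
#' 180 for planar trans; result in (-180, 180].
#'
#' @param conf Coordinate matrix (nm).
#' @param idx Integer vector of four site indices.
#' @return Angle in degrees.
#' @export
dihedral <- function(conf, idx) {
  stopifnot(length(idx) == 4L)
  p <- conf[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("collinear degeneracy: three consecutive sites are collinear")
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ## trans is +/-180: map -180 to 180, and flip sign so that the IUPAC
  ## convention (cis = 0, clockwise positive viewed 2 -> 3) holds
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Collective-variable time series over a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param topo Topology matching the trajectory.
#' @param cvs Character vector naming CVs to evaluate; any of `"ht"`,
#'   `"stk"`, `"sstk"`, `"nstk"`.  May be empty (times only).
#' @param sp Switching parameters for the stacking CVs.
#' @return A data.frame of class `"cv_series"` with column `time` (ps)
#'   and one column per requested CV.
#' @export
cv_series <- function(traj, topo, cvs = c("ht", "stk", "sstk"),
                      sp = switching_params(0.4, 6, 12)) {
  known <- c("ht", "stk", "sstk", "nstk")
  if (anyDuplicated(cvs)) stop("duplicate CV names")
  bad <- setdiff(cvs, known)
  if (length(bad)) stop("unknown CV(s): ", paste(bad, collapse = ", "))
  nf <- n_frames(traj)
  out <- data.frame(time = frame_times(traj))
  fns <- list(ht = function(x) ht_distance(x, topo),
              stk = function(x) stk(x, topo, sp),
              sstk = function(x) sstk(x, topo, sp),
              nstk = function(x) nstk(x, topo, sp))
  for (cv in cvs)
    out[[cv]] <- vapply(seq_len(nf),
                        function(i) fns[[cv]](frame_coords(traj, i)),
                        numeric(1))
  class(out) <- c("cv_series", class(out))
  out
}
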