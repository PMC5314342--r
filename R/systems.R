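## Coarse-grained strand/duplex systems: geometry, force-field terms and
## the Langevin simulation wrapper.
##
## Geometry: each monomer is a 4-bead tetrahedron (backbone bead + base
## triplet).  Single strands start from a twisted ideal helix; duplexes use
## an untwisted "ladder" geometry (straight backbones, paired base planes
## facing across the duplex axis) so that the distortion scenarios are
## exact rigid motions of one strand.

#' Coarse-grained model parameters
#'
#' Energies kJ/mol, distances nm, times ps.  The stacking well reuses the
#' stacking-CV switching form (`r0 = 0.4` nm, n = 6, m = 12); the pairing
#' well uses a longer-tailed switch (`r0 = 0.35` nm, n = 4, m = 8) whose
#' reach lets separated strands feel each other at ~0.5-0.6 nm.  Pairing
#' strength per base pair is `eps_hb` times the Watson-Crick H-bond count
#' (3 for G:C, 2 for A:T/U).  `kappa_gamma = 0` reproduces the unmodified
#' backbone exactly; `kappa_gamma > 0` (gamma strands only) adds a
#' torsional bias toward the helical backbone dihedral and base register,
#' stiffens backbone bending and restrains the base-arm orientation —
#' a single-knob stand-in for the conformational restriction imposed by
#' the gamma-serine substituent.
#'
#' @param bond_k Bond stiffness (backbone and base-arm bonds),
#'   kJ/mol/nm^2.
#' @param tri_k Base-triangle bond stiffness, kJ/mol/nm^2 (stiffer than
#'   `bond_k` so the aromatic plane stays well-defined).
#' @param angle_k Backbone bending stiffness, kJ/mol (on cos theta).
#' @param eps_stack Stacking well depth per base pair, kJ/mol.
#' @param eps_hb Pairing well depth per hydrogen bond, kJ/mol.
#' @param ev_k,ev_r Excluded-volume stiffness (kJ/mol/nm^2) and radius
#'   (nm) between backbone beads.
#' @param ev_r_base Excluded-volume radius (nm) between base-plane sites
#'   of different bases within a strand (keeps stacked bases from
#'   interpenetrating; paired bases across strands are exempt so the
#'   pairing contact can form).
#' @param kappa_gamma Gamma pre-organization bias strength, kJ/mol
#'   (applied only to `gamma_pna` strands).
#' @param gamma_target Target backbone dihedral, degrees; `NA` means "use
#'   the ideal-helix dihedral" measured at build time.
#' @param friction Langevin friction, 1/ps.
#' @param dt Integration time step, ps.
#' @param stack_switch,hb_switch Switching parameters of the stacking and
#'   pairing wells.
#' @return A list of class `"cg_params"`.
#' @export
cg_params <- function(bond_k = 1000, tri_k = 3000, angle_k = 25,
                      eps_stack = 7,
                      eps_hb = 5, ev_k = 100, ev_r = 0.3,
                      ev_r_base = 0.2,
                      kappa_gamma = 100, gamma_target = NA,
                      friction = 5, dt = 0.002,
                      stack_switch = switching_params(0.4, 6, 12),
                      hb_switch = switching_params(0.35, 4, 8)) {
  stopifnot(bond_k >= 0, tri_k >= 0, angle_k >= 0, eps_stack >= 0,
            eps_hb >= 0, ev_k >= 0, ev_r > 0, ev_r_base > 0,
            kappa_gamma >= 0, friction >= 0, dt > 0)
  structure(list(bond_k = bond_k, tri_k = tri_k, angle_k = angle_k,
                 eps_stack = eps_stack,
                 eps_hb = eps_hb, ev_k = ev_k, ev_r = ev_r,
                 ev_r_base = ev_r_base,
                 kappa_gamma = kappa_gamma, gamma_target = gamma_target,
                 friction = friction, dt = dt,
                 stack_switch = stack_switch, hb_switch = hb_switch),
            class = "cg_params")
}

## fixed helix geometry constants (nm / degrees)
.helix <- list(rise = 0.32, twist = 30, r_bb = 0.55, r_base = 0.07,
               r_tri = 0.12)

## coordinates of one strand: twist in degrees (0 = ladder), side = +1/-1
## (which side of the duplex axis the backbone sits on), L monomers
.strand_coords <- function(L, twist = .helix$twist, side = 1) {
  h <- .helix
  coords <- matrix(0, 4 * L, 3)
  for (i in seq_len(L)) {
    th <- (twist * (i - 1)) * pi / 180
    if (side < 0) th <- th + pi
    z <- h$rise * (i - 1)
    dir <- c(cos(th), sin(th), 0)
    bb <- c(h$r_bb * dir[1:2], z)
    cen <- c(h$r_base * dir[1:2], z)
    base0 <- 4L * (i - 1L)
    coords[base0 + 1L, ] <- bb
    ## base triangle in the xy-plane around the centroid (normal = z axis)
    for (k in 1:3) {
      al <- th + (90 + 120 * (k - 1)) * pi / 180
      coords[base0 + 1L + k, ] <- cen + h$r_tri * c(cos(al), sin(al), 0)
    }
  }
  coords
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

## bonded terms measured from a reference conformation (so the reference
## geometry is the bonded-term minimum)
.bonded_terms <- function(topo, coords, params, gamma_bias = FALSE) {
  L <- topo$n_monomers
  bonds <- list()
  add_bond <- function(i, j, k)
    bonds[[length(bonds) + 1L]] <<- c(i, j, .dist3(coords[i, ], coords[j, ]), k)
  for (i in seq_len(L)) {
    b <- topo$backbone_site[i]; p <- topo$plane_sites[i, ]
    add_bond(b, p[1], params$bond_k); add_bond(b, p[2], params$bond_k)
    add_bond(b, p[3], params$bond_k)
    add_bond(p[1], p[2], params$tri_k); add_bond(p[2], p[3], params$tri_k)
    add_bond(p[1], p[3], params$tri_k)
    if (i < L) add_bond(b, topo$backbone_site[i + 1], params$bond_k)
  }
  bonds <- do.call(rbind, bonds)
  cos_of <- function(a, j, b) {
    u <- coords[a, ] - coords[j, ]; v <- coords[b, ] - coords[j, ]
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  angles <- NULL
  if (L >= 3) {
    ## backbone bending; for gamma strands the stiffness grows with
    ## kappa_gamma (rigidification by the gamma substituent;
    ## kappa_gamma = 0 leaves the model unchanged)
    k_ang <- params$angle_k +
      if (gamma_bias) params$kappa_gamma / 2 else 0
    angles <- t(vapply(2:(L - 1), function(i) {
      a <- topo$backbone_site[i - 1]; j <- topo$backbone_site[i]
      b <- topo$backbone_site[i + 1]
      c(a, j, b, cos_of(a, j, b), k_ang)
    }, numeric(5)))
  }
  if (gamma_bias && params$kappa_gamma > 0 && L >= 2) {
    ## gamma pre-organization also restrains the base-arm orientation
    ## relative to the local backbone direction (the substituent hinders
    ## free swivel of the monomer about its backbone attachment)
    arm <- do.call(rbind, lapply(seq_len(L), function(i) {
      nb <- topo$backbone_site[if (i < L) i + 1L else i - 1L]
      j <- topo$backbone_site[i]
      t(vapply(topo$plane_sites[i, ], function(p)
        c(nb, j, p, cos_of(nb, j, p), params$kappa_gamma / 2),
        numeric(5)))
    }))
    angles <- rbind(angles, arm)
  }
  torsions <- NULL
  if (gamma_bias && params$kappa_gamma > 0 && L >= 4) {
    torsions <- t(vapply(seq_len(L - 3), function(i) {
      idx <- topo$backbone_site[i:(i + 3)]
      phi0 <- if (is.na(params$gamma_target))
        dihedral(coords, idx) * pi / 180 else params$gamma_target * pi / 180
      c(idx, phi0, params$kappa_gamma)
    }, numeric(6)))
  }
  if (gamma_bias && params$kappa_gamma > 0 && L >= 2) {
    ## base-register torsion: the rotation of consecutive bases about the
    ## backbone axis, biased toward its helical value — the degree of
    ## freedom the gamma substituent locks into register
    reg <- t(vapply(seq_len(L - 1), function(i) {
      idx <- c(topo$plane_sites[i, 1], topo$backbone_site[i],
               topo$backbone_site[i + 1], topo$plane_sites[i + 1, 1])
      c(idx, dihedral(coords, idx) * pi / 180, params$kappa_gamma)
    }, numeric(6)))
    torsions <- rbind(torsions, reg)
  }
  list(bonds = bonds, angles = angles, torsions = torsions)
}

.make_system <- function(topology, coords, params, strand_list,
                         hb_pairs = NULL, hb_w = NULL) {
  ## strand_list: list of per-strand info: list(topo_offset (sites),
  ## mono_offset, topo (strand_topology), gamma (logical))
  bonds <- NULL; angles <- NULL; torsions <- NULL
  plane_sites <- NULL; backbone <- NULL
  stack_pairs <- NULL; seq_pairs <- NULL
  n_mono_total <- 0L
  for (s in strand_list) {
    bt <- .bonded_terms(s$topo, coords[s$off + seq_len(s$topo$n_sites), ,
                                       drop = FALSE], params, s$gamma)
    shift <- function(m, cols) { if (!is.null(m)) m[, cols] <- m[, cols] + s$off; m }
    bonds <- rbind(bonds, shift(bt$bonds, 1:2))
    angles <- rbind(angles, shift(bt$angles, 1:3))
    torsions <- rbind(torsions, shift(bt$torsions, 1:4))
    plane_sites <- rbind(plane_sites, s$topo$plane_sites + s$off)
    backbone <- c(backbone, s$topo$backbone_site + s$off)
    L <- s$topo$n_monomers
    if (L >= 2) {
      prs <- t(utils::combn(L, 2)) + n_mono_total
      stack_pairs <- rbind(stack_pairs, prs)
      seq_pairs <- rbind(seq_pairs,
                         cbind(seq_len(L - 1), 2:L) + n_mono_total)
    }
    n_mono_total <- n_mono_total + L
  }
  ## excluded volume: backbone beads (skipping bonded neighbours) plus
  ## plane sites of different bases within a strand (paired bases across
  ## strands stay exempt so the pairing contact can form)
  nb <- length(backbone)
  ev <- t(utils::combn(nb, 2))
  mono_strand <- rep(seq_along(strand_list),
                     vapply(strand_list, function(s) s$topo$n_monomers, 0L))
  keep <- !(mono_strand[ev[, 1]] == mono_strand[ev[, 2]] &
              abs(ev[, 1] - ev[, 2]) == 1L)
  ev_pairs <- cbind(backbone[ev[keep, 1]], backbone[ev[keep, 2]])
  ev_rad <- rep(params$ev_r, nrow(ev_pairs))
  ## intra-strand base-base EV keeps stacked bases from interpenetrating;
  ## inter-strand bases interact only through the pairing wells
  if (!is.null(stack_pairs)) {
    for (r in seq_len(nrow(stack_pairs))) {
      pa <- plane_sites[stack_pairs[r, 1], ]
      pb <- plane_sites[stack_pairs[r, 2], ]
      ev_pairs <- rbind(ev_pairs,
                        cbind(rep(pa, each = 3), rep(pb, times = 3)))
      ev_rad <- c(ev_rad, rep(params$ev_r_base, 9L))
    }
  }

  first_topo <- strand_list[[1L]]$topo
  structure(list(
    topology = topology,
    params = params,
    coords0 = coords,
    n_sites = nrow(coords),
    bonds = bonds, angles = angles, torsions = torsions,
    plane_sites = plane_sites,
    stack_pairs = stack_pairs, seq_pairs = seq_pairs,
    hb_pairs = hb_pairs, hb_w = hb_w,
    ev_pairs = ev_pairs, ev_rad = ev_rad,
    head_sites = monomer_sites(first_topo, 1L) + strand_list[[1L]]$off,
    tail_sites = monomer_sites(first_topo, first_topo$n_monomers) +
      strand_list[[1L]]$off
  ), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d sites, %d bonds, %d stacking pairs, %d pairing terms\n",
              x$n_sites, nrow(x$bonds), NROW(x$stack_pairs),
              NROW(x$hb_pairs)))
  invisible(x)
}

#' Build a single-strand coarse-grained system
#'
#' The strand starts as an ideal twisted helix (the single-strand stand-in
#' for a duplex-derived conformation).  Each monomer contributes 4 sites.
#' For `kind = "gamma_pna"` a torsional bias of strength
#' `params$kappa_gamma` toward the helical backbone dihedral is added;
#' with `kappa_gamma = 0` the system is identical to the unmodified one.
#'
#' @param seq Base string.
#' @param kind `"pna"` or `"gamma_pna"`.
#' @param params A [cg_params()] object.
#' @return A `cg_system`.
#' @export
#' @examples
#' sys <- make_ss_system("GAACTC", "pna")
#' sys$n_sites  # 24
make_ss_system <- function(seq, kind = c("pna", "gamma_pna"),
                           params = cg_params()) {
  kind <- match.arg(kind)
  topo <- strand_topology(seq, kind)
  coords <- .strand_coords(topo$n_monomers)
  .make_system(topo, coords, params,
               list(list(off = 0L, topo = topo, gamma = kind == "gamma_pna")))
}

#' Build a duplex coarse-grained system
#'
#' Uses the untwisted ladder geometry: both backbones are straight and
#' parallel, paired base planes face each other across the duplex axis
#' with centroids 0.14 nm apart.  Inter-strand pairing wells act between
#' paired base centroids with strength `eps_hb` times the pair's H-bond
#' count, so the GAACTC hexamer carries 15 H-bond units (7 + 8 per half).
#'
#' @param duplex A `duplex_topology` from [build_duplex()].
#' @param params A [cg_params()] object.
#' @return A `cg_system` whose `hb_pairs` rows follow the duplex pair
#'   order (pair 1 at the PNA N-terminus).
#' @export
make_duplex_system <- function(duplex, params = cg_params()) {
  stopifnot(inherits(duplex, "duplex_topology"))
  a <- duplex$strand_a; b <- duplex$strand_b
  L <- duplex$n_pairs
  ca <- .strand_coords(L, twist = 0, side = +1)
  ## RNA strand: its monomer q sits at the rung of the pair it belongs to.
  ## pair p: PNA monomer p, RNA monomer L - p + 1 (5'->3' numbering), so
  ## RNA monomer q occupies rung L - q + 1.
  cb_rungs <- .strand_coords(L, twist = 0, side = -1)
  cb <- matrix(0, 4 * L, 3)
  for (q in seq_len(L)) {
    rung <- L - q + 1L
    cb[4 * (q - 1) + 1:4, ] <- cb_rungs[4 * (rung - 1) + 1:4, ]
  }
  coords <- rbind(ca, cb)
  ## pairing terms: base index of PNA monomer p is p; RNA monomer q is L+q
  hb_pairs <- cbind(duplex$pair_map[, 1], L + duplex$pair_map[, 2])
  .make_system(duplex, coords, params,
               list(list(off = 0L, topo = a, gamma = FALSE),
                    list(off = a$n_sites, topo = b, gamma = FALSE)),
               hb_pairs = hb_pairs, hb_w = duplex$pair_hbonds)
}

## 0-based topology list handed to the C++ engine
.topo_list <- function(sys) {
  p <- sys$params
  z <- function(m) if (is.null(m)) matrix(0, 0, 8) else m
  bonds <- sys$bonds; angles <- z(sys$angles); torsions <- z(sys$torsions)
  hb <- if (is.null(sys$hb_pairs)) matrix(0L, 0, 2) else sys$hb_pairs
  list(
    nsites = sys$n_sites,
    bond_i = as.integer(bonds[, 1] - 1), bond_j = as.integer(bonds[, 2] - 1),
    bond_r0 = as.numeric(bonds[, 3]),
    bond_k = as.numeric(bonds[, 4]),
    ang_i = as.integer(angles[, 1] - 1), ang_j = as.integer(angles[, 2] - 1),
    ang_l = as.integer(angles[, 3] - 1),
    ang_cos0 = as.numeric(angles[, 4]),
    ang_kf = as.numeric(angles[, 5]),
    tor_a = as.integer(torsions[, 1] - 1), tor_b = as.integer(torsions[, 2] - 1),
    tor_c = as.integer(torsions[, 3] - 1), tor_d = as.integer(torsions[, 4] - 1),
    tor_phi0 = as.numeric(torsions[, 5]), tor_k = as.numeric(torsions[, 6]),
    plane1 = as.integer(sys$plane_sites[, 1] - 1),
    plane2 = as.integer(sys$plane_sites[, 2] - 1),
    plane3 = as.integer(sys$plane_sites[, 3] - 1),
    stack_a = as.integer(sys$stack_pairs[, 1] - 1),
    stack_b = as.integer(sys$stack_pairs[, 2] - 1),
    seq_a = as.integer(sys$seq_pairs[, 1] - 1),
    seq_b = as.integer(sys$seq_pairs[, 2] - 1),
    hb_a = as.integer(hb[, 1] - 1), hb_b = as.integer(hb[, 2] - 1),
    hb_w = as.numeric(if (is.null(sys$hb_w)) numeric(0) else sys$hb_w),
    ev_i = as.integer(sys$ev_pairs[, 1] - 1),
    ev_j = as.integer(sys$ev_pairs[, 2] - 1),
    ev_rad = as.numeric(sys$ev_rad),
    head_sites = as.integer(sys$head_sites - 1),
    tail_sites = as.integer(sys$tail_sites - 1),
    eps_stack = p$eps_stack, eps_hb = p$eps_hb,
    ev_k = p$ev_k,
    sw_stack_r0 = p$stack_switch$r0, sw_stack_n = p$stack_switch$n,
    sw_stack_m = p$stack_switch$m,
    sw_hb_r0 = p$hb_switch$r0, sw_hb_n = p$hb_switch$n,
    sw_hb_m = p$hb_switch$m
  )
}

#' Potential energy and forces of a conformation
#'
#' @param sys A `cg_system`.
#' @param conf Coordinate matrix (defaults to the system's initial
#'   conformation).
#' @return List with `energy` (kJ/mol) and `forces` (n x 3, kJ/mol/nm).
#' @export
cg_energy <- function(sys, conf = sys$coords0) {
  cpp_cg_energy(as.matrix(conf), .topo_list(sys))
}

#' Energy-minimize a conformation by steepest descent
#'
#' @param sys A `cg_system`.
#' @param conf Starting coordinates.
#' @param steps Number of descent steps.
#' @param step_size Step length scale (nm^2 mol/kJ).
#' @param max_disp Per-coordinate displacement cap per step (nm).
#' @return Minimized coordinate matrix.
#' @export
minimize_energy <- function(sys, conf = sys$coords0, steps = 500,
                            step_size = 1e-4, max_disp = 0.01) {
  cpp_cg_minimize(as.matrix(conf), .topo_list(sys), as.integer(steps),
                  step_size, max_disp)
}

#' Self-avoiding random-coil conformation of a strand system
#'
#' Backbone beads follow a self-avoiding random walk (rejection on
#' overlap within the excluded-volume radius); each monomer's base
#' tetrahedron is attached with a random orientation.
#'
#' @param sys A single-strand `cg_system`.
#' @param seed Integer seed.
#' @return Coordinate matrix.
#' @export
random_coil <- function(sys, seed = 1) {
  topo <- sys$topology
  stopifnot(inherits(topo, "strand_topology"))
  set.seed(seed)
  L <- topo$n_monomers
  step <- sys$bonds[sys$bonds[, 1] %in% topo$backbone_site &
                      sys$bonds[, 2] %in% topo$backbone_site, 3][1]
  bb <- matrix(0, L, 3)
  for (i in 2:L) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- bb[i - 1, ] + step * u
      d <- if (i > 2) min(sqrt(rowSums((bb[1:(i - 2), , drop = FALSE] -
                                          matrix(cand, i - 2, 3, byrow = TRUE))^2)))
           else Inf
      if (d > sys$params$ev_r) { bb[i, ] <- cand; break }
    }
  }
  ref <- .strand_coords(L)
  coords <- matrix(0, 4 * L, 3)
  for (i in seq_len(L)) {
    idx <- 4 * (i - 1) + 1:4
    local <- sweep(ref[idx, , drop = FALSE], 2, ref[idx[1], ])
    ## random rotation (QR of a Gaussian matrix)
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    coords[idx, ] <- sweep(local %*% t(R), 2, bb[i, ], "+")
  }
  coords
}

#' Distorted duplex starting conformations
#'
#' The five re-annealing scenarios, built as rigid motions of the RNA
#' strand (1-4) or a rebuilt stretched geometry (5):
#' 1. fan-opened, keeping only the C-terminal-side pair near contact;
#' 2. fan-opened, keeping only the N-terminal-side pair;
#' 3. strands uniformly separated to an inter-strand base distance of
#'    0.5-0.6 nm with bases facing;
#' 4. strands crossed (X) at the central pair, termini separated;
#' 5. both strands fully stretched with randomly oriented bases,
#'    approached and energy-minimized.
#'
#' @param sys A duplex `cg_system`.
#' @param scenario Integer 1-5.
#' @param seed Integer seed (used by scenario 5).
#' @return Coordinate matrix.
#' @export
make_distorted_duplex <- function(sys, scenario, seed = 1) {
  stopifnot(inherits(sys$topology, "duplex_topology"))
  dx <- sys$topology
  L <- dx$n_pairs
  na <- dx$strand_a$n_sites
  coords <- sys$coords0
  bidx <- na + seq_len(dx$strand_b$n_sites)

  rot_about_x_axis <- function(coords, origin, angle) {
    ## rotate about the axis through `origin` parallel to the pairing
    ## direction (x)
    th <- angle * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    sweep(sweep(coords, 2, origin) %*% t(R), 2, origin, "+")
  }
  pair_centroid <- function(p) {
    ## midpoint of the two paired base centroids of pair p
    a <- colMeans(coords[dx$strand_a$plane_sites[dx$pair_map[p, 1], ], ])
    b <- colMeans(coords[na + dx$strand_b$plane_sites[dx$pair_map[p, 2], ], ])
    (a + b) / 2
  }

  if (scenario %in% 1:2) {
    hinge <- pair_centroid(if (scenario == 1) L else 1L)
    coords[bidx, ] <- rot_about_x_axis(coords[bidx, , drop = FALSE],
                                       hinge, 90)
  } else if (scenario == 3) {
    coords[bidx, 1] <- coords[bidx, 1] - 0.41  # 0.14 -> 0.55 nm, facing
  } else if (scenario == 4) {
    center <- (pair_centroid(ceiling(L / 2)) +
                 pair_centroid(ceiling(L / 2) + (L %% 2 == 0))) / 2
    coords[bidx, ] <- rot_about_x_axis(coords[bidx, , drop = FALSE],
                                       center, 105)
  } else if (scenario == 5) {
    set.seed(seed)
    ## both strands fully stretched with randomly oriented bases; the two
    ## strand axes are randomly oriented relative to each other
    ## (disordered mismatching), then approached and energy-minimized
    stretch <- function(topo, off, origin, axis) {
      step <- 0.45
      for (i in seq_len(topo$n_monomers)) {
        idx <- off + 4 * (i - 1) + 1:4
        local <- sweep(sys$coords0[idx, , drop = FALSE], 2,
                       sys$coords0[idx[1], ])
        qr_ <- qr(matrix(rnorm(9), 3, 3)); R <- qr.Q(qr_)
        if (det(R) < 0) R[, 1] <- -R[, 1]
        bbpos <- origin + step * (i - 1) * axis
        coords[idx, ] <<- sweep(local %*% t(R), 2, bbpos, "+")
      }
    }
    stretch(dx$strand_a, 0L, c(0, 0, 0), c(0, 0, 1))
    stretch(dx$strand_b, na, c(2.8, 0, 0.45 * (L - 1) + 0.22),
            c(0, 0, -1))
    coords <- cpp_cg_minimize(coords, .topo_list(sys), 200L, 1e-4, 0.005)
  } else stop("unknown scenario: ", scenario)
  coords
}

#' Run Langevin dynamics on a coarse-grained system
#'
#' BAOAB Langevin integration at unit site mass.  With `friction = 0` and
#' `temperature = 0` the integrator reduces to velocity Verlet
#' (deterministic, energy-conserving).  Runs are bitwise reproducible for
#' a fixed seed.
#'
#' @param sys A `cg_system`.
#' @param steps Number of integration steps.
#' @param temperature Thermostat temperature, K.
#' @param seed Integer seed.
#' @param conf Starting coordinates (default: the system's ideal start).
#' @param sample_stride Store every `sample_stride`-th step.
#' @param store_frames Keep coordinates (needed for trajectory analysis).
#' @param dt,friction Override the parameter defaults.
#' @return A list of class `"cg_run"`: `trajectory` (a `cg_trajectory`,
#'   if `store_frames`), `cvs` (data.frame: time, ht, stk, sstk, bias,
#'   epot, ekin), and `final` coordinates.
#' @export
run_md <- function(sys, steps, temperature = 300, seed = 1,
                   conf = sys$coords0, sample_stride = 100,
                   store_frames = TRUE, dt = sys$params$dt,
                   friction = sys$params$friction) {
  stopifnot(steps > 0)
  res <- cpp_run_cg(as.matrix(conf), .topo_list(sys), as.integer(steps),
                    dt, temperature, friction, as.integer(sample_stride),
                    as.integer(seed), NULL, store_frames)
  .wrap_cg_run(res, sys, dt * sample_stride, temperature, seed,
               store_frames)
}

.wrap_cg_run <- function(res, sys, frame_dt, temperature, seed,
                         store_frames, hills = NULL) {
  cvs <- data.frame(time = res$time, ht = res$ht, stk = res$stk,
                    sstk = res$sstk, bias = res$bias, epot = res$epot,
                    ekin = res$ekin)
  class(cvs) <- c("cv_series", class(cvs))
  out <- list(cvs = cvs, final = res$final,
              temperature = temperature, seed = seed)
  if (store_frames)
    out$trajectory <- trajectory(array(res$frames,
                                       dim = c(sys$n_sites, 3,
                                               length(res$time))),
                                 dt = frame_dt, temperature = temperature,
                                 seed = seed)
  if (!is.null(hills)) out$hills <- hills
  class(out) <- "cg_run"
  out
}

#' Analytic benchmark potentials
#'
#' Closed-form potentials used to validate the metadynamics engine
#' against quadrature oracles:
#' * `double_well_1d`: `U(x) = h ((x^2 - a^2)/a^2)^2 + c x` — symmetric
#'   double well of barrier `h` and minima near `±a`, tilted by `c`.
#' * `double_well_2d`: the same along x plus a harmonic channel
#'   `ky y^2 / 2`.
#' * `harmonic`: `U(x) = sum k_i x_i^2 / 2`.
#'
#' @param type Potential name (above).
#' @param h,a,c,ky,k Parameters (kJ/mol, nm); `k` is a vector for
#'   `harmonic`.
#' @param domain 2 x dim matrix of bounds (defaults chosen to confine the
#'   thermally relevant region).
#' @return An object of class `"analytic_potential"` with an `$energy`
#'   function accepting an `n x dim` matrix.
#' @export
#' @examples
#' pot <- analytic_potential("double_well_1d", h = 15, a = 0.5, c = 3)
#' pot$energy(cbind(c(-0.5, 0, 0.5)))
analytic_potential <- function(type = c("double_well_1d", "double_well_2d",
                                        "harmonic"),
                               h = 15, a = 0.5, c = 0, ky = 50, k = 100,
                               domain = NULL) {
  type <- match.arg(type)
  if (type == "double_well_1d") {
    dim <- 1L
    params <- list(h = h, a = a, c = c)
    energy <- function(x) {
      x <- as.matrix(x)
      h * ((x[, 1]^2 - a^2) / a^2)^2 + c * x[, 1]
    }
    if (is.null(domain)) domain <- cbind(c(-2 * a, 2 * a))
  } else if (type == "double_well_2d") {
    dim <- 2L
    params <- list(h = h, a = a, c = c, ky = ky)
    energy <- function(x) {
      x <- as.matrix(x)
      h * ((x[, 1]^2 - a^2) / a^2)^2 + c * x[, 1] + 0.5 * ky * x[, 2]^2
    }
    if (is.null(domain)) domain <- cbind(c(-2 * a, 2 * a), c(-1, 1))
  } else {
    k <- as.numeric(k)
    dim <- length(k)
    params <- list(k = k)
    energy <- function(x) {
      x <- as.matrix(x)
      rowSums(sweep(x^2, 2, k / 2, "*"))
    }
    if (is.null(domain)) domain <- rbind(-3 / sqrt(k), 3 / sqrt(k))
  }
  structure(list(type = type, dim = dim, params = params, energy = energy,
                 domain = domain),
            class = "analytic_potential")
}

#' Free-energy surface of an analytic potential by quadrature
#'
#' For each grid cell, `F = -kT log` of the Boltzmann integral of
#' `exp(-U/kT)` over the cell (midpoint rule on a fine sub-grid),
#' min-normalized to zero.  Serves as the independent oracle for the
#' metadynamics and reweighting estimators.
#'
#' @param pot An [analytic_potential()].
#' @param temperature Temperature, K.
#' @param edges List of bin-edge vectors, one per dimension (defaults to
#'   200 bins over the potential domain).
#' @param subdiv Sub-divisions per cell and dimension for the quadrature.
#' @return A `fes_grid` object (see [fes_from_hills()]).
#' @export
fes_by_quadrature <- function(pot, temperature = 300,
                              edges = NULL, subdiv = 10) {
  kT <- .kB * temperature
  if (is.null(edges))
    edges <- lapply(seq_len(pot$dim), function(d)
      seq(pot$domain[1, d], pot$domain[2, d], length.out = 201))
  stopifnot(length(edges) == pot$dim)
  fine <- lapply(edges, function(e) {
    ## subdiv midpoints inside every cell
    unlist(lapply(seq_len(length(e) - 1), function(i)
      seq(e[i], e[i + 1], length.out = 2 * subdiv + 1)[seq(2, 2 * subdiv, 2)]))
  })
  nb <- vapply(edges, function(e) length(e) - 1L, 0L)
  if (pot$dim == 1L) {
    w <- exp(-pot$energy(cbind(fine[[1]])) / kT)
    p <- rowsum(w, rep(seq_len(nb[1]), each = subdiv))[, 1]
    p <- p * diff(edges[[1]]) / subdiv
  } else {
    g <- expand.grid(x = fine[[1]], y = fine[[2]])
    w <- exp(-pot$energy(as.matrix(g)) / kT)
    ix <- rep(rep(seq_len(nb[1]), each = subdiv), times = nb[2] * subdiv)
    iy <- rep(seq_len(nb[2]), each = subdiv * nb[1] * subdiv)
    p <- matrix(rowsum(w, (iy - 1L) * nb[1] + ix)[, 1], nb[1], nb[2])
    area <- outer(diff(edges[[1]]), diff(edges[[2]])) / subdiv^2
    p <- p * area
  }
  F <- -kT * log(p)
  fes_grid(edges, F - min(F), units = "kJ/mol",
           cvs = paste0("cv", seq_len(pot$dim)))
}
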