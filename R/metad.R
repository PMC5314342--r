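## Well-tempered metadynamics: parameters, hills bookkeeping, FES
## reconstruction and reweighting.

#' Well-tempered metadynamics parameters
#'
#' Defaults follow the deposition protocol used throughout: initial hill
#' height 2.5 kJ/mol, hill widths 0.01 (nm for distance CVs,
#' dimensionless for stacking), one hill per ps, bias factor 30.
#'
#' @param W0 Initial hill height, kJ/mol.
#' @param sigma Hill widths, one per biased CV.
#' @param stride_ps Deposition period, ps.  Internally the deposition
#'   happens every `round(stride_ps / dt)` integration steps.
#' @param gamma Bias factor (> 1); hill heights decay as
#'   `W0 exp(-V / (kB (gamma - 1) T))`.
#' @param temperature Simulation temperature, K.
#' @return A list of class `"metad_params"`.
#' @export
metad_params <- function(W0 = 2.5, sigma = 0.01, stride_ps = 1,
                         gamma = 30, temperature = 300) {
  if (gamma <= 1) stop("bias factor gamma must exceed 1")
  stopifnot(W0 >= 0, all(sigma > 0), stride_ps > 0, temperature > 0)
  structure(list(W0 = W0, sigma = as.numeric(sigma), stride_ps = stride_ps,
                 gamma = gamma, temperature = temperature),
            class = "metad_params")
}

#' Hills container
#'
#' @param time Deposition times, ps.
#' @param centers Matrix (k x d) of hill centers in CV space.
#' @param heights Deposited (well-tempered) heights, kJ/mol.
#' @param sigma Per-CV widths (constant across hills).
#' @param gamma Bias factor.
#' @param cv_names Names of the biased CVs.
#' @return A data.frame of class `"hills"` with columns `time`, the CV
#'   centers, `sigma_<cv>`, `height` and `biasf`.
#' @export
hills <- function(time = numeric(0), centers = NULL, heights = numeric(0),
                  sigma, gamma, cv_names = NULL) {
  d <- length(sigma)
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  if (is.null(centers)) centers <- matrix(0, 0, d)
  centers <- matrix(centers, ncol = d)
  stopifnot(length(time) == nrow(centers), length(heights) == length(time),
            all(heights >= 0))
  k <- length(time)
  df <- data.frame(time = as.numeric(time))
  for (j in seq_len(d)) df[[cv_names[j]]] <- centers[, j]
  for (j in seq_len(d)) df[[paste0("sigma_", cv_names[j])]] <- rep(sigma[j], k)
  df$height <- as.numeric(heights)
  df$biasf <- rep(gamma, k)
  structure(df, class = c("hills", "data.frame"),
            cv_names = cv_names, sigma = as.numeric(sigma), gamma = gamma)
}

.hills_centers <- function(h) as.matrix(h[, attr(h, "cv_names"), drop = FALSE])

#' Metadynamics bias potential from a hills list
#'
#' `V(s) = sum_k W_k exp(-sum_d (s_d - c_kd)^2 / (2 sigma_d^2))`.
#'
#' @param h A `hills` object (possibly empty).
#' @param s Numeric vector (one point) or matrix (points in rows) in CV
#'   space.
#' @return Bias value(s), kJ/mol (0 for empty hills).
#' @export
bias_value <- function(h, s) {
  s <- matrix(s, ncol = length(attr(h, "sigma")))
  if (nrow(h) == 0L) return(numeric(nrow(s)))
  cen <- .hills_centers(h)
  sg <- attr(h, "sigma")
  vapply(seq_len(nrow(s)), function(i) {
    e <- sweep(cen, 2, s[i, ])
    sum(h$height * exp(-rowSums(sweep(e^2, 2, 2 * sg^2, "/"))))
  }, numeric(1))
}

#' @rdname bias_value
#' @return `bias_gradient`: matrix of dV/ds (points in rows).
#' @export
bias_gradient <- function(h, s) {
  sg <- attr(h, "sigma")
  s <- matrix(s, ncol = length(sg))
  g <- matrix(0, nrow(s), ncol(s))
  if (nrow(h) == 0L) return(g)
  cen <- .hills_centers(h)
  for (i in seq_len(nrow(s))) {
    e <- sweep(cen, 2, s[i, ])    # c_k - s
    w <- h$height * exp(-rowSums(sweep(e^2, 2, 2 * sg^2, "/")))
    g[i, ] <- colSums(w * sweep(e, 2, sg^2, "/"))
  }
  g
}

#' Deposit a well-tempered hill
#'
#' Appends a hill at `s` with height `W0 exp(-V(s) / (kB (gamma-1) T))`;
#' at an unbiased point the height equals `W0`, and repeated deposits at
#' an already-biased point shrink geometrically (standard metadynamics is
#' the `gamma -> Inf` limit).
#'
#' @param h A `hills` object.
#' @param s CV-space position of the new hill.
#' @param params A [metad_params()] object.
#' @param time Deposition time, ps.
#' @return The extended `hills` object.
#' @export
deposit_hill <- function(h, s, params, time = NA_real_) {
  if (params$gamma <= 1) stop("bias factor gamma must exceed 1")
  dT <- (params$gamma - 1) * params$temperature
  W <- params$W0 * exp(-bias_value(h, s) / (.kB * dT))
  hills(c(h$time, time), rbind(.hills_centers(h), s), c(h$height, W),
        sigma = attr(h, "sigma"), gamma = params$gamma,
        cv_names = attr(h, "cv_names"))
}

#' Regular free-energy grid
#'
#' @param edges List of bin-edge vectors, one per CV.
#' @param F Free energies at the cell centers (vector or matrix,
#'   kJ/mol), min-normalized to 0.
#' @param units `"kJ/mol"` or `"kcal/mol"`.
#' @param cvs CV names.
#' @return An object of class `"fes_grid"`.
#' @export
fes_grid <- function(edges, F, units = "kJ/mol", cvs = NULL) {
  if (is.null(cvs)) cvs <- paste0("cv", seq_along(edges))
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(edges = edges, mids = mids, F = F, units = units,
                 cvs = cvs), class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %s over %s; range [%.3g, %.3g] %s\n",
              paste(x$cvs, collapse = " x "),
              paste(vapply(x$mids, length, 0L), collapse = " x "),
              min(x$F[is.finite(x$F)]), max(x$F[is.finite(x$F)]), x$units))
  invisible(x)
}

#' Free-energy surface from the deposited hills
#'
#' Final-bias estimator: `F(s) = -(gamma/(gamma-1)) V(s, t_end)`,
#' min-normalized to zero.  An empty hills list yields a flat zero FES.
#'
#' @param h A `hills` object.
#' @param edges List of bin-edge vectors (per biased CV).
#' @param params A [metad_params()] object (for `gamma`).
#' @return A `fes_grid` in kJ/mol.
#' @export
fes_from_hills <- function(h, edges, params) {
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  dims <- vapply(mids, length, 0L)
  if (nrow(h) == 0L) {
    F <- if (length(dims) == 1L) numeric(dims) else matrix(0, dims[1], dims[2])
    return(fes_grid(edges, F, cvs = attr(h, "cv_names")))
  }
  V <- cpp_sum_hills_grid(.hills_centers(h), attr(h, "sigma"), h$height,
                          mids, 8.0)
  g <- params$gamma / (params$gamma - 1)
  F <- -g * V
  fes_grid(edges, F - min(F), cvs = attr(h, "cv_names"))
}

#' Convert FES units
#'
#' @param fes A `fes_grid`.
#' @param to `"kJ/mol"` or `"kcal/mol"` (factor 4.184 exactly).
#' @return The converted `fes_grid` (normalization preserved).
#' @export
convert_units <- function(fes, to = c("kJ/mol", "kcal/mol")) {
  to <- match.arg(to)
  if (identical(fes$units, to)) return(fes)
  fes$F <- if (to == "kcal/mol") fes$F / 4.184 else fes$F * 4.184
  fes$units <- to
  fes
}

## step-function interpolation of the reweighting offset c(t)
.ct_at <- function(ct, times) {
  idx <- findInterval(times, ct$time)
  vals <- c(ct$ct[1], ct$ct)   # before the first checkpoint use the first
  vals[idx + 1]
}

#' Reweight a biased trajectory onto arbitrary CVs
#'
#' Implements the time-dependent-offset frame-weight scheme: frame
#' weights `w_t` proportional to `exp((V(s_t, t) - c(t)) / kBT)` with
#' `c(t) = kBT log[ sum exp(-F_t/kBT) / sum exp(-(F_t + V_t)/kBT) ]`
#' computed from the running hills-based FES estimate on a grid over the
#' biased CVs.  The weighted histogram of the target CVs gives
#' `F = -kBT log(hist)`, min-normalized.
#'
#' @param cvs Data.frame with columns `time`, the target CV columns and
#'   `bias` (the instantaneous bias at each frame, kJ/mol).
#' @param h The `hills` object of the run.
#' @param targets Names of the CV columns to histogram (1 or 2).
#' @param edges List of bin-edge vectors for the targets.
#' @param params The run's [metad_params()].
#' @param bias_edges Optional grid over the biased CVs for the c(t)
#'   integrals (defaults to the span of the hill centers +/- 5 sigma at
#'   sigma/2 resolution).
#' @param ct_every Recompute c(t) every this many hills.
#' @param min_ess Warn if the effective sample size falls below this.
#' @return A `fes_grid` over the targets, with attributes `weights` and
#'   `ess`.
#' @export
reweight_fes <- function(cvs, h, targets, edges, params,
                         bias_edges = NULL, ct_every = 20, min_ess = 50) {
  stopifnot(all(targets %in% names(cvs)), "bias" %in% names(cvs),
            length(targets) %in% 1:2, length(edges) == length(targets))
  kT <- .kB * params$temperature
  if (nrow(h) > 0L) {
    sg <- attr(h, "sigma")
    cen <- .hills_centers(h)
    if (is.null(bias_edges))
      bias_edges <- lapply(seq_along(sg), function(d)
        seq(min(cen[, d]) - 5 * sg[d], max(cen[, d]) + 5 * sg[d],
            by = sg[d] / 2))
    axes <- lapply(bias_edges, function(e) (e[-1] + e[-length(e)]) / 2)
    ct <- cpp_ct_profile(h$time, cen, sg, h$height, axes,
                         params$gamma, kT, as.integer(ct_every), 8.0)
    logw <- (cvs$bias - .ct_at(ct, cvs$time)) / kT
  } else {
    logw <- rep(0, nrow(cvs))
  }
  w <- exp(logw - max(logw))
  ess <- sum(w)^2 / sum(w^2)
  if (ess < min_ess)
    warning(sprintf("degenerate reweighting: effective sample size %.1f", ess))
  ## weighted histogram over the targets
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  bin <- lapply(seq_along(targets), function(j) {
    b <- findInterval(cvs[[targets[j]]], edges[[j]], all.inside = FALSE)
    b[cvs[[targets[j]]] >= edges[[j]][length(edges[[j]])]] <- NA
    b[b == 0L] <- NA
    b
  })
  nb <- vapply(mids, length, 0L)
  if (length(targets) == 1L) {
    keep <- !is.na(bin[[1]])
    p <- vapply(seq_len(nb[1]), function(i)
      sum(w[keep][bin[[1]][keep] == i]), numeric(1))
  } else {
    keep <- !is.na(bin[[1]]) & !is.na(bin[[2]])
    code <- (bin[[2]][keep] - 1L) * nb[1] + bin[[1]][keep]
    tab <- rowsum(w[keep], code)
    p <- matrix(0, nb[1], nb[2])
    p[as.integer(rownames(tab))] <- tab[, 1]
  }
  F <- -kT * log(p / sum(p))
  out <- fes_grid(edges, F - min(F[is.finite(F)]), cvs = targets)
  attr(out, "weights") <- w / sum(w)
  attr(out, "ess") <- ess
  out
}

#' Boltzmann population of a region of a free-energy surface
#'
#' @param fes A `fes_grid`.
#' @param temperature Temperature, K.
#' @param region Function of the grid-center coordinates (one argument
#'   per CV) returning a logical mask; `NULL` selects everything.
#' @return Fraction of the Boltzmann mass (uniform cell volumes) inside
#'   the region.
#' @export
fes_region_mass <- function(fes, temperature = 300, region = NULL) {
  kT <- .kB * temperature
  w <- exp(-fes$F / kT)
  w[!is.finite(w)] <- 0
  if (is.null(region)) return(1)
  mask <- if (length(fes$mids) == 1L) outer(fes$mids[[1]], 1, function(a, b)
    region(a))[, 1] else outer(fes$mids[[1]], fes$mids[[2]], region)
  sum(w[mask]) / sum(w)
}

#' Free-energy difference between two basins of a 1-D FES
#'
#' `deltaF = -kT log(P_left / P_right)` with basin populations integrated
#' on either side of `split`.
#'
#' @param fes A one-dimensional `fes_grid`.
#' @param temperature Temperature, K.
#' @param split CV value separating the basins.
#' @return Free-energy difference (left minus right), kJ/mol.
#' @export
fes_basin_delta <- function(fes, temperature = 300, split = 0) {
  stopifnot(length(fes$mids) == 1L)
  kT <- .kB * temperature
  w <- exp(-fes$F / kT)
  w[!is.finite(w)] <- 0
  left <- sum(w[fes$mids[[1]] < split])
  right <- sum(w[fes$mids[[1]] >= split])
  -kT * log(left / right)
}

#' Run well-tempered metadynamics
#'
#' Biased BAOAB Langevin dynamics with on-the-fly Gaussian hill
#' deposition.  For an [analytic_potential()] the biased CVs are the
#' first `bias_dim` coordinates; for a single-strand `cg_system` the CVs
#' are the head-to-tail distance (HT) and the total stacking function
#' (Stk), with the sequential stacking (SStk) logged alongside for
#' reweighting.
#'
#' @param x An `analytic_potential` or single-strand `cg_system`.
#' @param params A [metad_params()] object; `sigma` must have one entry
#'   per biased CV.
#' @param steps Integration steps.
#' @param seed Integer seed (runs are reproducible per seed).
#' @param ... Method-specific arguments.
#' @return A list of class `"metad_run"` with elements `cvs` (per-frame
#'   data.frame including the instantaneous bias), `hills` and `params`.
#' @export
run_wtmetad <- function(x, params, steps, seed = 1, ...)
  UseMethod("run_wtmetad")

## shared: assemble the C++ bias-grid description
.metad_list <- function(params, lo, hi, dt, grid_spacing = NULL,
                        cutoff = 6) {
  d <- length(params$sigma)
  stopifnot(length(lo) == d, length(hi) == d)
  if (is.null(grid_spacing)) grid_spacing <- params$sigma / 4
  list(dim = as.integer(d), lo = as.numeric(lo), hi = as.numeric(hi),
       spacing = as.numeric(grid_spacing), sigma = params$sigma,
       W0 = params$W0, gamma = params$gamma,
       kT = .kB * params$temperature,
       stride_steps = max(1L, as.integer(round(params$stride_ps / dt))),
       cutoff = cutoff)
}

.wrap_hills <- function(hl, params, cv_names) {
  hills(hl$time, hl$centers, hl$heights, sigma = params$sigma,
        gamma = params$gamma, cv_names = cv_names)
}

#' @rdname run_wtmetad
#' @param dt,friction Integrator settings (analytic potentials).
#' @param x0 Starting point (defaults to the first minimum region).
#' @param sample_stride Store every n-th step.
#' @param bias_dim Number of leading coordinates to bias.
#' @export
run_wtmetad.analytic_potential <- function(x, params, steps, seed = 1,
                                           dt = 0.005, friction = 10,
                                           x0 = NULL, sample_stride = 20,
                                           bias_dim = 1, ...) {
  if (length(params$sigma) != bias_dim)
    stop("need one sigma per biased CV")
  if (is.null(x0))
    x0 <- if (x$type %in% c("double_well_1d", "double_well_2d"))
      c(-x$params$a, 0)[seq_len(x$dim)] else rep(0, x$dim)
  ml <- .metad_list(params, x$domain[1, seq_len(bias_dim)],
                    x$domain[2, seq_len(bias_dim)], dt)
  res <- cpp_run_particle(list(type = x$type, params = x$params),
                          as.numeric(x0), as.integer(steps), dt,
                          params$temperature, friction,
                          as.integer(sample_stride), as.integer(seed), ml)
  cvn <- paste0("x", seq_len(x$dim))
  cvs <- data.frame(time = res$time)
  for (d in seq_len(x$dim)) cvs[[cvn[d]]] <- res$x[, d]
  cvs$bias <- res$bias; cvs$epot <- res$epot; cvs$ekin <- res$ekin
  structure(list(cvs = cvs,
                 hills = .wrap_hills(res$hills, params, cvn[seq_len(bias_dim)]),
                 params = params, potential = x, seed = seed),
            class = "metad_run")
}

#' @rdname run_wtmetad
#' @param conf Starting conformation (cg systems).
#' @param cv_range List with `ht` and `stk` bias-grid ranges.
#' @param store_frames Keep trajectory frames.
#' @export
run_wtmetad.cg_system <- function(x, params, steps, seed = 1,
                                  conf = x$coords0, sample_stride = 100,
                                  cv_range = list(ht = c(0, 3),
                                                  stk = c(-0.5, 16)),
                                  store_frames = FALSE, ...) {
  if (length(params$sigma) != 2L)
    stop("cg metadynamics biases (HT, Stk): need sigma of length 2")
  dt <- x$params$dt
  ml <- .metad_list(params, c(cv_range$ht[1], cv_range$stk[1]),
                    c(cv_range$ht[2], cv_range$stk[2]), dt)
  res <- cpp_run_cg(as.matrix(conf), .topo_list(x), as.integer(steps), dt,
                    params$temperature, x$params$friction,
                    as.integer(sample_stride), as.integer(seed), ml,
                    store_frames)
  out <- .wrap_cg_run(res, x, dt * sample_stride, params$temperature, seed,
                      store_frames,
                      hills = .wrap_hills(res$hills, params, c("ht", "stk")))
  out$params <- params
  class(out) <- c("metad_run", class(out))
  out
}
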