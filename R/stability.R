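## Thermal melting and re-annealing analysis: per-base-pair H-bonding
## persistence, disruption detection, pre-break profiles and scenario
## classification.

#' Instantaneous per-pair coordination of a duplex conformation
#'
#' Rational-switch coordination (default `r0 = 0.45` nm, n = 6, m = 12,
#' matched to the contact-well width of the coarse model) of the
#' distance between the paired base centroids.
#'
#' @param conf Coordinate matrix.
#' @param sys A duplex `cg_system`.
#' @param sp Switching parameters of the coordination CV.
#' @return Numeric vector, one value per base pair (PNA N-terminus
#'   first).
#' @export
pairing_values <- function(conf, sys, sp = switching_params(0.45, 6, 12)) {
  hb <- sys$hb_pairs
  vapply(seq_len(nrow(hb)), function(p) {
    ca <- colMeans(conf[sys$plane_sites[hb[p, 1], ], , drop = FALSE])
    cb <- colMeans(conf[sys$plane_sites[hb[p, 2], ], , drop = FALSE])
    switch_value(sqrt(sum((ca - cb)^2)), sp)
  }, numeric(1))
}

#' Per-base-pair coordination time series
#'
#' One column per base pair, labeled `"PNAbase:RNAbase"`, evaluated on
#' every stored frame.  The per-pair reference (its coordination in the
#' fully formed ideal duplex) is stored as an attribute and used by all
#' persistence thresholds.
#'
#' @param x A `cg_run` (from [run_md()]) or `cg_trajectory`.
#' @param sys The duplex `cg_system` the trajectory belongs to.
#' @param sp Coordination switching parameters.
#' @return A data.frame of class `"pairing_series"`: column `time` plus
#'   one column per pair; attributes `reference` and `labels`.
#' @export
pairing_series <- function(x, sys, sp = switching_params(0.45, 6, 12)) {
  traj <- if (inherits(x, "cg_run")) x$trajectory else x
  stopifnot(inherits(traj, "cg_trajectory"),
            inherits(sys$topology, "duplex_topology"))
  nf <- n_frames(traj)
  hb <- sys$hb_pairs
  vals <- matrix(0, nf, nrow(hb))
  fr <- traj$frames
  for (p in seq_len(nrow(hb))) {
    pa <- sys$plane_sites[hb[p, 1], ]
    pb <- sys$plane_sites[hb[p, 2], ]
    d2 <- 0
    for (k in 1:3) {
      ca <- (fr[pa[1], k, ] + fr[pa[2], k, ] + fr[pa[3], k, ]) / 3
      cb <- (fr[pb[1], k, ] + fr[pb[2], k, ] + fr[pb[3], k, ]) / 3
      d2 <- d2 + (ca - cb)^2
    }
    vals[, p] <- switch_value(sqrt(d2), sp)
  }
  ref <- pairing_values(sys$coords0, sys, sp)
  out <- data.frame(time = frame_times(traj))
  labels <- sys$topology$pair_labels
  cols <- sprintf("pair%d.%s", seq_along(labels), labels)
  for (p in seq_along(labels)) out[[cols[p]]] <- vals[, p]
  structure(out, class = c("pairing_series", "data.frame"),
            reference = ref, labels = labels, columns = cols)
}

.series_matrix <- function(series)
  as.matrix(series[, attr(series, "columns"), drop = FALSE])

## logical frames x pairs matrix: pair persistently formed at each frame
## (coordination above theta_on * reference over the trailing m frames;
## early frames use the window available so far)
.persistent_matrix <- function(series, theta_on = 0.5, m_frames = 5) {
  vals <- .series_matrix(series)
  ref <- attr(series, "reference")
  ok <- sweep(vals, 2, theta_on * ref, ">")
  apply(ok, 2, function(col) {
    cs <- cumsum(col)
    n <- length(col)
    m <- pmin(seq_len(n), m_frames)
    (cs - c(rep(0, m_frames), head(cs, n - m_frames))[seq_len(n)]) == m
  })
}

#' Persistent base-pairing fraction at a time point
#'
#' Fraction of base pairs whose coordination has stayed above
#' `theta_on` times its fully-formed reference over the trailing
#' `m_frames` stored frames ("persistent", not instantaneous, pairing).
#'
#' @param series A [pairing_series()].
#' @param t Time (ps) within the series range.
#' @param theta_on Persistence threshold (fraction of reference).
#' @param m_frames Trailing window, frames.
#' @return Fraction in 0..1.
#' @export
pairing_fraction <- function(series, t, theta_on = 0.5, m_frames = 5) {
  if (t < series$time[1] || t > series$time[nrow(series)])
    stop("t outside the series time range")
  i <- max(which(series$time <= t))
  pm <- .persistent_matrix(series, theta_on, m_frames)
  mean(pm[i, ])
}

#' Detect complete duplex disruption
#'
#' Earliest time from which every pair stays below `theta_off` times its
#' reference for at least `persistence` consecutive frames; single-frame
#' dips do not count.
#'
#' @param series A [pairing_series()].
#' @param theta_off Disruption threshold (fraction of reference).
#' @param persistence Window length in frames.
#' @return Disruption time (ps), or `NA` if the duplex never breaks.
#' @export
detect_disruption <- function(series, theta_off = 0.2, persistence = 5) {
  vals <- .series_matrix(series)
  ref <- attr(series, "reference")
  below <- rowSums(sweep(vals, 2, theta_off * ref, ">=")) == 0
  n <- length(below)
  if (n < persistence) return(NA_real_)
  run <- stats::filter(as.numeric(below), rep(1, persistence),
                       sides = 1)
  idx <- which(run == persistence)
  if (length(idx) == 0L) return(NA_real_)
  series$time[idx[1] - persistence + 1L]
}

#' Per-pair H-bonding fraction before duplex disruption
#'
#' For each base pair, the time-averaged coordination over the window
#' ending just before the disruption time (frames in
#' `[t_disrupt - window, t_disrupt)`), normalized by the pair's
#' fully-formed reference and clipped to 0..1.  If the disruption occurs
#' earlier than one window, the window is shrunk with a warning.
#'
#' @param series A [pairing_series()].
#' @param window Averaging window, ps.
#' @param theta_off,persistence Passed to [detect_disruption()].
#' @param t_disrupt Optional disruption time override (ps).
#' @return Named numeric vector of per-pair fractions (pair labels).
#' @export
prebreak_profile <- function(series, window, theta_off = 0.2,
                             persistence = 5, t_disrupt = NULL) {
  if (is.null(t_disrupt))
    t_disrupt <- detect_disruption(series, theta_off, persistence)
  if (is.na(t_disrupt)) stop("no disruption detected")
  t0 <- t_disrupt - window
  if (t0 < series$time[1]) {
    warning("disruption earlier than the averaging window; shrinking")
    t0 <- series$time[1]
  }
  sel <- series$time >= t0 & series$time < t_disrupt
  if (!any(sel)) sel <- series$time <= t_disrupt
  vals <- .series_matrix(series)[sel, , drop = FALSE]
  prof <- colMeans(vals) / attr(series, "reference")
  setNames(pmin(pmax(prof, 0), 1), attr(series, "labels"))
}

#' Thermal melting scan of a duplex
#'
#' Runs Langevin dynamics at each (temperature, seed) combination from
#' the ideal duplex, detects complete disruption and collects the
#' pre-break per-pair H-bonding profiles.  The averaged profile is the
#' mean over runs with a detected disruption.
#'
#' @param sys A duplex `cg_system`.
#' @param temperatures Temperatures, K.
#' @param seeds Integer seeds.
#' @param steps Integration steps per run.
#' @param window Pre-break averaging window, ps.
#' @param sample_stride Frame storage stride (steps).
#' @param theta_off,persistence Disruption definition.
#' @return A list of class `"melt_scan"`: `results` (data.frame with
#'   temperature, seed, disruption_time), `profiles` (runs x pairs
#'   matrix, `NA` rows for undisrupted runs), `average_profile`, and
#'   `labels`.
#' @export
melt_scan <- function(sys, temperatures, seeds, steps = 200000,
                      window = 100, sample_stride = 100,
                      theta_off = 0.2, persistence = 5) {
  grid <- expand.grid(seed = seeds, temperature = temperatures)
  L <- sys$topology$n_pairs
  profiles <- matrix(NA_real_, nrow(grid), L)
  tdis <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    run <- run_md(sys, steps, temperature = grid$temperature[r],
                  seed = grid$seed[r], sample_stride = sample_stride)
    series <- pairing_series(run, sys)
    td <- detect_disruption(series, theta_off, persistence)
    tdis[r] <- td
    if (!is.na(td))
      profiles[r, ] <- suppressWarnings(
        prebreak_profile(series, window, theta_off, persistence,
                         t_disrupt = td))
  }
  disrupted <- !is.na(tdis)
  if (!any(disrupted))
    stop("no run reached complete disruption; use longer runs or higher temperatures")
  avg <- colMeans(profiles[disrupted, , drop = FALSE])
  structure(list(
    results = data.frame(temperature = grid$temperature, seed = grid$seed,
                         disruption_time = tdis),
    profiles = profiles,
    average_profile = setNames(avg, sys$topology$pair_labels),
    labels = sys$topology$pair_labels),
    class = "melt_scan")
}

#' Re-annealing run from a distorted duplex
#'
#' Builds the requested distortion scenario, runs Langevin dynamics at
#' `temperature` and classifies the outcome: `"full"` if the persistent
#' pairing fraction reaches at least `theta_full` and stays there for a
#' persistence window, `"none"` if at most one pair ever forms
#' persistently, `"partial"` otherwise.  The nucleation pair is the first
#' pair to become persistently formed.
#'
#' @param sys A duplex `cg_system`.
#' @param scenario Distortion scenario 1-5 (see
#'   [make_distorted_duplex()]).
#' @param steps Integration steps.
#' @param seed Integer seed.
#' @param theta_full Sustained pairing fraction defining full
#'   re-annealing.
#' @param temperature Temperature, K.
#' @param theta_on,persistence Persistence definition (see
#'   [pairing_fraction()]).
#' @param sample_stride Frame storage stride.
#' @return A list of class `"anneal_result"`: `scenario`, `outcome`,
#'   `time_to_anneal` (ps or `NA`), `nucleation_pair` (1-based index
#'   from the PNA N-terminus, or `NA`), `nucleation_label`,
#'   `formation_times` (per pair, ps) and `final_fraction`.
#' @export
anneal_run <- function(sys, scenario, steps = 400000, seed = 1,
                       theta_full = 0.9, temperature = 300,
                       theta_on = 0.5, persistence = 5,
                       sample_stride = 100) {
  conf <- make_distorted_duplex(sys, scenario, seed)
  run <- run_md(sys, steps, temperature = temperature, seed = seed,
                conf = conf, sample_stride = sample_stride)
  series <- pairing_series(run, sys)
  pm <- .persistent_matrix(series, theta_on, persistence)
  frac <- rowMeans(pm)
  L <- ncol(pm)
  ## sustained full pairing: fraction >= theta_full over a persistence run
  full_run <- stats::filter(as.numeric(frac >= theta_full),
                            rep(1, persistence), sides = 1)
  ifull <- which(full_run == persistence)
  time_to_anneal <- if (length(ifull)) series$time[ifull[1] - persistence + 1L]
                    else NA_real_
  formation <- apply(pm, 2, function(col) {
    i <- which(col)[1]
    if (is.na(i)) NA_real_ else series$time[i]
  })
  nucleus <- if (all(is.na(formation))) NA_integer_ else {
    cand <- which(formation == min(formation, na.rm = TRUE))
    if (length(cand) > 1L) {
      ## tie-break: strongest mean coordination over the first window
      i <- which(series$time == min(formation, na.rm = TRUE))
      vals <- .series_matrix(series)[seq_len(i), cand, drop = FALSE]
      cand[which.max(colMeans(vals))]
    } else cand
  }
  npers <- max(rowSums(pm))
  outcome <- if (!is.na(time_to_anneal)) "full"
             else if (npers <= 1L) "none" else "partial"
  structure(list(scenario = scenario, outcome = outcome,
                 time_to_anneal = time_to_anneal,
                 nucleation_pair = nucleus,
                 nucleation_label = if (is.na(nucleus)) NA_character_
                                    else sys$topology$pair_labels[nucleus],
                 formation_times = setNames(formation,
                                            sys$topology$pair_labels),
                 final_fraction = frac[length(frac)],
                 seed = seed),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("anneal_result: scenario %d, outcome %s, t_anneal %s ps, nucleus %s\n",
              x$scenario, x$outcome,
              format(x$time_to_anneal), format(x$nucleation_label)))
  invisible(x)
}
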