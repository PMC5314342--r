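# shared fixtures, built in code

hexamer_duplex <- function() build_duplex("GAACTC", "GAGTTC")

# a hand-made pairing series with a given frames x pairs value matrix
fake_series <- function(vals, dt = 1, reference = rep(1, ncol(vals)),
                        labels = NULL) {
  if (is.null(labels)) labels <- paste0("P", seq_len(ncol(vals)), ":Q")
  cols <- sprintf("pair%d.%s", seq_along(labels), labels)
  out <- data.frame(time = seq_len(nrow(vals)) * dt)
  for (p in seq_along(cols)) out[[cols[p]]] <- vals[, p]
  structure(out, class = c("pairing_series", "data.frame"),
            reference = reference, labels = labels, columns = cols)
}

# random rigid motion applied to a coordinate matrix
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, rnorm(3), "+")
}

# small random perturbation of a system's ideal conformation
perturbed_conf <- function(sys, sd = 0.02, seed = 1) {
  set.seed(seed)
  sys$coords0 + matrix(rnorm(length(sys$coords0), sd = sd), ncol = 3)
}

# fixed-width synthetic PDB text for a toy 2-residue, 2-chain structure
write_synthetic_pdb <- function(path, n_models = 1, chains = c("A", "B")) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0
  for (m in seq_len(n_models)) {
    if (n_models > 1) writeLines(sprintf("MODEL     %4d", m), con)
    for (ch in chains) {
      for (res in 1:2) {
        base <- (m - 1) * 0.5 + (match(ch, chains) - 1) * 10
        for (at in c("C1'", "N1", "C2", "C4")) {
          serial <- serial + 1
          xyz <- c(base + res, res * 2, serial * 0.1)
          writeLines(sprintf(
            "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            serial, at, "GUA", ch, res, xyz[1], xyz[2], xyz[3], 1.0, 0.0,
            substr(at, 1, 1)), con)
        }
      }
    }
    if (n_models > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
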