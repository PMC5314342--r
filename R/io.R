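## Readers/writers: PDB ingestion (via bio3d), FASTA sequence input (via
## seqinr), and the package's own XYZ / COLVAR / HILLS / FES text
## dialects.  All writers are deterministic byte-for-byte for identical
## inputs (fixed precision, fixed column order).

#' Read PDB models
#'
#' Thin wrapper over [bio3d::read.pdb()]; coordinates are converted from
#' Angstrom to nm on ingestion.  Multiple MODEL blocks become multiple
#' conformations.
#'
#' @param path Path to a PDB file.
#' @return An object of class `"pdb_models"`: `atom` (the bio3d atom
#'   table), `xyz_nm` (n_models x 3n matrix, nm) and `n_models`.
#' @export
read_pdb_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  structure(list(atom = pdb$atom, xyz_nm = xyz / 10,
                 n_models = nrow(xyz)),
            class = "pdb_models")
}

#' Map an atomistic PDB model onto the coarse-grained representation
#'
#' For every residue (optionally restricted to one chain — strand
#' deletion by chain selection) the backbone bead is placed at the mean
#' of the named backbone atoms and the plane triplet at three named base
#' atoms, giving the 4-site-per-monomer layout used by the simulator.
#'
#' @param models A [read_pdb_models()] result.
#' @param mapping List with character vectors `backbone` (one or more
#'   atom names averaged into the backbone bead) and `plane` (exactly
#'   three atom names defining the base plane).
#' @param chain Optional chain identifier to keep (others dropped).
#' @param model Model number (1-based).
#' @return A coordinate matrix (nm) in monomer order, 4 rows per
#'   residue, with attribute `residues` (data.frame of chain/resno).
#' @export
map_to_coarse <- function(models, mapping, chain = NULL, model = 1) {
  stopifnot(model >= 1, model <= models$n_models,
            length(mapping$plane) == 3L, length(mapping$backbone) >= 1L)
  at <- models$atom
  xyz <- matrix(models$xyz_nm[model, ], ncol = 3, byrow = TRUE)
  if (!is.null(chain)) {
    keep <- at$chain %in% chain
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
  }
  key <- paste(at$chain, at$resno)
  resids <- unique(key)
  coords <- matrix(0, 4 * length(resids), 3)
  for (r in seq_along(resids)) {
    sel <- key == resids[r]
    nm <- trimws(at$elety[sel])
    bb <- which(nm %in% mapping$backbone)
    if (length(bb) == 0L)
      stop("unmapped residue (no backbone atoms): ", resids[r])
    coords[4 * (r - 1) + 1, ] <- colMeans(xyz[sel, , drop = FALSE][bb, ,
                                                                   drop = FALSE])
    for (k in 1:3) {
      p <- which(nm == mapping$plane[k])
      if (length(p) != 1L)
        stop("missing plane atom ", mapping$plane[k], " in residue ",
             resids[r])
      coords[4 * (r - 1) + 1 + k, ] <- xyz[sel, , drop = FALSE][p, ]
    }
  }
  info <- do.call(rbind, strsplit(resids, " "))
  attr(coords, "residues") <- data.frame(chain = info[, 1],
                                         resno = as.integer(info[, 2]))
  coords
}

#' Read a single-record FASTA sequence
#'
#' @param path FASTA file with exactly one record.
#' @return Uppercase base string (alphabet-checked).
#' @export
read_fasta_seq <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
  if (length(fa) != 1L)
    stop("expected exactly one FASTA record, found ", length(fa))
  s <- toupper(paste(fa[[1]], collapse = ""))
  bad <- setdiff(strsplit(s, "")[[1]], .base_alphabet)
  if (length(bad)) stop("invalid base code(s): ", paste(bad, collapse = ", "))
  s
}

#' Write / read trajectories in XYZ format
#'
#' Standard XYZ blocks; the comment line carries
#' `time_ps=... temperature_K=... seed=...` so trajectories are
#' self-describing.  Coordinates are written in nm with 6 decimals.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @param labels Per-site element labels (default `"C"`).
#' @return `write_xyz`: invisibly, the path. `read_xyz`: a
#'   `cg_trajectory`.
#' @export
write_xyz <- function(traj, path, labels = NULL) {
  ns <- dim(traj$frames)[1]
  if (is.null(labels)) labels <- rep("C", ns)
  stopifnot(length(labels) == ns)
  con <- file(path, "w")
  on.exit(close(con))
  times <- frame_times(traj)
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(ns), con)
    writeLines(sprintf("time_ps=%.6f temperature_K=%g seed=%d",
                       times[f], traj$temperature, as.integer(traj$seed)),
               con)
    m <- traj$frames[, , f]
    writeLines(sprintf("%s %12.6f %12.6f %12.6f", labels,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  ns <- as.integer(lines[1])
  block <- ns + 2L
  nf <- length(lines) %/% block
  if (nf < 1L || length(lines) %% block != 0L)
    stop("malformed XYZ file: line count mismatch")
  frames <- array(0, dim = c(ns, 3, nf))
  times <- numeric(nf)
  meta <- c(temperature_K = NA_real_, seed = NA_real_)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * block
    kv <- strsplit(strsplit(lines[off + 2L], " +")[[1]], "=")
    kvv <- setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                    vapply(kv, `[`, "", 1))
    times[f] <- kvv[["time_ps"]]
    meta["temperature_K"] <- kvv[["temperature_K"]]
    meta["seed"] <- kvv[["seed"]]
    rows <- strsplit(trimws(lines[off + 2L + seq_len(ns)]), " +")
    frames[, , f] <- t(vapply(rows, function(r) as.numeric(r[2:4]),
                              numeric(3)))
  }
  dt <- if (nf > 1L) times[2] - times[1] else times[1]
  trajectory(frames, dt = dt, temperature = meta[["temperature_K"]],
             seed = as.integer(meta[["seed"]]))
}

#' Write / read COLVAR-style CV time series
#'
#' Whitespace-separated text with a `#! FIELDS time <names>` header, one
#' record per frame, fixed precision (`%.6f`).
#'
#' @param cvs A data.frame whose first column is `time`.
#' @param path Output file.
#' @return `write_colvar`: invisibly the path; `read_colvar`: the
#'   data.frame (CV names and order preserved).
#' @export
write_colvar <- function(cvs, path) {
  stopifnot(names(cvs)[1] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(cvs), collapse = " ")), con)
  body <- do.call(sprintf, c(
    list(paste(rep("%14.6f", ncol(cvs)), collapse = " ")),
    lapply(cvs, as.numeric)))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#! FIELDS"))
    stop("missing #! FIELDS header")
  fields <- strsplit(header, " +")[[1]][-(1:2)]
  df <- utils::read.table(path, skip = 1, col.names = fields)
  if (ncol(df) != length(fields)) stop("field/column count mismatch")
  df
}

#' Write / read HILLS files
#'
#' One hill per line under a
#' `#! FIELDS time <cvs> <sigma_cvs> height biasf` header, matching the
#' common metadynamics tooling dialect.
#'
#' @param h A `hills` object.
#' @param path File path.
#' @return `write_hills`: invisibly the path; `read_hills`: a `hills`
#'   object (an empty file body yields empty hills — zero bias).
#' @export
write_hills <- function(h, path) {
  write_colvar(as.data.frame(h), path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  df <- read_colvar(path)
  nm <- names(df)
  fixed <- c("time", "height", "biasf")
  sig_cols <- grep("^sigma_", nm, value = TRUE)
  cv_names <- setdiff(nm, c(fixed, sig_cols))
  if (nrow(df) == 0L)   # empty hills: zero bias (widths unrecoverable)
    return(hills(sigma = rep(1, length(cv_names)), gamma = NA_real_,
                 cv_names = cv_names))
  sigma <- as.numeric(df[1, paste0("sigma_", cv_names)])
  hills(df$time, as.matrix(df[, cv_names, drop = FALSE]), df$height,
        sigma = sigma, gamma = df$biasf[1], cv_names = cv_names)
}

#' Write a free-energy surface as text
#'
#' Grid-center coordinates and free energy per line; header lines record
#' the field names and units.
#'
#' @param fes A `fes_grid`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fes$cvs, collapse = " "),
                   "free_energy"), con)
  writeLines(paste("#! SET units", fes$units), con)
  if (length(fes$mids) == 1L) {
    writeLines(sprintf("%14.6f %14.6f", fes$mids[[1]],
                       as.numeric(fes$F)), con)
  } else {
    g <- expand.grid(a = fes$mids[[1]], b = fes$mids[[2]])
    writeLines(sprintf("%14.6f %14.6f %14.6f", g$a, g$b,
                       as.numeric(fes$F)), con)
  }
  invisible(path)
}

#' Write a pairing series or melt/anneal tables as TSV
#'
#' @param x A data.frame (e.g. a `pairing_series` or `melt_scan`
#'   results).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
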