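# Core data types: a Conformer (one structure with its energies and shape
# fingerprint) and an Ensemble (ordered conformer collection with a
# temperature and a per-step provenance log).

#' Create a conformer
#'
#' A conformer bundles one 3D structure with its electronic energy, optional
#' Gibbs free energy and harmonic frequencies, the scalar norm of its
#' rotational-constant vector (a cheap shape fingerprint used by the
#' duplicate filter), a degeneracy, an optional Boltzmann population and an
#' active flag.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n_atoms x 3) of Cartesian coordinates in
#'   Angstrom.
#' @param E_el electronic energy in kcal/mol (`NA` if unknown).
#' @param G Gibbs free energy in kcal/mol, optional.
#' @param frequencies harmonic wavenumbers in cm^-1, optional.
#' @param B_norm scalar norm of the rotational constant vector in MHz; when
#'   `NULL` it is computed from the geometry.
#' @param degeneracy positive integer degeneracy g_i (default 1).
#' @param population unitless population in `[0, 1]`, optional.
#' @param active logical, whether the conformer is still in play.
#' @return an object of class `conformer`.
#' @export
conformer <- function(symbols, coords, E_el = NA_real_, G = NA_real_,
                      frequencies = NULL, B_norm = NULL, degeneracy = 1L,
                      population = NA_real_, active = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) != length(symbols))
    stop("coords must be an (n_atoms x 3) matrix matching symbols",
         call. = FALSE)
  if (degeneracy < 1L) stop("degeneracy must be >= 1", call. = FALSE)
  if (!is.na(population) && (population < 0 || population > 1))
    stop("population must lie in [0, 1]", call. = FALSE)
  obj <- structure(list(
    symbols = as.character(symbols), coords = coords,
    E_el = as.numeric(E_el), G = as.numeric(G),
    frequencies = if (is.null(frequencies)) NULL else as.numeric(frequencies),
    B_norm = NA_real_, degeneracy = as.integer(degeneracy),
    population = as.numeric(population), active = isTRUE(active)
  ), class = "conformer")
  if (is.null(B_norm)) {
    obj$B_norm <- tryCatch(rotational_constants(obj)$B_norm,
                           error = function(e) NA_real_)
  } else {
    if (B_norm < 0) stop("B_norm must be >= 0", call. = FALSE)
    obj$B_norm <- as.numeric(B_norm)
  }
  obj
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms (%s)\n", length(x$symbols),
              paste(utils::head(unique(x$symbols), 5), collapse = ",")))
  cat(sprintf("  E_el = %.4f kcal/mol, G = %s, B_norm = %.2f MHz, %s\n",
              x$E_el,
              if (is.na(x$G)) "NA" else sprintf("%.4f", x$G),
              x$B_norm, if (x$active) "active" else "inactive"))
  invisible(x)
}

#' Create a conformer ensemble
#'
#' @param conformers list of [conformer()] objects sharing the same atom
#'   count and atom-symbol sequence.
#' @param temperature temperature in K used for Boltzmann weighting.
#' @return an object of class `ensemble`.
#' @export
ensemble <- function(conformers, temperature = 298.15) {
  if (length(conformers) < 1L)
    stop("an ensemble needs at least one conformer", call. = FALSE)
  ref <- conformers[[1L]]$symbols
  for (i in seq_along(conformers)) {
    if (!identical(conformers[[i]]$symbols, ref))
      stop("conformer ", i, " has an atom sequence inconsistent with ",
           "conformer 1", call. = FALSE)
  }
  structure(list(conformers = conformers,
                 temperature = as.numeric(temperature),
                 step_log = list()),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d conformers (%d active), %d atoms, T = %.2f K\n",
              length(x$conformers), sum(active_flags(x)),
              length(x$conformers[[1L]]$symbols), x$temperature))
  if (length(x$step_log))
    cat(sprintf("  %d refinement step(s) logged\n", length(x$step_log)))
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$conformers)

#' Logical vector of active flags
#' @param ens an [ensemble()].
#' @return logical vector, one entry per conformer.
#' @export
active_flags <- function(ens) {
  vapply(ens$conformers, function(cf) cf$active, logical(1))
}

#' Indices of active conformers
#' @param ens an [ensemble()].
#' @return integer vector of active conformer indices.
#' @export
active_indices <- function(ens) which(active_flags(ens))

#' Extract a per-conformer field as a vector
#' @param ens an [ensemble()].
#' @param field one of `"E_el"`, `"G"`, `"B_norm"`, `"population"`,
#'   `"degeneracy"`.
#' @param active_only restrict to active conformers.
#' @return numeric vector.
#' @export
ensemble_field <- function(ens, field = c("E_el", "G", "B_norm",
                                          "population", "degeneracy"),
                           active_only = FALSE) {
  field <- match.arg(field)
  v <- vapply(ens$conformers, function(cf) as.numeric(cf[[field]]),
              numeric(1))
  if (active_only) v <- v[active_flags(ens)]
  v
}

# --- XYZ I/O ---------------------------------------------------------------

#' Read a multi-structure XYZ file as an ensemble
#'
#' Each frame is a standard XYZ block: an atom-count line, a free-format
#' comment line, then one `symbol x y z` line per atom. When the comment line
#' parses as a single real number it is taken as the frame's electronic
#' energy in Hartree (the convention of CREST/GOAT ensemble files) and
#' converted to kcal/mol; a comment of the form `E=<value> kcal/mol ...`
#' (this package's own writer) is read back without conversion.
#'
#' @param path path to the XYZ file.
#' @param temperature ensemble temperature in K.
#' @return an [ensemble()] with all conformers active.
#' @export
read_xyz_ensemble <- function(path, temperature = 298.15) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  confs <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("frame ", frame, ": invalid atom-count line '", lines[i], "'",
           call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop("frame ", frame, ": file truncated (", nat, " atoms declared)",
           call. = FALSE)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop("frame ", frame, ": malformed coordinate line ", bad[1L],
           call. = FALSE)
    sym <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      v
    }, numeric(3)))
    if (anyNA(xyz))
      stop("frame ", frame, ": non-numeric coordinate", call. = FALSE)
    # a bare-number comment is a CREST-style Hartree energy
    E_el <- NA_real_
    cm <- trimws(comment)
    if (grepl("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?$", cm)) {
      E_el <- hartree_to_kcal(as.numeric(cm))
    } else {
      m <- regmatches(cm, regexec("E=([-+0-9.eE]+)\\s*kcal/mol", cm))[[1L]]
      if (length(m) == 2L) E_el <- as.numeric(m[2L])
    }
    confs[[frame]] <- conformer(sym, xyz, E_el = E_el)
    i <- i + 2L + nat
  }
  if (!length(confs)) stop("no XYZ frames found in ", path, call. = FALSE)
  ensemble(confs, temperature = temperature)
}

#' Write an ensemble to a multi-structure XYZ file
#'
#' The comment line carries `E=<value> kcal/mol idx=<n>` (Gibbs energy when
#' available, electronic energy otherwise) so round-tripping preserves the
#' stored energy and original index.
#'
#' @param ens an [ensemble()].
#' @param path output file path.
#' @param active_only write only active conformers (default `TRUE`).
#' @return invisibly, the number of frames written.
#' @export
write_xyz_ensemble <- function(ens, path, active_only = TRUE) {
  idx <- if (active_only) active_indices(ens) else seq_along(ens$conformers)
  if (!length(idx))
    stop("no conformers to write (empty active set)", call. = FALSE)
  out <- character(0)
  for (i in idx) {
    cf <- ens$conformers[[i]]
    e <- if (!is.na(cf$G)) cf$G else cf$E_el
    out <- c(out,
             as.character(length(cf$symbols)),
             sprintf("E=%.8f kcal/mol idx=%d", e, i),
             sprintf("%-3s %17.8f %17.8f %17.8f", cf$symbols,
                     cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]))
  }
  writeLines(out, path)
  invisible(length(idx))
}

# --- geometry-derived quantities ------------------------------------------

#' Interatomic distance matrix of a conformer
#'
#' @param conf a [conformer()].
#' @param include_hydrogens keep hydrogen atoms (default `TRUE`); excluding
#'   them focuses the descriptor on the heavy-atom skeleton.
#' @return symmetric matrix of Euclidean distances in Angstrom with zero
#'   diagonal.
#' @export
distance_matrix <- function(conf, include_hydrogens = TRUE) {
  keep <- if (include_hydrogens) seq_along(conf$symbols)
          else which(conf$symbols != "H")
  if (length(keep) < 2L)
    stop("degenerate geometry: fewer than 2 atoms remain", call. = FALSE)
  as.matrix(stats::dist(conf$coords[keep, , drop = FALSE]))
}

#' Rotational constants from the inertia tensor
#'
#' Builds the mass-weighted inertia tensor about the centre of mass,
#' diagonalises it, and converts the principal moments to rotational
#' constants B_k = h / (8 pi^2 I_k). Linear molecules have one vanishing
#' moment and yield two finite constants; the scalar norm is taken over the
#' finite components only. A single atom has `B_norm = 0` by convention.
#'
#' @param conf a [conformer()].
#' @return list with `moments` (principal moments, u Angstrom^2, ascending),
#'   `B_MHz` (finite rotational constants, MHz), and `B_norm` (Euclidean norm
#'   of `B_MHz`, MHz).
#' @export
rotational_constants <- function(conf) {
  n <- length(conf$symbols)
  if (n == 1L)
    return(list(moments = c(0, 0, 0), B_MHz = numeric(0), B_norm = 0))
  m <- atomic_masses(conf$symbols)
  com <- colSums(conf$coords * m) / sum(m)
  x <- sweep(conf$coords, 2L, com)
  Ixx <- sum(m * (x[, 2]^2 + x[, 3]^2))
  Iyy <- sum(m * (x[, 1]^2 + x[, 3]^2))
  Izz <- sum(m * (x[, 1]^2 + x[, 2]^2))
  Ixy <- -sum(m * x[, 1] * x[, 2])
  Ixz <- -sum(m * x[, 1] * x[, 3])
  Iyz <- -sum(m * x[, 2] * x[, 3])
  Iten <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3L, 3L)
  moments <- sort(eigen(Iten, symmetric = TRUE, only.values = TRUE)$values)
  moments[moments < 0] <- 0
  # a moment is "zero" (linear axis) when negligible next to the largest
  tol <- max(moments) * 1e-10
  finite <- moments > tol
  B_cm1 <- ROT_CM1 / moments[finite]
  B_MHz <- B_cm1 * CM1_TO_MHZ
  list(moments = moments, B_MHz = B_MHz,
       B_norm = sqrt(sum(B_MHz^2)))
}

#' Refresh geometry-derived fields on every conformer
#'
#' Recomputes `B_norm` from the current coordinates; called by the protocol
#' runner after any step that moves atoms.
#'
#' @param ens an [ensemble()].
#' @return the updated ensemble.
#' @export
refresh_geometry <- function(ens) {
  for (i in seq_along(ens$conformers)) {
    ens$conformers[[i]]$B_norm <-
      rotational_constants(ens$conformers[[i]])$B_norm
  }
  ens
}
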