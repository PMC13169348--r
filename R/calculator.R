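# Calculator contract: any backend that refines conformers must expose
# `capabilities` (subset of energy / optimize / frequencies /
# spectra_impulses) and `evaluate(step, conformer)` returning the fields the
# step requests. The synthetic calculator below fulfils the whole contract
# with a smooth pairwise-distance energy surface, so complete protocols run
# and are testable without any quantum-chemistry engine.

#' Construct a calculator
#'
#' @param capabilities character subset of `"energy"`, `"optimize"`,
#'   `"frequencies"`, `"spectra_impulses"`.
#' @param evaluate function `(step, conformer) -> list` with components
#'   `E_el` (kcal/mol, required), and optionally `coords` (same shape as the
#'   input), `frequencies` (cm^-1) and `impulses` (named list of
#'   [impulse_spectrum()] per kind), each present only when the step
#'   requests the matching capability.
#' @param name backend label used in reports.
#' @return a `calculator` list.
#' @export
calculator <- function(capabilities, evaluate, name = "custom") {
  caps <- c("energy", "optimize", "frequencies", "spectra_impulses")
  bad <- setdiff(capabilities, caps)
  if (length(bad))
    stop("unknown capabilities: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(capabilities = capabilities, evaluate = evaluate,
                 name = name),
            class = "calculator")
}

# smooth pairwise potential (kcal/mol): Lennard-Jones-like well at r0
.syn_pair_energy <- function(D, eps = 0.3, r0 = 1.5) {
  r <- D[upper.tri(D)]
  sum(eps * ((r0 / r)^12 - 2 * (r0 / r)^6))
}

.syn_energy <- function(coords, multiplicity = 1L, seed = 0L, noise = 0,
                        eps = 0.3, r0 = 1.5) {
  D <- as.matrix(stats::dist(coords))
  e <- .syn_pair_energy(D, eps, r0) + 10 * (multiplicity - 1)
  if (noise > 0) {
    # deterministic, rigid-motion-invariant pseudo-noise
    e <- e + noise * sin(seed + 100 * sum(D[upper.tri(D)]))
  }
  e
}

.syn_gradient <- function(coords, eps = 0.3, r0 = 1.5) {
  n <- nrow(coords)
  g <- matrix(0, n, 3L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- coords[i, ] - coords[j, ]
      r <- sqrt(sum(d^2))
      dEdr <- 12 * eps / r * ((r0 / r)^6 - (r0 / r)^12)
      g[i, ] <- g[i, ] + dEdr * d / r
      g[j, ] <- g[j, ] - dEdr * d / r
    }
  }
  g
}

# bounded steepest descent; never returns a higher-energy geometry
.syn_optimize <- function(coords, multiplicity = 1L, seed = 0L, noise = 0,
                          max_iter = 200L, tol = 1e-5) {
  x <- coords
  e <- .syn_energy(x, multiplicity, seed, noise)
  alpha <- 0.01
  for (it in seq_len(max_iter)) {
    g <- .syn_gradient(x)
    gn <- sqrt(sum(g^2))
    if (gn < tol) break
    # cap the largest per-atom displacement at 0.3 A for stability on the
    # steep repulsive wall
    step <- alpha * g
    amax <- max(sqrt(rowSums(step^2)))
    if (amax > 0.3) step <- step * (0.3 / amax)
    trial <- x - step
    et <- .syn_energy(trial, multiplicity, seed, noise)
    if (et < e) {
      x <- trial
      e <- et
      alpha <- min(alpha * 1.2, 0.2)
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-9) break
    }
  }
  list(coords = x, E_el = e)
}

# toy pairwise-spring Hessian; eigenvalues mapped onto a cm^-1 scale
.syn_frequencies <- function(coords, k_scale = 400) {
  n <- nrow(coords)
  H <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- coords[i, ] - coords[j, ]
      r <- sqrt(sum(d^2))
      k <- exp(-(r - 1.5)^2)
      u <- d / r
      blk <- k * (u %o% u)
      ii <- (3L * (i - 1L) + 1L):(3L * i)
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      H[ii, ii] <- H[ii, ii] + blk
      H[jj, jj] <- H[jj, jj] + blk
      H[ii, jj] <- H[ii, jj] - blk
      H[jj, ii] <- H[jj, ii] - blk
    }
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-8]            # drop rigid-body null modes
  sort(k_scale * sqrt(ev))
}

.syn_impulses <- function(coords, freqs, kinds, conformer = NA_integer_) {
  out <- list()
  for (kind in kinds) {
    if (kind %in% c("IR", "VCD")) {
      pos <- freqs
      int <- if (kind == "IR") 0.2 + sin(pos / 50)^2 else sin(pos / 37)
    } else {
      # toy electronic transitions from the distance-matrix spectrum
      D <- as.matrix(stats::dist(coords))
      ev <- sort(abs(eigen(D, symmetric = TRUE,
                           only.values = TRUE)$values),
                 decreasing = TRUE)
      ev <- ev[seq_len(min(5L, length(ev)))]
      pos <- 220 + 180 * ev / max(ev)
      int <- if (kind == "UV") 0.2 + cos(pos / 40)^2 else cos(pos / 29)
    }
    out[[kind]] <- impulse_spectrum(kind, pos, int, conformer = conformer)
  }
  out
}

#' Deterministic synthetic calculator
#'
#' Implements the full calculator contract on a smooth surface built from
#' interatomic distances only (hence exactly invariant under rigid motion):
#' a Lennard-Jones-like pairwise energy plus `10 * (multiplicity - 1)`
#' kcal/mol per unit of spin multiplicity, bounded steepest-descent
#' optimisation on that surface, harmonic frequencies from a toy
#' pairwise-spring Hessian (all positive, cm^-1 scale), and stick spectra
#' derived deterministically from the frequencies / distance-matrix
#' eigenvalues. Identical seed and geometry give bit-identical results.
#'
#' @param seed integer seed folded into the optional noise term.
#' @param noise magnitude (kcal/mol) of a deterministic geometry-dependent
#'   perturbation; 0 (default) disables it.
#' @return a [calculator()] with all four capabilities.
#' @export
synthetic_calculator <- function(seed = 1L, noise = 0) {
  force(seed); force(noise)
  evaluate <- function(step, conformer) {
    mult <- if (!is.null(step$multiplicity)) step$multiplicity else 1L
    kind <- if (!is.null(step$kind)) step$kind else "single_point"
    coords <- conformer$coords
    out <- list()
    if (kind %in% c("opt", "opt_freq")) {
      opt <- .syn_optimize(coords, mult, seed, noise)
      coords <- opt$coords
      out$coords <- coords
      out$E_el <- opt$E_el
    } else {
      out$E_el <- .syn_energy(coords, mult, seed, noise)
    }
    if (kind %in% c("freq", "opt_freq")) {
      out$frequencies <- .syn_frequencies(coords)
    }
    kinds <- step$spectra$kinds
    if (!is.null(kinds) && length(kinds)) {
      freqs <- out$frequencies
      if (is.null(freqs) && any(kinds %in% c("IR", "VCD")))
        freqs <- .syn_frequencies(coords)
      out$impulses <- .syn_impulses(coords, freqs, kinds)
    }
    out
  }
  calculator(c("energy", "optimize", "frequencies", "spectra_impulses"),
             evaluate, name = "synthetic")
}
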