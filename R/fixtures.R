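# Deterministic generators of test ensembles and synthetic spectra with
# recorded ground truth. Geometries are chain-like backbones with seeded
# torsional perturbations: torsion changes move rotational constants and
# distance-matrix eigenvalues the way real conformational changes do,
# without needing actual chemistry.

#' Generate a synthetic conformer ensemble with known ground truth
#'
#' Builds `n_conformers` chain-like geometries (alternating C/C/O/N
#' backbone, 1.5 Angstrom bonds) whose torsions are perturbed per
#' conformer, assigns energies uniformly over `[0, energy_spread]`, and
#' plants `n_planted_duplicates` exact geometric copies of existing
#' conformers whose energies are jittered below `dup_energy_jitter`, so a
#' dual-filter deduplication at default thresholds removes exactly the
#' planted copies. All randomness derives from `seed`.
#'
#' @param n_conformers total conformer count (including planted
#'   duplicates).
#' @param n_atoms chain length (>= 4).
#' @param n_planted_duplicates number of planted exact-copy duplicates
#'   (`< n_conformers`).
#' @param energy_spread width of the uniform energy distribution, kcal/mol.
#' @param seed RNG seed.
#' @param dup_energy_jitter maximum |energy offset| of a planted duplicate
#'   from its original, kcal/mol (default 0.01, below the default thrG).
#' @param temperature ensemble temperature, K.
#' @return list with `ensemble` (an [ensemble()]) and `truth`: a list with
#'   `duplicate_of` (named integer vector: planted index -> original
#'   index), `energies` (assigned E_el per conformer) and `energy_order`
#'   (conformer indices sorted by energy).
#' @export
make_ensemble <- function(n_conformers, n_atoms = 8L,
                          n_planted_duplicates = 0L, energy_spread = 3,
                          seed = 1L, dup_energy_jitter = 0.01,
                          temperature = 298.15) {
  if (n_planted_duplicates >= n_conformers)
    stop("n_planted_duplicates must be < n_conformers", call. = FALSE)
  if (energy_spread <= 0) stop("energy_spread must be > 0", call. = FALSE)
  if (n_atoms < 4L) stop("n_atoms must be >= 4", call. = FALSE)
  set.seed(seed)
  symbols <- rep(c("C", "C", "O", "N"), length.out = n_atoms)
  n_base <- n_conformers - n_planted_duplicates

  base_geom <- function() {
    # chain with random bend/torsion angles; bond length 1.5 A
    coords <- matrix(0, n_atoms, 3L)
    coords[2L, ] <- c(1.5, 0, 0)
    for (a in 3L:n_atoms) {
      theta <- stats::runif(1, 1.6, 2.2)        # bend
      phi <- stats::runif(1, -pi, pi)           # torsion
      prev <- coords[a - 1L, ]
      dir <- prev - coords[a - 2L, ]
      dir <- dir / sqrt(sum(dir^2))
      # arbitrary orthonormal frame around the chain direction
      ref <- if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * dir) * dir
      u <- u / sqrt(sum(u^2))
      v <- c(dir[2L] * u[3L] - dir[3L] * u[2L],
             dir[3L] * u[1L] - dir[1L] * u[3L],
             dir[1L] * u[2L] - dir[2L] * u[1L])
      step <- cos(pi - theta) * dir +
        sin(pi - theta) * (cos(phi) * u + sin(phi) * v)
      coords[a, ] <- prev + 1.5 * step
    }
    coords
  }

  geoms <- replicate(n_base, base_geom(), simplify = FALSE)
  energies <- sort(stats::runif(n_base, 0, energy_spread))
  # keep non-duplicate conformers energy-separated beyond the default
  # thrG (0.05 kcal/mol) whenever the spread allows it, so the planted
  # copies are provably the only duplicate pairs
  gap_min <- min(0.11, energy_spread / n_base)
  if (n_base > 1L) {
    for (i in 2L:n_base)
      energies[i] <- max(energies[i], energies[i - 1L] + gap_min)
  }
  # planted duplicates: exact copies with sub-threshold energy jitter
  dup_of <- integer(0)
  if (n_planted_duplicates > 0L) {
    originals <- sample.int(n_base, n_planted_duplicates, replace = TRUE)
    for (d in seq_len(n_planted_duplicates)) {
      geoms[[n_base + d]] <- geoms[[originals[d]]]
      jit <- stats::runif(1, 0, dup_energy_jitter)
      energies <- c(energies, energies[originals[d]] + jit)
    }
    dup_of <- stats::setNames(originals,
                              n_base + seq_len(n_planted_duplicates))
  }

  confs <- lapply(seq_len(n_conformers), function(i)
    conformer(symbols, geoms[[i]], E_el = energies[i]))
  ens <- ensemble(confs, temperature = temperature)
  list(ensemble = ens,
       truth = list(duplicate_of = dup_of, energies = energies,
                    energy_order = order(energies)))
}

#' Generate a stick spectrum plus a matching "experimental" curve
#'
#' Draws random band positions/intensities for the requested kind and
#' convolutes them at the known `(gamma_true, delta_true)` onto a uniform
#' grid; the resulting curve plays the role of an experimental reference
#' with recorded ground truth, so shift/width fitting can be validated
#' end to end.
#'
#' @param gamma_true FWHM used to build the reference curve.
#' @param delta_true shift used (multiplicative for IR/VCD, additive for
#'   UV/ECD).
#' @param kind spectrum kind.
#' @param seed RNG seed.
#' @param n_sticks number of bands (default 8).
#' @param noise relative amplitude of added Gaussian noise (default 0).
#' @param n_grid grid size of the reference curve (default 1000).
#' @return list with `impulses` (an [impulse_spectrum()]), `exp` (a
#'   [continuous_spectrum()]) and `truth` (`gamma`, `delta`).
#' @export
make_spectrum_pair <- function(gamma_true, delta_true, kind = "IR",
                               seed = 1L, n_sticks = 8L, noise = 0,
                               n_grid = 1000L) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  set.seed(seed)
  vib <- kind %in% c("IR", "VCD")
  pos <- sort(stats::runif(n_sticks,
                           if (vib) 600 else 220,
                           if (vib) 1800 else 420))
  int <- stats::runif(n_sticks, 0.2, 1)
  if (kind %in% c("VCD", "ECD"))
    int <- int * sample(c(-1, 1), n_sticks, replace = TRUE)
  imp <- impulse_spectrum(kind, pos, int)
  shifted <- if (vib) pos * delta_true else pos + delta_true
  pad <- 6 * gamma_true
  grid <- seq(min(shifted) - pad, max(shifted) + pad,
              length.out = n_grid)
  curve <- convolute(imp, gamma_true, delta_true, grid)
  if (noise > 0)
    curve$y <- curve$y + stats::rnorm(n_grid, 0,
                                      noise * max(abs(curve$y)))
  list(impulses = imp, exp = curve,
       truth = list(gamma = gamma_true, delta = delta_true))
}
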