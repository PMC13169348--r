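# qRRHO thermochemistry. Harmonic-oscillator vibrational entropies are
# interpolated towards free-rotor values below ~100 cm^-1 with the damping
# function w(nu) = 1 / (1 + (nu0/nu)^alpha); ZPE and thermal enthalpy stay
# harmonic. Populations follow g_i exp(-dE_i / RT).

#' Low-frequency damping weight
#'
#' `w(nu) = 1 / (1 + (nu0/nu)^alpha)`: close to 1 for stiff modes, 0.5 at
#' `nu = nu0`, and vanishing for very soft modes, whose harmonic entropy
#' would otherwise diverge.
#'
#' @param nu wavenumber(s), cm^-1, strictly positive.
#' @param nu0 reference wavenumber, cm^-1 (default 100).
#' @param alpha damping exponent (default 4).
#' @return weights in (0, 1].
#' @export
damping_weight <- function(nu, nu0 = 100, alpha = 4) {
  if (any(nu <= 0)) stop("nu must be > 0", call. = FALSE)
  1 / (1 + (nu0 / nu)^alpha)
}

#' Thermochemistry input bundle
#'
#' @param frequencies harmonic wavenumbers, cm^-1 (non-negative; imaginary
#'   modes must be excluded upstream). May be empty for an atom.
#' @param moments_of_inertia principal moments in u Angstrom^2: 3 values
#'   (nonlinear), 2 (linear), or `NULL` (single atom).
#' @param molecular_mass molecular mass, u.
#' @param symmetry_number rotational symmetry number (default 1).
#' @param temperature temperature, K.
#' @param pressure pressure, atm (default 1).
#' @param nu0 damping reference wavenumber, cm^-1 (default 100).
#' @param alpha damping exponent (default 4).
#' @param B_av averaging moment for the free-rotor limit, kg m^2
#'   (default 1e-44).
#' @return a `thermo_input` list.
#' @export
thermo_input <- function(frequencies = numeric(0), moments_of_inertia = NULL,
                         molecular_mass, symmetry_number = 1L,
                         temperature = 298.15, pressure = 1,
                         nu0 = 100, alpha = 4, B_av = 1e-44) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (nu0 <= 0) stop("nu0 must be > 0", call. = FALSE)
  frequencies <- as.numeric(frequencies)
  if (any(frequencies < 0))
    stop("frequencies must be >= 0 (drop imaginary modes first)",
         call. = FALSE)
  if (any(frequencies == 0)) {
    warning("dropping ", sum(frequencies == 0), " zero frequencies")
    frequencies <- frequencies[frequencies > 0]
  }
  structure(list(frequencies = frequencies,
                 moments_of_inertia = moments_of_inertia,
                 molecular_mass = molecular_mass,
                 symmetry_number = as.integer(symmetry_number),
                 temperature = temperature, pressure = pressure,
                 nu0 = nu0, alpha = alpha, B_av = B_av),
            class = "thermo_input")
}

# per-mode harmonic vibrational entropy, cal/(mol K); x = h c nu / k T
.s_harmonic <- function(nu, T) {
  x <- H_PLANCK * C_LIGHT_CM * nu / (K_BOLTZ * T)
  s <- R_SI * (x / (expm1(x)) - log(1 - exp(-x)))
  s * J_MOL_TO_KCAL * 1000
}

# per-mode free-rotor entropy with damped effective moment, cal/(mol K)
.s_free_rotor <- function(nu, T, B_av) {
  mu <- H_PLANCK / (8 * pi^2 * C_LIGHT_CM * nu)   # kg m^2
  mu_eff <- mu * B_av / (mu + B_av)
  s <- R_SI * (0.5 + log(sqrt(8 * pi^3 * mu_eff * K_BOLTZ * T) / H_PLANCK))
  s * J_MOL_TO_KCAL * 1000
}

#' qRRHO Gibbs free energy
#'
#' Standard ideal-gas statistical thermodynamics with the vibrational
#' entropy of each mode interpolated between the harmonic-oscillator and
#' free-rotor expressions via [damping_weight()]; zero-point energy and
#' thermal enthalpy are kept fully harmonic. Returns
#' `G = E_el + ZPE + H_corr - T * S_total`.
#'
#' @param E_el electronic energy, kcal/mol.
#' @param inp a [thermo_input()].
#' @return list with `ZPE` and `H_corr` (kcal/mol), `S_total`
#'   (cal/(mol K)), `G` (kcal/mol), and the per-contribution entropy
#'   breakdown `S_trans`, `S_rot`, `S_vib`.
#' @export
qrrho_gibbs <- function(E_el, inp) {
  stopifnot(inherits(inp, "thermo_input"))
  T <- inp$temperature
  nu <- inp$frequencies
  mom <- inp$moments_of_inertia
  n_rot <- if (is.null(mom)) 0L else length(mom)
  if (!length(nu) && n_rot > 0L && all(mom <= 0))
    stop("insufficient data: polyatomic input without frequencies or ",
         "finite moments of inertia", call. = FALSE)

  # translation (Sackur-Tetrode), per mole at pressure p
  m_kg <- inp$molecular_mass * AMU_KG
  V <- R_SI * T / (inp$pressure * 101325)          # m^3/mol
  q_trans <- (2 * pi * m_kg * K_BOLTZ * T / H_PLANCK^2)^1.5 * V / N_AVOGADRO
  S_trans <- R_SI * (log(q_trans) + 2.5) * J_MOL_TO_KCAL * 1000
  H_trans <- 1.5 * R_SI * T * J_MOL_TO_KCAL

  # rotation
  if (n_rot == 0L) {
    S_rot <- 0
    H_rot <- 0
  } else if (n_rot == 2L || any(mom <= 0)) {
    I <- max(mom) * UA2_TO_KGM2
    q_rot <- 8 * pi^2 * I * K_BOLTZ * T / (inp$symmetry_number * H_PLANCK^2)
    S_rot <- R_SI * (log(q_rot) + 1) * J_MOL_TO_KCAL * 1000
    H_rot <- R_SI * T * J_MOL_TO_KCAL
  } else {
    Ik <- mom * UA2_TO_KGM2
    q_rot <- sqrt(pi) / inp$symmetry_number *
      (8 * pi^2 * K_BOLTZ * T / H_PLANCK^2)^1.5 * sqrt(prod(Ik))
    S_rot <- R_SI * (log(q_rot) + 1.5) * J_MOL_TO_KCAL * 1000
    H_rot <- 1.5 * R_SI * T * J_MOL_TO_KCAL
  }

  # vibration: harmonic ZPE/enthalpy, damped entropy
  if (length(nu)) {
    x <- H_PLANCK * C_LIGHT_CM * nu / (K_BOLTZ * T)
    ZPE <- sum(0.5 * H_PLANCK * C_LIGHT_CM * nu) * N_AVOGADRO *
      J_MOL_TO_KCAL
    H_vib <- sum(H_PLANCK * C_LIGHT_CM * nu / expm1(x)) * N_AVOGADRO *
      J_MOL_TO_KCAL
    w <- damping_weight(nu, inp$nu0, inp$alpha)
    S_vib <- sum(w * .s_harmonic(nu, T) +
                   (1 - w) * .s_free_rotor(nu, T, inp$B_av))
  } else {
    ZPE <- 0
    H_vib <- 0
    S_vib <- 0
  }

  S_total <- S_trans + S_rot + S_vib                # cal/(mol K)
  H_corr <- H_trans + H_rot + H_vib + R_KCAL * T    # + PV term
  G <- E_el + ZPE + H_corr - T * S_total / 1000
  list(ZPE = ZPE, H_corr = H_corr, S_total = S_total, G = G,
       S_trans = S_trans, S_rot = S_rot, S_vib = S_vib)
}

#' Boltzmann populations
#'
#' `p_i = g_i exp(-dE_i / RT) / sum_j g_j exp(-dE_j / RT)` with energies
#' taken relative to the minimum, R = 1.987204e-3 kcal/(mol K).
#'
#' @param energies energies, kcal/mol.
#' @param degeneracies positive integer degeneracies (default all 1).
#' @param temperature temperature, K.
#' @return populations summing to 1.
#' @export
boltzmann_populations <- function(energies, degeneracies = NULL,
                                  temperature = 298.15) {
  if (!length(energies)) stop("empty energy list", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (is.null(degeneracies)) degeneracies <- rep(1, length(energies))
  if (length(degeneracies) != length(energies))
    stop("degeneracies and energies differ in length", call. = FALSE)
  dE <- energies - min(energies)
  q <- degeneracies * exp(-dE / (R_KCAL * temperature))
  q / sum(q)
}

#' Population-weighted ensemble average energy
#'
#' `E_av = sum_i p_i E_i`.
#'
#' @param energies energies, kcal/mol.
#' @param populations weights summing to 1 (within 1e-9).
#' @return averaged energy, kcal/mol.
#' @export
boltzmann_average <- function(energies, populations) {
  if (length(energies) != length(populations))
    stop("energies and populations differ in length", call. = FALSE)
  if (abs(sum(populations) - 1) > 1e-9)
    stop("populations must sum to 1", call. = FALSE)
  sum(populations * energies)
}

#' Attach qRRHO free energies and populations to an ensemble
#'
#' For every active conformer with frequencies, drops imaginary (negative)
#' modes with a warning, evaluates [qrrho_gibbs()], and stores `G`;
#' populations over the active set are recomputed from G when every active
#' conformer has one, from E_el otherwise.
#'
#' @param ens an [ensemble()].
#' @param nu0,alpha damping parameters passed to [thermo_input()].
#' @return the updated ensemble.
#' @export
apply_thermochemistry <- function(ens, nu0 = 100, alpha = 4) {
  for (i in active_indices(ens)) {
    cf <- ens$conformers[[i]]
    if (is.null(cf$frequencies) || !length(cf$frequencies)) next
    freqs <- cf$frequencies
    if (any(freqs < 0)) {
      warning("conformer ", i, ": dropping ", sum(freqs < 0),
              " imaginary frequencies before thermochemistry")
      freqs <- freqs[freqs > 0]
    }
    rc <- rotational_constants(cf)
    mom <- rc$moments[rc$moments > max(rc$moments) * 1e-10]
    inp <- thermo_input(frequencies = freqs,
                        moments_of_inertia = mom,
                        molecular_mass = sum(atomic_masses(cf$symbols)),
                        temperature = ens$temperature,
                        nu0 = nu0, alpha = alpha)
    ens$conformers[[i]]$G <- qrrho_gibbs(cf$E_el, inp)$G
  }
  update_populations(ens)
}

#' Recompute active-set Boltzmann populations
#'
#' @param ens an [ensemble()].
#' @param use_gibbs weight on G when `TRUE`, on E_el when `FALSE`; default
#'   `NULL` picks G if every active conformer has one.
#' @return the ensemble with `population` set on active conformers (and
#'   cleared on inactive ones).
#' @export
update_populations <- function(ens, use_gibbs = NULL) {
  idx <- active_indices(ens)
  G <- vapply(ens$conformers[idx], function(cf) cf$G, numeric(1))
  if (is.null(use_gibbs)) use_gibbs <- !anyNA(G)
  E <- if (use_gibbs) G
       else vapply(ens$conformers[idx], function(cf) cf$E_el, numeric(1))
  if (anyNA(E))
    stop("missing ", if (use_gibbs) "G" else "E_el",
         " on active conformer(s) ",
         paste(idx[is.na(E)], collapse = ", "), call. = FALSE)
  g <- vapply(ens$conformers[idx], function(cf) cf$degeneracy, integer(1))
  p <- boltzmann_populations(E, g, ens$temperature)
  for (k in seq_along(ens$conformers))
    ens$conformers[[k]]$population <- NA_real_
  for (k in seq_along(idx))
    ens$conformers[[idx[k]]]$population <- p[k]
  ens
}
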