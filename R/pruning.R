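# Duplicate removal and energy-window filtering. Two conformers are treated
# as the same structure when BOTH |dE| < thrG and |dB_norm| < thrB hold; the
# higher-energy one of the pair is discarded. Scanning runs in ascending
# energy order with a greedy keep list, so the global minimum always
# survives and the result is deterministic.

#' Pruning thresholds
#'
#' @param thrG energy equivalence threshold, kcal/mol.
#' @param thrB rotational-constant-norm equivalence threshold, MHz.
#' @param thrGmax retention window above the minimum, kcal/mol.
#' @return a `prune_thresholds` list.
#' @export
prune_thresholds <- function(thrG = 0.05, thrB = 15, thrGmax = 6.0) {
  if (thrG <= 0 || thrB <= 0 || thrGmax <= 0)
    stop("all pruning thresholds must be > 0", call. = FALSE)
  structure(list(thrG = thrG, thrB = thrB, thrGmax = thrGmax),
            class = "prune_thresholds")
}

#' Step-type-dependent default thresholds
#'
#' Plain single-point steps keep a wide 6.0 kcal/mol window so that
#' high-energy structures that may relax substantially in a later
#' optimisation are carried forward; steps that optimise geometries or
#' compute frequencies tighten the window to 3.5 kcal/mol, which retains all
#' conformers with non-negligible Boltzmann population. thrG and thrB
#' defaults follow CREST-style duplicate-detection conventions. Explicit
#' protocol values always override these defaults.
#'
#' @param step_kind one of `"single_point"`, `"opt"`, `"freq"`,
#'   `"opt_freq"`.
#' @param thrG,thrB,thrGmax optional user overrides.
#' @return a [prune_thresholds()].
#' @export
default_thresholds <- function(step_kind, thrG = NULL, thrB = NULL,
                               thrGmax = NULL) {
  kinds <- c("single_point", "opt", "freq", "opt_freq")
  if (!step_kind %in% kinds)
    stop("unknown step kind '", step_kind, "'; expected one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  base_gmax <- if (step_kind == "single_point") 6.0 else 3.5
  prune_thresholds(
    thrG = if (is.null(thrG)) 0.05 else thrG,
    thrB = if (is.null(thrB)) 15 else thrB,
    thrGmax = if (is.null(thrGmax)) base_gmax else thrGmax
  )
}

# pull the working energy, erroring on missing data
.prune_energy <- function(ens, idx, use_gibbs) {
  E <- vapply(ens$conformers[idx],
              function(cf) if (use_gibbs) cf$G else cf$E_el, numeric(1))
  if (anyNA(E))
    stop("missing ", if (use_gibbs) "G" else "E_el",
         " on active conformer(s) ",
         paste(idx[is.na(E)], collapse = ", "), call. = FALSE)
  E
}

#' Remove duplicate conformers by the dual energy/rotational filter
#'
#' Active conformers are sorted by ascending energy (ties broken by original
#' index) and scanned greedily: a conformer is deactivated when both
#' `|dE| < thrG` and `|dB_norm| < thrB` hold against any already-kept
#' conformer. No structural alignment is performed.
#'
#' @param ens an [ensemble()].
#' @param thr a [prune_thresholds()].
#' @param use_gibbs compare Gibbs energies instead of electronic energies.
#' @return the ensemble with duplicates deactivated; a `prune_report`
#'   attribute records each conformer's fate.
#' @export
deduplicate <- function(ens, thr = prune_thresholds(), use_gibbs = FALSE) {
  idx <- active_indices(ens)
  E <- .prune_energy(ens, idx, use_gibbs)
  B <- vapply(ens$conformers[idx], function(cf) cf$B_norm, numeric(1))
  if (anyNA(B))
    stop("missing B_norm on active conformer(s) ",
         paste(idx[is.na(B)], collapse = ", "), call. = FALSE)
  ord <- order(E, idx)
  kept <- integer(0)
  status <- rep("kept", length(idx))
  names(status) <- idx
  for (j in ord) {
    dup_of <- 0L
    for (k in kept) {
      if (abs(E[j] - E[k]) < thr$thrG && abs(B[j] - B[k]) < thr$thrB) {
        dup_of <- k
        break
      }
    }
    if (dup_of > 0L) {
      ens$conformers[[idx[j]]]$active <- FALSE
      status[j] <- paste0("duplicate-of-", idx[dup_of])
    } else {
      kept <- c(kept, j)
    }
  }
  attr(ens, "prune_report") <- data.frame(
    index = idx, E = E, B_norm = B, status = unname(status),
    stringsAsFactors = FALSE)
  ens
}

#' Retain only conformers inside the energy window
#'
#' Conformers whose relative energy `E_i - E_min >= thrGmax` are
#' deactivated; strict `<` retains, so the minimum always survives.
#'
#' @param ens an [ensemble()].
#' @param thrGmax window width above the active minimum, kcal/mol.
#' @param use_gibbs use Gibbs energies.
#' @return the ensemble with out-of-window conformers deactivated.
#' @export
energy_window <- function(ens, thrGmax = 6.0, use_gibbs = FALSE) {
  idx <- active_indices(ens)
  E <- .prune_energy(ens, idx, use_gibbs)
  rel <- E - min(E)
  drop <- rel >= thrGmax
  for (j in which(drop)) ens$conformers[[idx[j]]]$active <- FALSE
  attr(ens, "window_report") <- data.frame(
    index = idx, E_rel = rel,
    status = ifelse(drop, "over-window", "kept"),
    stringsAsFactors = FALSE)
  ens
}

#' Integer-percent retention rate
#'
#' `round(100 * final / starting)`, the headline summary of a refinement
#' protocol.
#'
#' @param starting starting conformer count(s).
#' @param final final conformer count(s).
#' @return integer percent(s).
#' @export
retention_rate <- function(starting, final) {
  if (any(starting <= 0)) stop("starting count must be > 0", call. = FALSE)
  as.integer(round(100 * final / starting))
}
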