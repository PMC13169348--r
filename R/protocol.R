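# JSON refinement protocols: parsing/validation into protocol_step objects
# and sequential execution against a calculator. Each step evaluates the
# active conformers, refreshes geometry-derived fields, applies
# thermochemistry when frequencies are available, prunes duplicates and
# out-of-window structures, optionally clusters, optionally simulates and
# aligns spectra, and writes a tab-separated report plus the surviving
# ensemble. Reports contain no timestamps, so identical inputs and seed
# reproduce them byte for byte.

.STEP_KINDS <- c("single_point", "opt", "freq", "opt_freq")

.ALLOWED_STEP_KEYS <- c("kind", "level", "solvent", "charge",
                        "multiplicity", "thresholds", "cluster", "spectra",
                        "extra_input", "temperature")

.check_keys <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop("unknown protocol key(s) at ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
}

#' Construct a protocol step
#'
#' @param kind step kind: `"single_point"`, `"opt"`, `"freq"` or
#'   `"opt_freq"`.
#' @param level level-of-theory label (free text, e.g. a functional/basis
#'   tag); required.
#' @param solvent optional solvent label.
#' @param charge total charge (integer, default 0).
#' @param multiplicity spin multiplicity (positive integer, default 1).
#' @param thresholds optional named list overriding `thrG`, `thrB`,
#'   `thrGmax`.
#' @param cluster optional list: `enabled`, `k` (or `NULL` for automatic),
#'   `include_hydrogens`.
#' @param spectra optional list: `kinds` (subset of IR/VCD/UV/ECD),
#'   `fwhm_vibro`, `fwhm_electro`, `experimental` (named list kind -> XY
#'   file path).
#' @param extra_input optional character vector of engine directive strings
#'   passed through to the calculator.
#' @param temperature optional per-step temperature override, K.
#' @param index step index (filled by [parse_protocol()]).
#' @return a `protocol_step` list.
#' @export
protocol_step <- function(kind, level, solvent = NULL, charge = 0L,
                          multiplicity = 1L, thresholds = NULL,
                          cluster = NULL, spectra = NULL,
                          extra_input = NULL, temperature = NULL,
                          index = NA_integer_) {
  if (!kind %in% .STEP_KINDS)
    stop("unknown step kind '", kind, "'", call. = FALSE)
  if (is.null(level) || !nzchar(level))
    stop("step ", index, ": 'level' is required", call. = FALSE)
  if (length(charge) != 1L || is.na(charge) ||
      abs(charge - round(charge)) > 0)
    stop("step ", index, ": charge must be an integer", call. = FALSE)
  if (multiplicity < 1L)
    stop("step ", index, ": multiplicity must be >= 1", call. = FALSE)
  if (!is.null(thresholds))
    .check_keys(thresholds, c("thrG", "thrB", "thrGmax"),
                paste0("steps[", index, "].thresholds"))
  if (!is.null(cluster))
    .check_keys(cluster, c("enabled", "k", "include_hydrogens"),
                paste0("steps[", index, "].cluster"))
  if (!is.null(spectra)) {
    .check_keys(spectra, c("kinds", "fwhm_vibro", "fwhm_electro",
                           "experimental"),
                paste0("steps[", index, "].spectra"))
    bad <- setdiff(unlist(spectra$kinds), SPECTRUM_KINDS)
    if (length(bad))
      stop("step ", index, ": unknown spectrum kind(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(index = as.integer(index), kind = kind, level = level,
                 solvent = solvent, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 thresholds = thresholds, cluster = cluster,
                 spectra = spectra,
                 extra_input = as.character(extra_input),
                 temperature = temperature),
            class = "protocol_step")
}

#' Parse and validate a JSON protocol file
#'
#' The protocol is a JSON object with a top-level `"steps"` array; each
#' entry accepts the fields of [protocol_step()]. Unknown keys are rejected
#' with the offending path; defaults (charge 0, multiplicity 1, step-kind
#' energy windows) are filled in.
#'
#' @param path path to the JSON protocol.
#' @return list of `protocol_step` objects.
#' @export
parse_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .check_keys(doc, c("steps", "temperature"), "top level")
  if (is.null(doc$steps) || !length(doc$steps))
    stop("protocol must contain a non-empty 'steps' array", call. = FALSE)
  steps <- vector("list", length(doc$steps))
  for (i in seq_along(doc$steps)) {
    raw <- doc$steps[[i]]
    .check_keys(raw, .ALLOWED_STEP_KEYS, paste0("steps[", i, "]"))
    if (is.null(raw$kind))
      stop("steps[", i, "]: 'kind' is required", call. = FALSE)
    if (is.null(raw$level))
      stop("steps[", i, "]: 'level' is required", call. = FALSE)
    if (!is.null(raw$spectra$kinds))
      raw$spectra$kinds <- unlist(raw$spectra$kinds)
    steps[[i]] <- protocol_step(
      kind = raw$kind, level = raw$level, solvent = raw$solvent,
      charge = if (is.null(raw$charge)) 0L else raw$charge,
      multiplicity = if (is.null(raw$multiplicity)) 1L
                     else raw$multiplicity,
      thresholds = raw$thresholds, cluster = raw$cluster,
      spectra = raw$spectra,
      extra_input = if (is.null(raw$extra_input)) NULL
                    else unlist(raw$extra_input),
      temperature = if (!is.null(raw$temperature)) raw$temperature
                    else doc$temperature,
      index = i)
  }
  steps
}

#' Effective pruning thresholds of a step
#'
#' Step-kind defaults overridden by any protocol-supplied values.
#'
#' @param step a [protocol_step()].
#' @return a [prune_thresholds()].
#' @export
step_thresholds <- function(step) {
  default_thresholds(step$kind,
                     thrG = step$thresholds$thrG,
                     thrB = step$thresholds$thrB,
                     thrGmax = step$thresholds$thrGmax)
}

.step_capabilities <- function(step) {
  caps <- "energy"
  if (step$kind %in% c("opt", "opt_freq")) caps <- c(caps, "optimize")
  if (step$kind %in% c("freq", "opt_freq")) caps <- c(caps, "frequencies")
  if (!is.null(step$spectra) && length(step$spectra$kinds))
    caps <- c(caps, "spectra_impulses")
  caps
}

.write_step_report <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Run a refinement protocol
#'
#' Executes the steps in order against the calculator. Per step, for every
#' active conformer: evaluate (energy, optionally new geometry,
#' frequencies, stick spectra), then recompute rotational-constant norms,
#' apply qRRHO thermochemistry when frequencies are present, recompute
#' Boltzmann populations, remove duplicates, apply the energy window,
#' optionally cluster, and optionally simulate/align spectra. A
#' tab-separated report and the surviving ensemble in XYZ format are
#' written per step, plus one JSON run summary. A conformer whose
#' evaluation fails is flagged and excluded; the run continues.
#'
#' @param ens an [ensemble()].
#' @param steps list of [protocol_step()] (e.g. from [parse_protocol()]).
#' @param calc a [calculator()].
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param seed master seed for the clustering restarts.
#' @return the refined ensemble (step log filled in); reports on disk.
#' @export
run_protocol <- function(ens, steps, calc, out_dir = NULL, seed = 1L) {
  stopifnot(inherits(ens, "ensemble"), inherits(calc, "calculator"))
  needed <- unique(unlist(lapply(steps, .step_capabilities)))
  missing_caps <- setdiff(needed, calc$capabilities)
  if (length(missing_caps))
    stop("calculator '", calc$name, "' lacks required capabilities: ",
         paste(missing_caps, collapse = ", "), call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (step in steps) {
    si <- step$index
    if (!is.null(step$temperature)) ens$temperature <- step$temperature
    n_before <- length(active_indices(ens))
    failures <- integer(0)
    impulses_by_kind <- list()
    has_freq <- FALSE

    for (i in active_indices(ens)) {
      res <- tryCatch(calc$evaluate(step, ens$conformers[[i]]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        ens$conformers[[i]]$active <- FALSE
        failures <- c(failures, i)
        next
      }
      old_E <- ens$conformers[[i]]$E_el
      old_G <- ens$conformers[[i]]$G
      ens$conformers[[i]]$E_el <- res$E_el
      if (!is.null(res$coords)) {
        if (!identical(dim(res$coords), dim(ens$conformers[[i]]$coords)))
          stop("calculator returned a coordinate array of wrong shape for ",
               "conformer ", i, call. = FALSE)
        ens$conformers[[i]]$coords <- res$coords
      }
      if (!is.null(res$frequencies)) {
        ens$conformers[[i]]$frequencies <- res$frequencies
        has_freq <- TRUE
      } else if (step$kind == "single_point" && !is.na(old_G) &&
                 !is.na(old_E)) {
        # carry the previous step's thermal correction onto the refined
        # electronic energy (standard composite-G practice)
        ens$conformers[[i]]$G <- res$E_el + (old_G - old_E)
      } else {
        ens$conformers[[i]]$G <- NA_real_
      }
      if (!is.null(res$impulses)) {
        for (kind in names(res$impulses)) {
          res$impulses[[kind]]$conformer <- i
          impulses_by_kind[[kind]][[as.character(i)]] <-
            res$impulses[[kind]]
        }
      }
    }
    if (!length(active_indices(ens)))
      stop("step ", si, ": every conformer failed evaluation",
           call. = FALSE)

    ens <- refresh_geometry(ens)
    if (has_freq) ens <- apply_thermochemistry(ens)
    use_gibbs <- !anyNA(ensemble_field(ens, "G", active_only = TRUE))
    thr <- step_thresholds(step)
    ens <- deduplicate(ens, thr, use_gibbs = use_gibbs)
    dedup_report <- attr(ens, "prune_report")
    n_dedup <- length(active_indices(ens))
    ens <- energy_window(ens, thr$thrGmax, use_gibbs = use_gibbs)
    window_report <- attr(ens, "window_report")
    n_window <- length(active_indices(ens))
    ens <- update_populations(ens, use_gibbs = use_gibbs)

    cluster_res <- NULL
    if (isTRUE(step$cluster$enabled)) {
      k <- step$cluster$k
      inc_h <- isTRUE(step$cluster$include_hydrogens)
      ens <- cluster_ensemble(ens, k = k, include_hydrogens = inc_h,
                              seed = seed + si)
      cluster_res <- attr(ens, "cluster_result")
      ens <- update_populations(ens, use_gibbs = use_gibbs)
    }
    n_final <- length(active_indices(ens))

    fits <- list()
    if (length(impulses_by_kind) && !is.null(out_dir)) {
      act <- as.character(active_indices(ens))
      p <- ensemble_field(ens, "population", active_only = TRUE)
      for (kind in names(impulses_by_kind)) {
        imps <- impulses_by_kind[[kind]][act]
        if (any(vapply(imps, is.null, logical(1)))) next
        fv <- step$spectra$fwhm_vibro
        fe <- step$spectra$fwhm_electro
        gamma <- if (kind %in% c("IR", "VCD")) {
          if (is.null(fv)) default_fwhm(kind) else fv
        } else {
          if (is.null(fe)) default_fwhm(kind) else fe
        }
        pos <- unlist(lapply(imps, function(s) s$positions))
        pad <- 4 * gamma
        grid <- seq(max(min(pos) - pad, 1e-3), max(pos) + pad,
                    length.out = 1000L)
        sp <- ensemble_spectrum(imps, p, gamma = gamma, grid = grid)
        write_xy_spectrum(sp, file.path(out_dir,
          sprintf("step_%d_%s.xy", si, tolower(kind))))
        exp_path <- step$spectra$experimental[[kind]]
        if (!is.null(exp_path)) {
          exp_sp <- read_xy_spectrum(exp_path)
          fits[[kind]] <- autoconvolute(imps, p, exp_sp)
        }
      }
    }

    # merge the dedup and window fates into one per-conformer status table
    status <- dedup_report$status
    over <- window_report$index[window_report$status == "over-window"]
    status[dedup_report$index %in% over] <- "over-window"
    if (length(failures)) {
      status <- c(status, rep("failed", length(failures)))
      dedup_report <- rbind(dedup_report,
        data.frame(index = failures, E = NA_real_, B_norm = NA_real_,
                   status = "failed"))
    }
    rows <- data.frame(
      index = dedup_report$index,
      E_el = ensemble_field(ens, "E_el")[dedup_report$index],
      G = ensemble_field(ens, "G")[dedup_report$index],
      B_norm = dedup_report$B_norm,
      population = ensemble_field(ens, "population")[dedup_report$index],
      status = status)
    rows <- rows[order(rows$index), ]

    entry <- list(step = si, kind = step$kind, level = step$level,
                  thresholds = unclass(thr), use_gibbs = use_gibbs,
                  n_before = n_before, n_after_dedup = n_dedup,
                  n_after_window = n_window, n_final = n_final,
                  failures = failures)
    if (!is.null(cluster_res))
      entry$cluster <- list(k = cluster_res$k,
                            silhouette = cluster_res$silhouette)
    if (length(fits))
      entry$fits <- lapply(fits, function(f)
        list(gamma = f$gamma_opt, delta = f$delta_opt, rmsd = f$rmsd,
             S = f$S, converged = f$converged))
    ens$step_log[[length(ens$step_log) + 1L]] <- entry

    if (!is.null(out_dir)) {
      .write_step_report(rows,
        file.path(out_dir, sprintf("step_%d_report.tsv", si)))
      write_xyz_ensemble(ens,
        file.path(out_dir, sprintf("step_%d_ensemble.xyz", si)))
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(calculator = calc$name, seed = seed,
           temperature = ens$temperature, steps = ens$step_log),
      file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  ens
}

#' Emit a template protocol file
#'
#' Writes a minimal three-step refinement protocol (single point,
#' optimisation + frequencies, final single point) that users can edit.
#'
#' @param path output path for the JSON template.
#' @return invisibly, `path`.
#' @export
protocol_template <- function(path) {
  tmpl <- list(steps = list(
    list(kind = "single_point", level = "cheap-sp"),
    list(kind = "opt_freq", level = "dft-opt"),
    list(kind = "single_point", level = "dft-final")
  ))
  jsonlite::write_json(tmpl, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
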