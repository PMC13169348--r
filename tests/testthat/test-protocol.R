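write_protocol <- function(doc) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

test_that("protocol parsing fills defaults and validates fields", {
  p <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "gfn2"))))
  steps <- parse_protocol(p)
  expect_length(steps, 1L)
  expect_equal(steps[[1]]$charge, 0L)
  expect_equal(steps[[1]]$multiplicity, 1L)
  expect_equal(step_thresholds(steps[[1]])$thrGmax, 6.0)

  # three-step refinement: windows 6.0 / 3.5 / 6.0
  p3 <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "a"),
    list(kind = "opt_freq", level = "b"),
    list(kind = "single_point", level = "c"))))
  s3 <- parse_protocol(p3)
  expect_equal(vapply(s3, function(s) step_thresholds(s)$thrGmax,
                      numeric(1)),
               c(6.0, 3.5, 6.0))

  # a triplet step is legal (singlet-triplet gap workflows)
  pt <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "a", charge = 0,
         multiplicity = 3))))
  expect_equal(parse_protocol(pt)[[1]]$multiplicity, 3L)
})

test_that("protocol validation rejects bad documents with the path", {
  expect_error(parse_protocol(write_protocol(list(steps = list()))),
               "non-empty")
  expect_error(parse_protocol(write_protocol(list(steps = list(
    list(kind = "single_point"))))), "level")
  expect_error(parse_protocol(write_protocol(list(steps = list(
    list(kind = "single_point", level = "x", charge = 0.5))))),
    "integer")
  expect_error(parse_protocol(write_protocol(list(steps = list(
    list(kind = "single_point", level = "x", basis = "def2"))))),
    "steps\\[1\\].*basis")
  expect_error(parse_protocol(write_protocol(list(steps = list(
    list(kind = "dance", level = "x"))))), "kind")
  # user thresholds override defaults
  p <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "x",
         thresholds = list(thrGmax = 10)))))
  expect_equal(step_thresholds(parse_protocol(p)[[1]])$thrGmax, 10)
})

test_that("synthetic calculator: determinism, descent, rigid invariance", {
  calc <- synthetic_calculator(seed = 3)
  fx <- make_ensemble(2, n_atoms = 7, seed = 8)
  cf <- fx$ensemble$conformers[[1]]
  sp <- protocol_step("single_point", "x", index = 1)
  e1 <- calc$evaluate(sp, cf)$E_el
  expect_identical(calc$evaluate(sp, cf)$E_el, e1)
  # optimisation never raises the energy
  op <- protocol_step("opt", "x", index = 1)
  res <- calc$evaluate(op, cf)
  expect_lte(res$E_el, e1)
  # pairwise-distance surface is exactly rigid-motion invariant
  set.seed(13)
  moved <- cf
  moved$coords <- rigid_transform(cf$coords, random_rotation(), c(4, 5, 6))
  expect_equal(calc$evaluate(sp, moved)$E_el, e1, tolerance = 1e-9)
  # toy Hessian gives strictly positive frequencies
  fq <- protocol_step("freq", "x", index = 1)
  freqs <- calc$evaluate(fq, cf)$frequencies
  expect_true(length(freqs) > 0 && all(freqs > 0))
})

test_that("a no-op protocol leaves the survivor count unchanged", {
  fx <- make_ensemble(10, n_atoms = 6, seed = 14)  # no planted duplicates
  p <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "x",
         thresholds = list(thrG = 1e-9, thrB = 1e-9, thrGmax = 1e9)))))
  ens <- run_protocol(fx$ensemble, parse_protocol(p),
                      synthetic_calculator(), out_dir = NULL)
  expect_equal(length(active_indices(ens)), 10L)
  # and single-point steps never move atoms
  expect_identical(ens$conformers[[3]]$coords,
                   fx$ensemble$conformers[[3]]$coords)
})

test_that("planted duplicates appear as duplicate-of rows in the report", {
  fx <- make_ensemble(14, n_atoms = 7, n_planted_duplicates = 3, seed = 25)
  out <- withr::local_tempfile()
  p <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "x",
         thresholds = list(thrGmax = 1e6)))))
  # passthrough calculator keeps the fixture energies, whose ground truth
  # marks the planted copies as the only duplicate pairs
  passthrough <- calculator("energy", function(step, conformer)
    list(E_el = conformer$E_el), name = "passthrough")
  run_protocol(fx$ensemble, parse_protocol(p), passthrough,
               out_dir = out)
  rep1 <- read.delim(file.path(out, "step_1_report.tsv"))
  expect_equal(sum(grepl("^duplicate-of-", rep1$status)), 3L)
  expect_equal(sum(rep1$status == "kept"), 11L)
})

test_that("multiplicity enters through the step and shifts the energy", {
  fx <- make_ensemble(3, n_atoms = 6, seed = 31)
  mk <- function(mult) list(
    protocol_step("single_point", "x", multiplicity = mult,
                  thresholds = list(thrGmax = 1e6), index = 1L))
  calc <- synthetic_calculator()
  e1 <- run_protocol(fx$ensemble, mk(1), calc, out_dir = NULL)
  e3 <- run_protocol(fx$ensemble, mk(3), calc, out_dir = NULL)
  gaps <- ensemble_field(e3, "E_el") - ensemble_field(e1, "E_el")
  # the synthetic surface carries a closed-form 10 kcal/mol-per-unit
  # multiplicity offset: the singlet-triplet gap is exactly 20
  expect_equal(gaps, rep(20, 3), tolerance = 1e-9)
})

test_that("identical seed and protocol reproduce reports byte for byte", {
  fx <- make_ensemble(12, n_atoms = 7, n_planted_duplicates = 2, seed = 19)
  p <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "a"),
    list(kind = "opt_freq", level = "b",
         cluster = list(enabled = TRUE)),
    list(kind = "single_point", level = "c"))))
  steps <- parse_protocol(p)
  run_once <- function(dir) {
    run_protocol(fx$ensemble, steps, synthetic_calculator(seed = 2),
                 out_dir = dir, seed = 77)
    files <- sort(list.files(dir, full.names = TRUE))
    tools::md5sum(files)
  }
  d1 <- withr::local_tempfile(); d2 <- withr::local_tempfile()
  h1 <- run_once(d1); h2 <- run_once(d2)
  expect_identical(unname(h1), unname(h2))
  expect_identical(basename(names(h1)), basename(names(h2)))
})

test_that("capability mismatches fail before any evaluation", {
  fx <- make_ensemble(4, n_atoms = 6, seed = 41)
  energy_only <- calculator("energy", function(step, conformer)
    list(E_el = 0), name = "sp-only")
  p <- write_protocol(list(steps = list(
    list(kind = "opt_freq", level = "x"))))
  expect_error(run_protocol(fx$ensemble, parse_protocol(p), energy_only,
                            out_dir = NULL),
               "lacks required capabilities")
})

test_that("failing conformers are flagged and the run continues", {
  fx <- make_ensemble(6, n_atoms = 6, seed = 51)
  flaky <- calculator("energy", function(step, conformer) {
    if (abs(conformer$E_el - fx$truth$energies[3]) < 1e-12)
      stop("SCF did not converge")
    list(E_el = conformer$E_el)
  }, name = "flaky")
  p <- write_protocol(list(steps = list(
    list(kind = "single_point", level = "x",
         thresholds = list(thrGmax = 1e6)))))
  ens <- run_protocol(fx$ensemble, parse_protocol(p), flaky,
                      out_dir = NULL)
  expect_equal(ens$step_log[[1]]$failures, 3L)
  expect_equal(length(active_indices(ens)), 5L)
})

test_that("spectra steps write curves and fit against experiment", {
  fx <- make_ensemble(4, n_atoms = 6, seed = 61)
  out <- withr::local_tempfile()
  dir.create(out)
  # build an "experimental" IR file from the synthetic calculator itself
  calc <- synthetic_calculator()
  st <- protocol_step("opt_freq", "x", index = 1,
                      spectra = list(kinds = "IR"))
  imp <- calc$evaluate(st, fx$ensemble$conformers[[1]])$impulses$IR
  grid <- seq(min(imp$positions) - 50, max(imp$positions) + 50,
              length.out = 600)
  write_xy_spectrum(convolute(imp, 9, 1, grid),
                    file.path(out, "exp_ir.txt"))
  p <- write_protocol(list(steps = list(
    list(kind = "opt_freq", level = "x",
         spectra = list(kinds = "IR",
                        experimental = list(
                          IR = file.path(out, "exp_ir.txt")))))))
  ens <- run_protocol(fx$ensemble, parse_protocol(p), calc,
                      out_dir = out, seed = 1)
  expect_true(file.exists(file.path(out, "step_1_ir.xy")))
  fit <- ens$step_log[[1]]$fits$IR
  expect_false(is.null(fit))
  expect_gte(fit$S, 0)
})

test_that("protocol template emits a parseable three-step protocol", {
  path <- withr::local_tempfile(fileext = ".json")
  protocol_template(path)
  steps <- parse_protocol(path)
  expect_length(steps, 3L)
  expect_equal(vapply(steps, function(s) s$kind, character(1)),
               c("single_point", "opt_freq", "single_point"))
})
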