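test_that("Lorentzian line shape: peak height and half maximum", {
  imp <- impulse_spectrum("IR", 1000, 1)
  grid <- seq(900, 1100, by = 0.5)
  sp <- convolute(imp, gamma = 10, delta = 1, grid = grid)
  expect_equal(sp$y[grid == 1000], 1.0, tolerance = 1e-12)
  expect_equal(sp$y[grid == 1005], 0.5, tolerance = 1e-12)
  expect_equal(sp$y[grid == 995], 0.5, tolerance = 1e-12)
  expect_error(convolute(imp, gamma = 0, grid = grid), "gamma")
})

test_that("Gaussian line shape: area-normalised peak and sigma relation", {
  gam <- 2 * sqrt(2 * log(2))   # sigma = 1
  imp <- impulse_spectrum("UV", 300, 1)
  grid <- sort(unique(c(seq(280, 320, by = 0.01),
                        300 - gam / 2, 300 + gam / 2)))
  sp <- convolute(imp, gamma = gam, delta = 0, grid = grid)
  expect_equal(max(sp$y), 1 / sqrt(2 * pi), tolerance = 1e-9)
  # exact half maximum at the +/- gamma/2 points
  expect_equal(sp$y[grid == 300 + gam / 2], 0.5 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(sp$y[grid == 300 - gam / 2], 0.5 / sqrt(2 * pi),
               tolerance = 1e-12)
  # numeric FWHM from interpolated half-max crossings equals gamma
  above <- sp$y >= max(sp$y) / 2
  lo <- stats::approx(sp$y[1:which.max(sp$y)],
                      grid[1:which.max(sp$y)],
                      xout = max(sp$y) / 2)$y
  hi <- stats::approx(rev(sp$y[which.max(sp$y):length(grid)]),
                      rev(grid[which.max(sp$y):length(grid)]),
                      xout = max(sp$y) / 2)$y
  expect_equal(hi - lo, gam, tolerance = 1e-3)
})

test_that("convolution is linear and shifts act as documented", {
  grid <- seq(500, 2000, length.out = 2000)
  a <- impulse_spectrum("IR", 800, 2)
  b <- impulse_spectrum("IR", 1500, 1)
  both <- impulse_spectrum("IR", c(800, 1500), c(2, 1))
  expect_equal(convolute(both, 8, 1, grid)$y,
               convolute(a, 8, 1, grid)$y + convolute(b, 8, 1, grid)$y,
               tolerance = 1e-12)
  # multiplicative shift moves a vibrational band to omega * delta
  sp <- convolute(a, 8, 0.95, grid)
  expect_equal(grid[which.max(sp$y)], 800 * 0.95, tolerance = 1)
  # negative additive shift moves an electronic band to shorter wavelength
  uv <- impulse_spectrum("UV", 350, 1)
  gr2 <- seq(250, 450, length.out = 2000)
  sp2 <- convolute(uv, 20, -30, gr2)
  expect_equal(gr2[which.max(sp2$y)], 320, tolerance = 0.5)
})

test_that("achiral kinds refuse negative intensities; chiral carry sign", {
  expect_error(impulse_spectrum("IR", c(100, 200), c(1, -1)),
               "non-negative")
  expect_silent(impulse_spectrum("VCD", c(100, 200), c(1, -1)))
  expect_silent(impulse_spectrum("ECD", c(300, 310), c(-2, 0.5)))
  expect_error(impulse_spectrum("UV", -5, 1), "positive")
})

test_that("ensemble spectra are population-linear and order-invariant", {
  grid <- seq(500, 2000, length.out = 1000)
  i1 <- impulse_spectrum("IR", c(700, 1200), c(1, 0.5))
  i2 <- impulse_spectrum("IR", c(900, 1600), c(0.8, 1))
  # single conformer with p = 1 reduces to plain convolution
  expect_equal(ensemble_spectrum(list(i1), 1, 8, grid = grid)$y,
               convolute(i1, 8, grid = grid)$y)
  # identical conformers at p = 1/2 each: same curve
  expect_equal(ensemble_spectrum(list(i1, i1), c(0.5, 0.5), 8,
                                 grid = grid)$y,
               convolute(i1, 8, grid = grid)$y, tolerance = 1e-12)
  # direct weighted-sum oracle and permutation invariance
  mix <- ensemble_spectrum(list(i1, i2), c(2 / 3, 1 / 3), 8, grid = grid)
  expect_equal(mix$y, 2 / 3 * convolute(i1, 8, grid = grid)$y +
                 1 / 3 * convolute(i2, 8, grid = grid)$y,
               tolerance = 1e-12)
  expect_equal(ensemble_spectrum(list(i2, i1), c(1 / 3, 2 / 3), 8,
                                 grid = grid)$y, mix$y)
  expect_error(ensemble_spectrum(list(i1), c(0.5, 0.5), 8, grid = grid),
               "length")
})

test_that("weighting window: branch values, floor, and continuity", {
  win <- weight_window(1000, 1800, 1200, 1600)
  expect_equal(win$sigma1, 20)   # 0.1 * |1000 - 1200|
  expect_equal(win$sigma2, 20)
  # inner region -> 1; outside experimental window -> 0
  expect_equal(weight_function(c(1200, 1400, 1600), win), c(1, 1, 1))
  expect_equal(weight_function(c(999.9, 1800.1), win), c(0, 0))
  # taper: Gaussian normalised to 1 at the interior bound
  expect_equal(weight_function(1180, win), exp(-0.5), tolerance = 1e-12)
  # three sigma out the Gaussian (0.011) is below the 0.15 floor
  expect_equal(weight_function(1200 - 3 * 20, win), 0.15)
  expect_equal(weight_function(1600 + 3 * 20, win), 0.15)
  # continuity at the interior bounds to 1e-9
  eps <- 1e-7
  expect_equal(weight_function(1200 - eps, win),
               weight_function(1200 + eps, win), tolerance = 1e-9)
  expect_equal(weight_function(1600 + eps, win),
               weight_function(1600 - eps, win), tolerance = 1e-9)
  # disabled window degenerates to the step function
  off <- weight_window(1000, 1800, 1200, 1600, enabled = FALSE)
  expect_equal(weight_function(c(999, 1001, 1500, 1799, 1801), off),
               c(0, 1, 1, 1, 0))
  expect_error(weight_window(10, 5), "bounds")
})

test_that("weighted RMSD: identity, antipodal bound, and hand values", {
  x <- seq(0, 10, length.out = 50)
  sp <- continuous_spectrum(x, sin(x))
  expect_equal(weighted_rmsd(sp, sp), 0)
  # antipodal unit-normalised signals reach 2
  sq <- continuous_spectrum(x, rep(c(1, -1), length.out = 50))
  nq <- continuous_spectrum(x, -sq$y)
  expect_equal(weighted_rmsd(sq, nq), 2)
  # 5-point hand evaluation, explicit weights, no normalisation
  xs <- 1:5
  a <- continuous_spectrum(xs, c(0.0, 0.5, 1.0, 0.5, 0.0))
  b <- continuous_spectrum(xs, c(0.1, 0.4, 0.9, 0.7, 0.1))
  win <- weight_window(1, 5, 2, 4)
  w <- weight_function(xs, win)
  hand <- sqrt(sum(w * (a$y - b$y)^2) / sum(w))
  expect_equal(weighted_rmsd(a, b, win, normalize = FALSE), hand,
               tolerance = 1e-12)
})

test_that("similarity index: bounds, chiral max, clipping", {
  expect_equal(similarity(0), 1)
  expect_equal(similarity(0.25), 0.75)
  expect_equal(similarity(2, chiral = TRUE), 0)
  expect_equal(similarity(1.0, chiral = TRUE), 0.5)
  expect_equal(similarity(5), 0)       # clipped
  expect_error(similarity(-1), "rmsd")
})

test_that("autoconvolute recovers known parameters and respects bounds", {
  pair <- make_spectrum_pair(10, 0.97, "IR", seed = 41)
  fit <- autoconvolute(list(pair$impulses), 1, pair$exp)
  expect_true(fit$converged)
  expect_lt(abs(fit$gamma_opt - 10) / 10, 0.01)
  expect_lt(abs(fit$delta_opt - 0.97) / 0.97, 0.01)
  expect_gte(fit$S, 0.999)
  # chiral electronic case with additive shift
  pe <- make_spectrum_pair(30, -20, "ECD", seed = 42)
  fe <- autoconvolute(list(pe$impulses), 1, pe$exp)
  expect_lt(abs(fe$gamma_opt - 30) / 30, 0.01)
  expect_lt(abs(fe$delta_opt - (-20)) / 20, 0.01)
  # experiment built at the bound midpoints: immediate fixed point
  mid_gamma <- mean(default_fit_bounds("IR")$gamma)
  mid_delta <- mean(default_fit_bounds("IR")$delta)
  pm <- make_spectrum_pair(mid_gamma, mid_delta, "IR", seed = 43)
  fm <- autoconvolute(list(pm$impulses), 1, pm$exp)
  expect_lt(fm$rmsd, 1e-6)
  # truth outside the gamma bounds: estimate pinned at the nearest bound
  pb <- make_spectrum_pair(40, 1.0, "IR", seed = 44)
  fb <- autoconvolute(list(pb$impulses), 1, pb$exp)
  expect_equal(fb$gamma_opt, default_fit_bounds("IR")$gamma[2],
               tolerance = 1e-6)
})

test_that("XY spectra round-trip through text files", {
  x <- seq(200, 400, length.out = 41)   # includes the 300 nm peak
  y <- exp(-((x - 300) / 25)^2)
  path <- withr::local_tempfile(fileext = ".txt")
  # comma-separated, shuffled row order
  set.seed(1)
  ord <- sample(41)
  writeLines(sprintf("%.6f,%.6f", x[ord], y[ord]), path)
  sp <- read_xy_spectrum(path, n = 200)
  expect_equal(range(sp$x), c(200, 400))
  # linear resampling can sag slightly between the 5 nm-spaced data rows
  expect_equal(max(sp$y), 1, tolerance = 0.01)
  # writer output is readable again
  p2 <- withr::local_tempfile(fileext = ".xy")
  write_xy_spectrum(sp, p2)
  sp2 <- read_xy_spectrum(p2, n = 200)
  expect_equal(sp2$y, sp$y, tolerance = 1e-6)
})
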