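# Shared geometry builders and small numeric oracles for the test suite.

water_conformer <- function(E_el = NA_real_) {
  conformer(c("O", "H", "H"),
            rbind(c(0, 0, 0.1173),
                  c(0, 0.7572, -0.4692),
                  c(0, -0.7572, -0.4692)),
            E_el = E_el)
}

# equilateral triangle of carbons, side 1 Angstrom
triangle_conformer <- function(side = 1) {
  conformer(c("C", "C", "C"),
            side * rbind(c(0, 0, 0),
                         c(1, 0, 0),
                         c(0.5, sqrt(3) / 2, 0)))
}

# a random proper rotation matrix (seeded by the caller)
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(coords, rot = diag(3), shift = c(0, 0, 0)) {
  sweep(coords %*% t(rot), 2, -shift)
}

# write a multi-frame XYZ string to a temp file
write_xyz_text <- function(frames) {
  path <- withr::local_tempfile(fileext = ".xyz",
                                .local_envir = parent.frame())
  writeLines(unlist(frames), path)
  path
}

water_frame <- function(comment = "frame") {
  c("3", comment,
    "O   0.000000   0.000000   0.117300",
    "H   0.000000   0.757200  -0.469200",
    "H   0.000000  -0.757200  -0.469200")
}

# independent brute-force oracle for the dual-filter duplicate rule:
# scan conformers in ascending-energy order (ties by index) and drop any
# conformer matching an already-kept one on BOTH energy and B_norm
brute_force_survivors <- function(E, B, thrG, thrB) {
  ord <- order(E, seq_along(E))
  kept <- integer(0)
  for (j in ord) {
    dup <- FALSE
    for (k in kept) {
      if (abs(E[j] - E[k]) < thrG && abs(B[j] - B[k]) < thrB) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, j)
  }
  sort(kept)
}

# build an ensemble with prescribed energies and B_norms (geometry is a
# placeholder diatomic; B_norm is overridden)
synthetic_EB_ensemble <- function(E, B) {
  confs <- lapply(seq_along(E), function(i)
    conformer(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
              E_el = E[i], B_norm = B[i]))
  ensemble(confs)
}

# independently coded mean silhouette width (no cluster:: dependency)
naive_mean_silhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
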