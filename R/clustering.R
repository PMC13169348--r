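# PCA-guided K-means clustering of conformers. Features are the sorted
# eigenvalues of each conformer's interatomic distance matrix -- invariant
# under rigid motion and atom relabelling -- reduced by PCA, clustered by
# K-means over a silhouette-scanned grid of cluster counts. Each cluster is
# represented by its lowest-energy member.

#' Distance-matrix eigenvalue features
#'
#' Row i holds the eigenvalues (sorted descending) of active conformer i's
#' interatomic distance matrix. Eigenvalues are invariant under rigid
#' translation/rotation and atom reordering, making them a cheap
#' alignment-free shape descriptor.
#'
#' @param ens an [ensemble()].
#' @param include_hydrogens include hydrogens in the distance matrix
#'   (default `FALSE`: focus on the heavy-atom skeleton).
#' @return numeric matrix, n_active x n_atoms_used; rownames are conformer
#'   indices.
#' @export
eigen_features <- function(ens, include_hydrogens = FALSE) {
  idx <- active_indices(ens)
  rows <- lapply(idx, function(i) {
    D <- distance_matrix(ens$conformers[[i]], include_hydrogens)
    sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  })
  feat <- do.call(rbind, rows)
  rownames(feat) <- idx
  feat
}

#' PCA reduction of a feature matrix
#'
#' Mean-centred projection onto the leading principal components covering at
#' least `variance_kept` of the total variance. Deterministic up to
#' component sign.
#'
#' @param features numeric matrix (rows = conformers).
#' @param variance_kept fraction of variance to retain (default 0.95).
#' @return score matrix with an attribute `explained` (per-component
#'   variance fractions).
#' @export
pca_reduce <- function(features, variance_kept = 0.95) {
  if (nrow(features) < 2L)
    stop("PCA needs at least 2 rows", call. = FALSE)
  tot <- sum(apply(features, 2L, stats::var))
  if (tot <= .Machine$double.eps) {
    warning("constant feature matrix: returning a single zero component")
    scores <- matrix(0, nrow(features), 1L,
                     dimnames = list(rownames(features), "PC1"))
    attr(scores, "explained") <- 1
    return(scores)
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(expl) >= variance_kept)[1L]
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  attr(scores, "explained") <- expl[seq_len(ncomp)]
  scores
}

# one seeded K-means run with centers drawn from distinct rows
.kmeans_once <- function(scores, k, seed) {
  set.seed(seed)
  uniq <- unique(scores)
  if (nrow(uniq) < k) return(NULL)
  centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
  tryCatch(
    stats::kmeans(scores, centers = centers, iter.max = 100L),
    error = function(e) NULL)
}

# mean silhouette width of a labelling (cluster::silhouette)
.mean_silhouette <- function(scores, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Silhouette-driven K-means with representative extraction
#'
#' With `k_user` given, runs K-means at that single k. Otherwise scans every
#' integer k from `max(2, ceiling(0.10 n))` to `floor(0.80 n)` (n = number
#' of active conformers), running `restarts` seeded K-means starts per k,
#' and selects the labelling with the highest mean silhouette width; ties go
#' to the smaller k. The representative of each cluster is its
#' lowest-energy member.
#'
#' @param scores PCA score matrix from [pca_reduce()]; rownames are
#'   conformer indices.
#' @param energies energy per row of `scores`, kcal/mol.
#' @param k_user optional fixed cluster count (2 <= k_user <= n-1).
#' @param seed master seed; restart seeds are derived from it.
#' @param restarts K-means restarts per k (default 10).
#' @return a `cluster_result` list: `k`, `labels`, `silhouette`,
#'   `representatives` (conformer indices from the rownames of `scores`),
#'   `seed`.
#' @export
optimize_k <- function(scores, energies, k_user = NULL, seed = 1L,
                       restarts = 10L) {
  n <- nrow(scores)
  if (length(energies) != n)
    stop("energies must match rows of scores", call. = FALSE)
  conf_idx <- if (is.null(rownames(scores))) seq_len(n)
              else as.integer(rownames(scores))
  if (is.null(k_user) && n < 3L) {
    warning("fewer than 3 active conformers: clustering skipped")
    return(structure(list(k = n, labels = seq_len(n), silhouette = NA_real_,
                          representatives = conf_idx, seed = seed),
                     class = "cluster_result"))
  }
  if (!is.null(k_user)) {
    if (k_user < 2L || k_user > n - 1L)
      stop("k_user must satisfy 2 <= k <= n-1", call. = FALSE)
    grid <- as.integer(k_user)
  } else {
    grid <- seq.int(max(2L, ceiling(0.10 * n)), max(2L, floor(0.80 * n)))
  }
  best <- NULL
  for (k in grid) {
    for (r in seq_len(restarts)) {
      fit <- .kmeans_once(scores, k, seed = seed + 1000L * k + r)
      if (is.null(fit)) next
      s <- .mean_silhouette(scores, fit$cluster)
      if (is.na(s)) next
      # strict > : ties keep the earlier (smaller-k) candidate
      if (is.null(best) || s > best$sil + 1e-12) {
        best <- list(k = k, labels = fit$cluster, sil = s)
      }
    }
  }
  if (is.null(best))
    stop("K-means failed for every k in the grid", call. = FALSE)
  reps <- vapply(seq_len(best$k), function(cl) {
    members <- which(best$labels == cl)
    conf_idx[members[which.min(energies[members])]]
  }, integer(1))
  structure(list(k = best$k, labels = unname(best$labels),
                 silhouette = best$sil, representatives = reps,
                 seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, mean silhouette = %s\n", x$k,
              if (is.na(x$silhouette)) "NA" else sprintf("%.4f",
                                                         x$silhouette)))
  cat("  representatives:", paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' Boltzmann-average energy loss of a clustering
#'
#' `dE_av = E_av(full ensemble) - E_av(representatives)`, the full average
#' using the supplied populations and the clustered average using Boltzmann
#' weights recomputed over the representatives alone. Zero when every
#' conformer is its own cluster; grows as the clustering gets coarser.
#'
#' @param full_E energies of the full active set, kcal/mol.
#' @param full_p populations of the full active set (sum to 1).
#' @param cluster_result a result from [optimize_k()]; its
#'   `representatives` index into `full_E`.
#' @param temperature temperature, K, for the re-weighting.
#' @return dE_av in kcal/mol.
#' @export
evaluate_clustering_loss <- function(full_E, full_p, cluster_result,
                                     temperature = 298.15) {
  reps <- cluster_result$representatives
  if (!length(reps)) stop("empty representative set", call. = FALSE)
  E_av_tot <- boltzmann_average(full_E, full_p)
  E_rep <- full_E[reps]
  p_rep <- boltzmann_populations(E_rep, temperature = temperature)
  E_av_tot - boltzmann_average(E_rep, p_rep)
}

#' Cluster the active conformers of an ensemble
#'
#' Convenience wrapper: [eigen_features()] -> [pca_reduce()] ->
#' [optimize_k()], then deactivates every non-representative conformer.
#'
#' @param ens an [ensemble()].
#' @param k optional fixed cluster count.
#' @param include_hydrogens passed to [eigen_features()].
#' @param variance_kept passed to [pca_reduce()].
#' @param seed master seed for the K-means restarts.
#' @return the reduced ensemble with a `cluster_result` attribute.
#' @export
cluster_ensemble <- function(ens, k = NULL, include_hydrogens = FALSE,
                             variance_kept = 0.95, seed = 1L) {
  idx <- active_indices(ens)
  if (length(idx) < 3L && is.null(k)) {
    warning("fewer than 3 active conformers: clustering skipped")
    return(ens)
  }
  feat <- eigen_features(ens, include_hydrogens)
  scores <- suppressWarnings(pca_reduce(feat, variance_kept))
  G <- ensemble_field(ens, "G", active_only = TRUE)
  E <- if (!anyNA(G)) G else ensemble_field(ens, "E_el", active_only = TRUE)
  res <- optimize_k(scores, E, k_user = k, seed = seed)
  for (i in setdiff(idx, res$representatives))
    ens$conformers[[i]]$active <- FALSE
  attr(ens, "cluster_result") <- res
  ens
}
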