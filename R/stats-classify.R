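# Descriptor-level statistics: the two-group t-value used to select
# discriminating interface parameters, PCA on the six key descriptors,
# k-means clustering (k = 3) and the segment-count class rule.

#' Two-group t-value for a descriptor
#'
#' `t = (M1 - M2) / sqrt(Var1/n1 + Var2/n2)` on group summary statistics
#' (unequal-variance z-style form).  Values of |t| above 1.34 correspond to
#' more than 90\% confidence for group sizes in the reference regime.
#'
#' @param g1,g2 `group_stats` objects (see [group_stats()] /
#'   [aggregate_descriptor()]).
#' @param significance_threshold |t| threshold (default 1.34).
#' @return List of class `t_value`: `t`, `significant`, `threshold`.
#' @export
#' @examples
#' gI  <- group_stats(3.33, 1.87, 6)
#' gII <- group_stats(8.36, 0.85, 11)
#' t_value(gI, gII)  # about -8.1: class I uses far fewer segments
t_value <- function(g1, g2, significance_threshold = 1.34) {
  stopifnot(inherits(g1, "group_stats"), inherits(g2, "group_stats"))
  pooled <- g1$variance / g1$n + g2$variance / g2$n
  if (pooled <= 0) stop("zero pooled variance: t-value undefined")
  t <- (g1$mean - g2$mean) / sqrt(pooled)
  structure(list(t = t, significant = abs(t) > significance_threshold,
                 threshold = significance_threshold),
            class = "t_value")
}

#' @export
print.t_value <- function(x, ...) {
  cat(sprintf("t = %.3f (%ssignificant at |t| > %.2f)\n", x$t,
              if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}

#' The six key interface descriptors used for multivariate classification
#' @return Character vector of panel column names.
#' @export
key_descriptors <- function() {
  c("asa_mean_side", "n_segments", "gap_volume", "pocket_volume",
    "hb_per_100A2", "pct_charged_residues")
}

#' Principal component analysis of a descriptor panel
#'
#' Columns are centred and scaled to unit variance (the descriptors span
#' incompatible units), then the correlation matrix is eigendecomposed.
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive, making scores reproducible across platforms.
#'
#' @param panel_matrix Numeric matrix or data.frame, complexes x
#'   descriptors.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return List of class `descriptor_pca`: `scores`, `loadings`
#'   (orthonormal columns), `explained_variance` (fractions), `center`,
#'   `scale`.
#' @export
descriptor_pca <- function(panel_matrix, standardize = TRUE) {
  X <- as.matrix(panel_matrix)
  if (nrow(X) < 3L) stop("need at least 3 rows for PCA")
  if (anyNA(X)) stop("missing values in descriptor panel")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant descriptor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  ctr <- colMeans(X)
  scl <- if (standardize) sds else rep(1, ncol(X))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  C <- stats::cov(Z)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  scores <- Z %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, loadings = V,
                 explained_variance = e$values / sum(e$values),
                 center = ctr, scale = scl),
            class = "descriptor_pca")
}

#' K-means clustering of PCA scores
#'
#' Best-of-`restarts` k-means (total within-cluster sum of squares),
#' deterministic under `seed`.  Labels are canonicalised by ordering the
#' cluster centroids along the first score column, so the same partition
#' always gets the same label numbering.
#'
#' @param scores Numeric matrix (e.g. PCA scores), rows = complexes.
#' @param k Number of clusters (default 3).
#' @param restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @return List of class `descriptor_kmeans`: `labels` (1..k), `centroids`,
#'   `tot_withinss`, `seed`, `restarts`.
#' @export
descriptor_kmeans <- function(scores, k = 3L, restarts = 50L, seed = 1L) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) stop("k exceeds number of rows")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = restarts,
                      iter.max = 100L)
  ord <- order(km$centers[, 1])
  relab <- match(seq_len(k), ord)
  labels <- relab[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(labels = labels, centroids = centroids,
                 tot_withinss = km$tot.withinss,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "descriptor_kmeans")
}

#' Interface class from the segment count
#'
#' Class I (protein/peptide-like) interfaces use fewer than six continuous
#' segments; class II (globular/globular) six or more.
#'
#' @param n_segments Non-negative segment count(s).
#' @return `"I"` or `"II"`, vectorised.
#' @export
assign_class <- function(n_segments) {
  stopifnot(all(n_segments >= 0))
  ifelse(n_segments < 6, "I", "II")
}
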