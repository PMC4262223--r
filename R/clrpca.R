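#' Robust compositional PCA coordinates
#'
#' Two-dimensional ordination of compositional feature vectors for visual
#' screening of anomalous samples. Zeros are replaced multiplicatively by a
#' small value and rows renormalised; the centred log-ratio (clr) transform
#' maps compositions to a zero-sum Euclidean space; principal axes are
#' computed from a robust (minimum-covariance-determinant) covariance
#' estimate in isometric log-ratio coordinates (the clr plane's orthonormal
#' basis), falling back to the classical covariance when the robust estimate
#' is not computable (e.g. too few samples).
#'
#' @param features A proportions matrix (rows = samples, `K >= 3` columns),
#'   e.g. from [cluster_proportions()].
#' @param zero_replacement Value substituted for exact zeros; default is
#'   half a single event's proportion, `0.5 / n_events`, per sample (using
#'   the `n_events` attribute when present, otherwise `1e-6`).
#' @return A `J x 2` matrix of coordinates (rownames = sample ids).
#' @export
clr_pca_2d <- function(features, zero_replacement = NULL) {
  x <- as.matrix(features)
  K <- ncol(x)
  if (K < 3) stop("compositional PCA needs at least 3 parts (clusters)")
  n_events <- attr(features, "n_events")
  repl <- if (!is.null(zero_replacement)) rep(zero_replacement, nrow(x))
          else if (!is.null(n_events)) 0.5 / n_events
          else rep(1e-6, nrow(x))
  for (j in seq_len(nrow(x))) {
    z <- x[j, ] == 0
    if (any(z)) x[j, z] <- repl[j]
    x[j, ] <- x[j, ] / sum(x[j, ])
  }
  clr <- log(x) - rowMeans(log(x))
  # orthonormal basis of the zero-sum plane (isometric log-ratio coords)
  H <- stats::contr.helmert(K)
  V <- sweep(H, 2, sqrt(colSums(H^2)), `/`)
  Y <- clr %*% V
  rob <- tryCatch(MASS::cov.rob(Y, method = "mcd"),
                  error = function(e) list(center = colMeans(Y),
                                           cov = stats::cov(Y)))
  eig <- eigen(rob$cov, symmetric = TRUE)
  coords <- sweep(Y, 2, rob$center) %*% eig$vectors[, 1:2, drop = FALSE]
  dimnames(coords) <- list(rownames(x), c("PC1", "PC2"))
  coords
}
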