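#' Model hyperparameters
#'
#' Container for the seven free parameters of the hierarchical random-effects
#' mixture model: the two Dirichlet-process precisions `alpha` (within-sample,
#' over local clusters) and `gamma` (across samples, over global clusters), and
#' the Normal-inverse-Wishart base distribution over a global cluster's
#' parameters \eqn{(\mu_k, \Sigma_k)}:
#' \deqn{\Sigma_k \sim IW(\Sigma_0, m), \quad
#'       \mu_k \mid \Sigma_k \sim N(\mu_0, \Sigma_k/\kappa_0),}
#' with local-cluster means drawn around the global mean as Gaussian random
#' effects, \eqn{\mu_{jkt} \sim N(\mu_k, \Sigma_k/\kappa_1)}.
#'
#' `kappa0` scales the prior spread of global means around `mu0` (smaller
#' values put clusters further apart a priori); `kappa1` scales the
#' random-effects displacement of local cluster means (smaller values allow
#' larger sample-to-sample displacement). `m` is the inverse-Wishart degrees
#' of freedom; at the minimum feasible value `d + 2` the prior expectation of
#' \eqn{\Sigma_k} equals `Sigma0` while leaving the covariance maximally free.
#'
#' @param mu0 Prior mean vector (length `d`).
#' @param Sigma0 Inverse-Wishart scale matrix (`d x d`, symmetric positive
#'   definite).
#' @param m Inverse-Wishart degrees of freedom, `m >= d + 2`.
#' @param kappa0 Positive scaling of the prior mean precision.
#' @param kappa1 Positive random-effects scaling.
#' @param alpha Positive local DP precision.
#' @param gamma Positive top-level DP precision.
#' @param s Scale constant recorded when `Sigma0 = I/s` (informational).
#'
#' @return An object of class `"aspire_hyper"`: a validated list with the
#'   above elements plus the dimensionality `d`.
#' @seealso [default_hyperparams()] for the data-driven defaults.
#' @export
aspire_hyper <- function(mu0, Sigma0, m, kappa0, kappa1,
                         alpha = 1, gamma = 1, s = NA_real_) {
  mu0 <- as.numeric(mu0)
  d <- length(mu0)
  Sigma0 <- as.matrix(Sigma0)
  if (!is.numeric(Sigma0) || any(dim(Sigma0) != d))
    stop("'Sigma0' must be a ", d, "x", d, " numeric matrix")
  if (max(abs(Sigma0 - t(Sigma0))) > 1e-8 * max(1, max(abs(Sigma0))))
    stop("'Sigma0' must be symmetric")
  ev <- eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'Sigma0' must be positive definite")
  if (!is.numeric(m) || length(m) != 1 || m < d + 2)
    stop("'m' must be a scalar >= d + 2 (= ", d + 2, ")")
  for (nm in c("kappa0", "kappa1", "alpha", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("'", nm, "' must be a non-negative scalar")
  }
  if (kappa0 <= 0 || kappa1 <= 0) stop("'kappa0' and 'kappa1' must be > 0")
  structure(
    list(alpha = alpha, gamma = gamma, kappa0 = kappa0, kappa1 = kappa1,
         mu0 = mu0, Sigma0 = Sigma0, m = m, s = s, d = d),
    class = "aspire_hyper"
  )
}

#' Default hyperparameters for a batch
#'
#' Data-driven defaults: vague DP precisions `alpha = gamma = 1`; inverse-
#' Wishart degrees of freedom at the minimum feasible value `m = d + 2` so the
#' cluster covariances may deviate freely from their prior expectation;
#' prior mean `mu0` equal to the pooled mean of all events in the batch; and
#' scale matrix `Sigma0 = I/s`.
#'
#' `s` and `kappa0` are the two constants a user may want to calibrate to the
#' measurement scale of their instrument; the defaults here (`s = 1`,
#' `kappa0 = 0.01`) suit data whose within-cluster standard deviations are of
#' order one and whose cluster centres spread over tens of units, as is the
#' case after the usual log-transform-and-standardise preprocessing.
#'
#' @param batch A list of numeric event matrices (rows = cells, columns =
#'   channels), all with the same number of columns.
#' @param s Positive scale constant; `Sigma0 = I/s`.
#' @param kappa0 Positive prior-mean scaling.
#' @param kappa1 Positive random-effects scaling (candidate values are usually
#'   compared with [select_kappa1()]).
#'
#' @return An `"aspire_hyper"` object.
#' @examples
#' b <- list(matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE))
#' hp <- default_hyperparams(b, s = 4, kappa0 = 0.01, kappa1 = 0.05)
#' hp$mu0      # pooled mean (1, 1)
#' hp$m        # d + 2 = 4
#' @export
default_hyperparams <- function(batch, s = 1, kappa0 = 0.01, kappa1 = 0.05) {
  batch <- as_batch(batch)
  if (length(batch) == 0) stop("'batch' must contain at least one sample")
  dims <- vapply(batch, ncol, integer(1))
  if (length(unique(dims)) != 1)
    stop("all samples must share the same number of channels; got ",
         paste(unique(dims), collapse = ", "))
  d <- dims[[1]]
  if (!is.numeric(s) || length(s) != 1 || s <= 0) stop("'s' must be a positive scalar")
  pooled <- do.call(rbind, batch)
  aspire_hyper(mu0 = colMeans(pooled), Sigma0 = diag(d) / s, m = d + 2,
               kappa0 = kappa0, kappa1 = kappa1, alpha = 1, gamma = 1, s = s)
}

#' @export
print.aspire_hyper <- function(x, ...) {
  cat("Hyperparameters (d = ", x$d, "):\n", sep = "")
  cat(sprintf("  alpha = %g, gamma = %g, kappa0 = %g, kappa1 = %g, m = %g\n",
              x$alpha, x$gamma, x$kappa0, x$kappa1, x$m))
  cat("  mu0 =", format(x$mu0, digits = 4), "\n")
  cat("  Sigma0:\n")
  print(x$Sigma0, digits = 4)
  invisible(x)
}

## Coerce a single matrix / data.frame / list into a named list of matrices.
as_batch <- function(x) {
  if (is.matrix(x)) x <- list(x)
  if (is.data.frame(x)) x <- list(as.matrix(x))
  if (!is.list(x)) stop("'batch' must be a matrix or a list of matrices")
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    if (!is.numeric(m)) stop("event matrices must be numeric")
    storage.mode(m) <- "double"
    m
  })
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- sprintf("sample%02d", seq_along(x))
  x
}
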