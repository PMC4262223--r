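## Collapsed predictive densities.
##
## Conjugate chain: (mu_k, Sigma_k) ~ NIW(mu0, kappa0, Sigma0, m); each local
## cluster t of class k has mean mu_jkt ~ N(mu_k, Sigma_k/kappa1) and events
## x ~ N(mu_jkt, Sigma_k).  Integrating each local mean gives, per cluster
## with n points and empirical mean xbar, an effective weight
##   ntil = n * kappa1 / (n + kappa1)
## so that xbar acts like ntil pseudo-observations of mu_k, while the
## within-cluster scatter contributes to Sigma_k with its full n - 1 + 1
## degrees.  The posterior over (mu_k, Sigma_k) given class data partitioned
## into clusters is then again Normal-inverse-Wishart, and every one-point
## predictive is a multivariate Student-t.

lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

## NIW posterior over (mu_k, Sigma_k) given a class's local clusters.
class_posterior <- function(clusters, hp) {
  d <- hp$d
  N <- 0L
  W <- 0
  V <- numeric(d)
  M <- matrix(0, d, d)
  logw <- 0
  for (cl in clusters) {
    n <- cl$n
    if (n == 0L) next
    xbar <- cl$sum / n
    ntil <- n * hp$kappa1 / (n + hp$kappa1)
    N <- N + n
    W <- W + ntil
    V <- V + ntil * xbar
    M <- M + cl$scatter - (n - ntil) * tcrossprod(xbar)
    logw <- logw + (d / 2) * log(hp$kappa1 / (hp$kappa1 + n))
  }
  kappa_n <- hp$kappa0 + W
  mu_n <- (hp$kappa0 * hp$mu0 + V) / kappa_n
  Lambda <- hp$Sigma0 + M + hp$kappa0 * tcrossprod(hp$mu0) -
    kappa_n * tcrossprod(mu_n)
  Lambda <- (Lambda + t(Lambda)) / 2
  list(kappa_n = kappa_n, mu_n = mu_n, Lambda = Lambda, m_n = hp$m + N,
       N = N, logw = logw)
}

#' Log marginal likelihood of one class's data
#'
#' Closed-form marginal likelihood of all events currently assigned to one
#' global cluster (class), given their partition into local clusters, with the
#' class parameters \eqn{(\mu_k, \Sigma_k)} and every local-cluster mean
#' integrated out analytically. The sum of this quantity over classes is the
#' "Gibbs likelihood" used to compare random-effects scalings in
#' [select_kappa1()].
#'
#' @param class_stats A list of per-local-cluster [suffstats()] objects (a
#'   single object is treated as one cluster; `NULL`/empty gives 0).
#' @param hp An [aspire_hyper()] object.
#' @return The log marginal likelihood (a scalar; 0 for an empty class).
#' @export
class_log_marginal <- function(class_stats, hp) {
  clusters <- as_cluster_list(class_stats)
  if (length(clusters) == 0) return(0)
  post <- class_posterior(clusters, hp)
  d <- hp$d
  N <- post$N
  ld0 <- determinant(hp$Sigma0, logarithm = TRUE)$modulus[1]
  ldn <- determinant(post$Lambda, logarithm = TRUE)$modulus[1]
  -(N * d / 2) * log(pi) +
    post$logw + (d / 2) * log(hp$kappa0 / post$kappa_n) +
    lmvgamma(post$m_n / 2, d) - lmvgamma(hp$m / 2, d) +
    (hp$m / 2) * ld0 - (post$m_n / 2) * ldn
}

#' Class predictive distribution
#'
#' Posterior predictive density of a new event that opens a *fresh* local
#' cluster within class `k`, given all events currently assigned to that class
#' (partitioned into their local clusters). Marginalising the fresh local
#' mean (drawn `N(mu_k, Sigma_k/kappa1)`) and the class parameters under
#' their Normal-inverse-Wishart posterior yields a multivariate Student-t:
#' dof `m + N - d + 1`, centre the posterior mean of `mu_k`, and scale
#' inflated by `1 + 1/kappa1 + 1/kappa_n`.
#'
#' With empty `class_stats` this is the prior predictive for a brand-new
#' class (see [prior_predictive()]).
#'
#' @inheritParams class_log_marginal
#' @return An object of class `"aspire_studentt"`: list with `dof`, `center`
#'   and `scale` (the positive-definite scale matrix of the multivariate t).
#' @seealso [dstudentt()] to evaluate the density, [local_cluster_predictive()]
#'   for joining an existing cluster.
#' @export
class_predictive <- function(class_stats, hp) {
  clusters <- as_cluster_list(class_stats)
  post <- class_posterior(clusters, hp)
  dof <- post$m_n - hp$d + 1
  if (dof <= 0) stop("degenerate posterior: non-positive Student-t dof")
  cc <- 1 + 1 / hp$kappa1 + 1 / post$kappa_n
  scale <- cc * post$Lambda / dof
  if (!all(is.finite(scale)) || min(eigen(scale, TRUE, TRUE)$values) <= 0)
    stop("numerical breakdown: predictive scale matrix is not positive definite")
  structure(list(dof = dof, center = post$mu_n, scale = scale),
            class = "aspire_studentt")
}

#' Multivariate Student-t log density
#'
#' @param x Numeric vector (one point) or matrix (rows = points).
#' @param params An `"aspire_studentt"` object (`dof`, `center`, `scale`).
#' @param log Return log density (default) or density.
#' @return Numeric vector of (log) densities.
#' @export
dstudentt <- function(x, params, log = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d <- length(params$center)
  R <- chol(params$scale)
  z <- backsolve(R, t(x) - params$center, transpose = TRUE)
  q <- colSums(z^2)
  ld <- lgamma((params$dof + d) / 2) - lgamma(params$dof / 2) -
    (d / 2) * log(params$dof * pi) - sum(log(diag(R))) -
    ((params$dof + d) / 2) * log1p(q / params$dof)
  if (log) ld else exp(ld)
}

#' @export
print.aspire_studentt <- function(x, ...) {
  cat("Multivariate Student-t: dof =", format(x$dof, digits = 4), "\n")
  cat("  center =", format(x$center, digits = 4), "\n")
  invisible(x)
}

#' Predictive log density for joining an existing local cluster
#'
#' Log posterior predictive density of event `x` joining an existing local
#' cluster with statistics `cluster_stats`, whose class also contains the
#' clusters in `class_stats_excl` (across all samples). The candidate event
#' itself must already have been removed from all statistics. The local mean
#' of the candidate cluster and the class parameters are integrated out; the
#' result is a Student-t centred at a precision-weighted compromise
#' `w * mu_n + (1 - w) * xbar` between the class posterior mean and the
#' cluster's empirical mean, with `w = kappa1/(kappa1 + n)`: small `kappa1`
#' (strong random effects) trusts the cluster's own mean, large `kappa1`
#' shrinks towards the class mean.
#'
#' @param x Numeric event vector.
#' @param cluster_stats [suffstats()] of the candidate cluster (`n >= 1`).
#' @param class_stats_excl The class's *other* local clusters (list of
#'   [suffstats()], possibly empty/`NULL`), excluding the candidate cluster
#'   and the candidate point.
#' @param hp An [aspire_hyper()] object.
#' @return Log predictive density (scalar).
#' @export
local_cluster_predictive <- function(x, cluster_stats, class_stats_excl, hp) {
  if (!inherits(cluster_stats, "aspire_suffstats") || cluster_stats$n < 1L)
    stop("'cluster_stats' must be non-empty; use class_predictive()/",
         "prior_predictive() for a new cluster")
  clusters <- c(as_cluster_list(class_stats_excl), list(cluster_stats))
  post <- class_posterior(clusters, hp)
  dof <- post$m_n - hp$d + 1
  n <- cluster_stats$n
  xbar <- cluster_stats$sum / n
  w <- hp$kappa1 / (hp$kappa1 + n)
  center <- w * post$mu_n + (1 - w) * xbar
  cc <- 1 + 1 / (hp$kappa1 + n) + w^2 / post$kappa_n
  params <- structure(list(dof = dof, center = center,
                           scale = cc * post$Lambda / dof),
                      class = "aspire_studentt")
  dstudentt(x, params, log = TRUE)
}

#' Prior predictive log density
#'
#' Predictive density of an event under an entirely new class: the class
#' parameters are drawn from the Normal-inverse-Wishart base distribution and
#' a fresh local-cluster mean from the random-effects kernel. Identical to
#' `class_predictive(NULL, hp)` evaluated at `x`; Student-t centred at `mu0`.
#'
#' @param x Numeric event vector or matrix of events.
#' @param hp An [aspire_hyper()] object.
#' @return Log predictive density (scalar or vector).
#' @export
prior_predictive <- function(x, hp) {
  dstudentt(x, class_predictive(NULL, hp), log = TRUE)
}

#' Joint marginal log likelihood of a whole local cluster under a class
#'
#' Joint predictive likelihood of a set of events entering a candidate class
#' *as one new local cluster*, given the class's current data
#' (`context_stats`, partitioned into its local clusters and excluding the
#' set). Computed by the chain rule: the first point is scored by the class
#' predictive, and each subsequent point by [local_cluster_predictive()] with
#' the growing set as the candidate cluster. By exchangeability the result is
#' invariant to the ordering of `set_points`, and it equals the difference of
#' closed-form class marginals with and without the set.
#'
#' @param set_points Numeric matrix of events (rows), non-empty.
#' @param context_stats The candidate class's local clusters (list of
#'   [suffstats()], possibly empty/`NULL` for a new class).
#' @param hp An [aspire_hyper()] object.
#' @return Joint log likelihood (scalar).
#' @export
joint_set_log_likelihood <- function(set_points, context_stats, hp) {
  if (is.vector(set_points)) set_points <- matrix(set_points, nrow = 1)
  set_points <- as.matrix(set_points)
  if (nrow(set_points) == 0) stop("'set_points' must be non-empty")
  context <- as_cluster_list(context_stats)
  total <- dstudentt(set_points[1, ], class_predictive(context, hp), log = TRUE)
  grow <- suffstats(set_points[1, , drop = FALSE])
  if (nrow(set_points) > 1) {
    for (i in 2:nrow(set_points)) {
      total <- total +
        local_cluster_predictive(set_points[i, ], grow, context, hp)
      grow <- suffstats_update(grow, set_points[i, ], "add")
    }
  }
  total
}
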