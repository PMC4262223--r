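## Independent oracles for the collapsed predictive densities.
##
## Route 1 (exact): the joint density of all events of one class, stacked as
## an N x d matrix X with local-cluster membership matrix Z, is matrix-t:
## given Sigma, X ~ MN(1 mu0', Omega, Sigma) with row covariance
##   Omega = I_N + (1/kappa1) Z Z' + (1/kappa0) 1 1'
## and Sigma ~ IW(Sigma0, m).  Integrating Sigma gives a closed form that
## never touches the package's sequential conjugate updates.
##
## Route 2 (Monte Carlo): forward draws from the stated hierarchy, either
## directly (prior predictive) or by self-normalised importance sampling with
## draws of (mu, Sigma) from the NIW prior (data-conditioned predictives).

oracle_lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

## points_by_cluster: list of matrices, one per local cluster (rows = events)
oracle_class_marginal <- function(points_by_cluster, hp) {
  points_by_cluster <- Filter(function(m) nrow(m) > 0, points_by_cluster)
  if (length(points_by_cluster) == 0) return(0)
  X <- do.call(rbind, points_by_cluster)
  N <- nrow(X)
  d <- ncol(X)
  z <- rep(seq_along(points_by_cluster),
           vapply(points_by_cluster, nrow, integer(1)))
  Z <- outer(z, seq_along(points_by_cluster), `==`) * 1
  Omega <- diag(N) + (1 / hp$kappa1) * tcrossprod(Z) +
    (1 / hp$kappa0) * matrix(1, N, N)
  Xc <- sweep(X, 2, hp$mu0)
  S <- hp$Sigma0 + t(Xc) %*% solve(Omega, Xc)
  -(N * d / 2) * log(pi) - (d / 2) * determinant(Omega)$modulus[1] +
    oracle_lmvgamma((hp$m + N) / 2, d) - oracle_lmvgamma(hp$m / 2, d) +
    (hp$m / 2) * determinant(hp$Sigma0)$modulus[1] -
    ((hp$m + N) / 2) * determinant(S)$modulus[1]
}

## Predictive of x joining cluster `join` (index into points_by_cluster, or
## 0 to open a new cluster) of a class with the given data, as a marginal
## ratio.  Exact.
oracle_predictive <- function(x, points_by_cluster, join, hp) {
  aug <- points_by_cluster
  x <- matrix(x, nrow = 1)
  if (join == 0) aug <- c(aug, list(x)) else aug[[join]] <- rbind(aug[[join]], x)
  oracle_class_marginal(aug, hp) - oracle_class_marginal(points_by_cluster, hp)
}

## --- Monte Carlo oracles --------------------------------------------------

riw <- function(Sigma0, m) {
  # one draw from IW(Sigma0, m)
  solve(stats::rWishart(1, df = m, Sigma = solve(Sigma0))[, , 1])
}

rmvn1 <- function(mu, Sigma) {
  mu + drop(crossprod(chol(Sigma), stats::rnorm(length(mu))))
}

## Direct MC of the prior predictive: draw (mu, Sigma) ~ NIW, a local mean
## from the random-effects kernel, and average the Gaussian density at x.
oracle_mc_prior_predictive <- function(x, hp, ndraws, seed = 42) {
  set.seed(seed)
  d <- hp$d
  vals <- numeric(ndraws)
  for (r in seq_len(ndraws)) {
    Sigma <- riw(hp$Sigma0, hp$m)
    mu <- rmvn1(hp$mu0, Sigma / hp$kappa0)
    mloc <- rmvn1(mu, Sigma / hp$kappa1)
    vals[r] <- dmvnorm1(x, mloc, Sigma)
  }
  list(est = mean(vals), se = stats::sd(vals) / sqrt(ndraws))
}

dmvnorm1 <- function(x, mu, Sigma) {
  R <- chol(Sigma)
  z <- backsolve(R, x - mu, transpose = TRUE)
  exp(-0.5 * sum(z^2) - sum(log(diag(R))) - length(x) / 2 * log(2 * pi))
}

## Self-normalised importance sampling for data-conditioned predictives:
## (mu, Sigma) from the NIW prior, weighted by the class data likelihood
## (local means integrated per cluster by elementary Gaussian algebra), and
## the predictive kernel f(x | mu, Sigma) for the requested move.
## join = 0: new local cluster; join = t: existing cluster t.
oracle_mc_predictive <- function(x, points_by_cluster, join, hp, ndraws,
                                 seed = 42) {
  set.seed(seed)
  d <- hp$d
  logw <- numeric(ndraws)
  fx <- numeric(ndraws)
  for (r in seq_len(ndraws)) {
    Sigma <- riw(hp$Sigma0, hp$m)
    mu <- rmvn1(hp$mu0, Sigma / hp$kappa0)
    lw <- 0
    for (P in points_by_cluster) {
      n <- nrow(P)
      if (n == 0) next
      xbar <- colMeans(P)
      ntil <- n * hp$kappa1 / (n + hp$kappa1)
      Pc <- sweep(P, 2, xbar)
      Sw <- crossprod(Pc)
      R <- chol(Sigma)
      ldS <- 2 * sum(log(diag(R)))
      qS <- sum(backsolve(R, t(Pc), transpose = TRUE)^2) +
        ntil * sum(backsolve(R, xbar - mu, transpose = TRUE)^2)
      lw <- lw - (n * d / 2) * log(2 * pi) - (n / 2) * ldS +
        (d / 2) * log(hp$kappa1 / (hp$kappa1 + n)) - qS / 2
    }
    logw[r] <- lw
    if (join == 0) {
      mloc <- rmvn1(mu, Sigma / hp$kappa1)
    } else {
      P <- points_by_cluster[[join]]
      n <- nrow(P)
      kap <- hp$kappa1 + n
      mpost <- (hp$kappa1 * mu + n * colMeans(P)) / kap
      mloc <- rmvn1(mpost, Sigma / kap)
    }
    fx[r] <- dmvnorm1(x, mloc, Sigma)
  }
  w <- exp(logw - max(logw))
  est <- sum(w * fx) / sum(w)
  # delta-method standard error of the self-normalised ratio estimator
  se <- sqrt(sum(w^2 * (fx - est)^2)) / sum(w)
  list(est = est, se = se)
}

## --- set partition enumeration -------------------------------------------

## All set partitions of n items as restricted-growth strings (n small).
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, mx) {
    i <- length(code) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- code
      return(invisible())
    }
    for (b in seq_len(mx + 1)) rec(c(code, b), max(mx, b))
  }
  rec(integer(0), 0L)
  out
}

canonical_code <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ".")
}

log_crp <- function(sizes, conc) {
  length(sizes) * log(conc) + sum(lgamma(sizes))
}

## Exact stationary law of the event -> local-cluster partition for the
## hierarchical sampler on a single sample: enumerate event partitions rho
## and, nested, partitions sigma of rho's blocks into classes.  The
## class-level CRP normaliser (gamma)_B depends on the number of blocks B of
## rho and must be kept; the event-level normaliser (alpha)_n is common to
## all rho and drops out.
aspire_partition_law <- function(X, hp) {
  n <- nrow(X)
  rhos <- all_partitions(n)
  logp <- vapply(rhos, function(rho) {
    blocks <- lapply(sort(unique(rho)), function(b) X[rho == b, , drop = FALSE])
    B <- length(blocks)
    sigmas <- all_partitions(B)
    terms <- vapply(sigmas, function(sg) {
      classes <- lapply(sort(unique(sg)), function(cid) blocks[sg == cid])
      lm <- sum(vapply(classes, oracle_class_marginal, numeric(1), hp = hp))
      log_crp(tabulate(sg), hp$gamma) + lm
    }, numeric(1))
    log_crp(tabulate(rho), hp$alpha) -
      (lgamma(hp$gamma + B) - lgamma(hp$gamma)) + logsumexp(terms)
  }, numeric(1))
  p <- exp(logp - logsumexp(logp))
  names(p) <- vapply(rhos, canonical_code, character(1))
  p
}

## Exact stationary partition law for the pooled Dirichlet-process mixture:
## CRP(alpha) prior times the plain NIW marginal likelihood per block.
dpgmm_partition_law <- function(X, hp) {
  n <- nrow(X)
  rhos <- all_partitions(n)
  logp <- vapply(rhos, function(rho) {
    lm <- sum(vapply(sort(unique(rho)), function(b) {
      P <- X[rho == b, , drop = FALSE]
      oracle_niw_marginal(P, hp)
    }, numeric(1)))
    log_crp(tabulate(rho), hp$alpha) + lm
  }, numeric(1))
  p <- exp(logp - logsumexp(logp))
  names(p) <- vapply(rhos, canonical_code, character(1))
  p
}

## Plain NIW marginal (no random effects): multivariate-t route via
## Omega = I + (1/kappa0) 1 1'.
oracle_niw_marginal <- function(X, hp) {
  N <- nrow(X)
  if (N == 0) return(0)
  d <- ncol(X)
  Omega <- diag(N) + (1 / hp$kappa0) * matrix(1, N, N)
  Xc <- sweep(X, 2, hp$mu0)
  S <- hp$Sigma0 + t(Xc) %*% solve(Omega, Xc)
  -(N * d / 2) * log(pi) - (d / 2) * determinant(Omega)$modulus[1] +
    oracle_lmvgamma((hp$m + N) / 2, d) - oracle_lmvgamma(hp$m / 2, d) +
    (hp$m / 2) * determinant(hp$Sigma0)$modulus[1] -
    ((hp$m + N) / 2) * determinant(S)$modulus[1]
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## --- vectorised Monte Carlo oracles (d = 1 or 2 only) ---------------------
## Forward draws of (mu, Sigma) from the NIW prior with elementary closed
## forms per draw; self-normalised importance weights condition on the class
## data.  Fast enough for 1e6 draws in plain R.

rniw_vec <- function(hp, n) {
  d <- hp$d
  if (d == 1) {
    prec <- stats::rgamma(n, shape = hp$m / 2, rate = hp$Sigma0[1, 1] / 2)
    S11 <- 1 / prec
    out <- list(S11 = S11, S12 = NULL, S22 = NULL,
                W11 = prec, W12 = NULL, W22 = NULL, logdetS = log(S11))
    out$L11 <- sqrt(S11); out$L21 <- NULL; out$L22 <- NULL
    out$mu1 <- hp$mu0[1] + out$L11 * stats::rnorm(n) / sqrt(hp$kappa0)
    out$mu2 <- NULL
  } else if (d == 2) {
    W <- stats::rWishart(n, df = hp$m, Sigma = solve(hp$Sigma0))
    W11 <- W[1, 1, ]; W12 <- W[1, 2, ]; W22 <- W[2, 2, ]
    detW <- W11 * W22 - W12^2
    S11 <- W22 / detW; S12 <- -W12 / detW; S22 <- W11 / detW
    L11 <- sqrt(S11); L21 <- S12 / L11; L22 <- sqrt(pmax(S22 - L21^2, 1e-300))
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    out <- list(S11 = S11, S12 = S12, S22 = S22,
                W11 = W11, W12 = W12, W22 = W22, logdetS = -log(detW),
                L11 = L11, L21 = L21, L22 = L22,
                mu1 = hp$mu0[1] + L11 * z1 / sqrt(hp$kappa0),
                mu2 = hp$mu0[2] + (L21 * z1 + L22 * z2) / sqrt(hp$kappa0))
  } else stop("vectorised oracle supports d <= 2")
  out
}

## quadratic form v' Sigma^-1 v for vectors of deviations
qform_vec <- function(dr, v1, v2 = NULL) {
  if (is.null(dr$W12)) dr$W11 * v1^2
  else dr$W11 * v1^2 + 2 * dr$W12 * v1 * v2 + dr$W22 * v2^2
}

## N(x; m, Sigma) log density per draw
ldnorm_vec <- function(dr, d, dev1, dev2 = NULL) {
  -d / 2 * log(2 * pi) - dr$logdetS / 2 - qform_vec(dr, dev1, dev2) / 2
}

## draw a local mean around (m1, m2) with covariance Sigma/kap
rlocal_vec <- function(dr, m1, m2, kap, n) {
  z1 <- stats::rnorm(n)
  if (is.null(dr$L21)) list(l1 = m1 + dr$L11 * z1 / sqrt(kap), l2 = NULL)
  else {
    z2 <- stats::rnorm(n)
    list(l1 = m1 + dr$L11 * z1 / sqrt(kap),
         l2 = m2 + (dr$L21 * z1 + dr$L22 * z2) / sqrt(kap))
  }
}

## MC oracle for any predictive: join = 0 (fresh local cluster) or index of
## the cluster in points_by_cluster; empty points_by_cluster gives the prior
## predictive.  Returns density estimate and standard error.
oracle_mc_vec <- function(x, points_by_cluster, join, hp, ndraws, seed = 42) {
  set.seed(seed)
  d <- hp$d
  dr <- rniw_vec(hp, ndraws)
  logw <- numeric(ndraws)
  for (P in points_by_cluster) {
    n <- nrow(P)
    if (n == 0) next
    xb <- colMeans(P)
    ntil <- n * hp$kappa1 / (n + hp$kappa1)
    Pc <- sweep(P, 2, xb)
    Sw <- crossprod(Pc)
    trterm <- if (d == 1) dr$W11 * Sw[1, 1]
              else dr$W11 * Sw[1, 1] + 2 * dr$W12 * Sw[1, 2] + dr$W22 * Sw[2, 2]
    dev1 <- xb[1] - dr$mu1
    dev2 <- if (d == 2) xb[2] - dr$mu2 else NULL
    logw <- logw - (n * d / 2) * log(2 * pi) - (n / 2) * dr$logdetS +
      (d / 2) * log(hp$kappa1 / (hp$kappa1 + n)) -
      (trterm + ntil * qform_vec(dr, dev1, dev2)) / 2
  }
  if (join == 0) {
    loc <- rlocal_vec(dr, dr$mu1, dr$mu2, hp$kappa1, ndraws)
  } else {
    P <- points_by_cluster[[join]]
    n <- nrow(P)
    xb <- colMeans(P)
    kap <- hp$kappa1 + n
    m1 <- (hp$kappa1 * dr$mu1 + n * xb[1]) / kap
    m2 <- if (d == 2) (hp$kappa1 * dr$mu2 + n * xb[2]) / kap else NULL
    loc <- rlocal_vec(dr, m1, m2, kap, ndraws)
  }
  fx <- exp(ldnorm_vec(dr, d, x[1] - loc$l1,
                       if (d == 2) x[2] - loc$l2 else NULL))
  w <- exp(logw - max(logw))
  est <- sum(w * fx) / sum(w)
  se <- sqrt(sum(w^2 * (fx - est)^2)) / sum(w)
  list(est = est, se = se)
}
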