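test_that("default hyperparameters follow the data-driven rules", {
  b <- list(matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE),
            matrix(c(1, 1), 1, 2))
  hp <- default_hyperparams(b, s = 4, kappa0 = 0.3, kappa1 = 0.7)
  expect_equal(hp$alpha, 1)
  expect_equal(hp$gamma, 1)
  expect_equal(hp$m, 4)                       # d + 2
  expect_equal(hp$mu0, c(1, 1))               # pooled mean over all events
  expect_equal(hp$Sigma0, diag(2) / 4)        # identity / s
  expect_equal(hp$kappa0, 0.3)
  expect_equal(hp$kappa1, 0.7)

  hp3 <- default_hyperparams(list(matrix(0, 2, 3)), s = 4)
  expect_equal(hp3$Sigma0, diag(0.25, 3))

  expect_error(default_hyperparams(list()), "at least one")
  expect_error(default_hyperparams(list(matrix(0, 2, 2), matrix(0, 2, 3))),
               "same number of channels")
  expect_error(aspire_hyper(c(0, 0), diag(2), m = 3, kappa0 = 1, kappa1 = 1),
               "d \\+ 2")
  expect_error(aspire_hyper(c(0, 0), matrix(c(1, 2, 2, 1), 2), m = 4,
                            kappa0 = 1, kappa1 = 1), "positive definite")
  expect_error(aspire_hyper(0, matrix(1), m = 3, kappa0 = 0, kappa1 = 1),
               "kappa0")
})

test_that("sufficient statistics update and invert exactly", {
  s <- suffstats(matrix(c(1, 2), 1, 2))
  expect_equal(s$n, 1L)
  expect_equal(s$sum, c(1, 2))
  expect_equal(s$scatter, matrix(c(1, 2, 2, 4), 2))

  s3 <- suffstats(matrix(c(1, 2, 3), 3, 1))
  expect_equal(s3$n, 3L)
  expect_equal(s3$sum, 6)
  expect_equal(s3$scatter, matrix(14))

  empty <- suffstats(d = 2)
  expect_error(suffstats_update(empty, c(1, 1), "remove"), "empty")

  # add/remove round trip is lossless over many random operations
  set.seed(42)
  base <- suffstats(matrix(rnorm(20), 10, 2))
  st <- base
  pts <- matrix(rnorm(5e4 * 2, sd = 5), ncol = 2)
  for (i in seq_len(nrow(pts))) {
    st <- suffstats_update(st, pts[i, ], "add")
    st <- suffstats_update(st, pts[i, ], "remove")
  }
  expect_equal(st$n, base$n)
  expect_equal(st$sum, base$sum, tolerance = 1e-12)
  expect_equal(st$scatter, base$scatter, tolerance = 1e-12)
})

test_that("predictive densities match the closed-form joint-marginal oracle", {
  set.seed(7)
  for (d in 1:2) {
    for (k1 in c(0.05, 0.4, 3)) {
      hp <- test_hp(d = d, kappa1 = k1)
      pb <- list(matrix(rnorm(4 * d) + 1, 4, d),
                 matrix(rnorm(3 * d) - 2, 3, d))
      cl <- lapply(pb, suffstats)
      x <- rnorm(d)
      # class marginal (both routes)
      expect_equal(class_log_marginal(cl, hp), oracle_class_marginal(pb, hp),
                   tolerance = 1e-9)
      # fresh-cluster predictive within the class
      expect_equal(dstudentt(x, class_predictive(cl, hp)),
                   oracle_predictive(x, pb, 0, hp), tolerance = 1e-9)
      # joining an existing cluster
      expect_equal(local_cluster_predictive(x, cl[[1]], cl[2], hp),
                   oracle_predictive(x, pb, 1, hp), tolerance = 1e-9)
      # prior predictive (empty class)
      expect_equal(prior_predictive(x, hp),
                   oracle_predictive(x, list(), 0, hp), tolerance = 1e-9)
    }
  }
})

test_that("prior predictive is a Student-t centred at mu0", {
  hp <- aspire_hyper(mu0 = 0, Sigma0 = matrix(1), m = 3, kappa0 = 1, kappa1 = 1)
  # the kappa chain collapses: scale (1 + 1/k1 + 1/k0) Sigma0 / dof = 1
  xs <- c(-2.5, -0.3, 0, 0.7, 1.9)
  expect_equal(prior_predictive(xs[3], hp), dt(0, df = 3, log = TRUE))
  for (x in xs)
    expect_equal(prior_predictive(x, hp), dt(x, df = 3, log = TRUE),
                 tolerance = 1e-12)

  hp2 <- test_hp(d = 2)
  # symmetry about mu0 and mode at mu0
  for (delta in list(c(1, 0), c(0.3, -0.7), c(-2, 2)))
    expect_equal(prior_predictive(hp2$mu0 + delta, hp2),
                 prior_predictive(hp2$mu0 - delta, hp2))
  expect_gt(prior_predictive(hp2$mu0, hp2),
            prior_predictive(hp2$mu0 + c(0.5, 0), hp2))
  # definitional identity with the empty-class predictive
  p <- class_predictive(NULL, hp2)
  x <- c(0.4, -1)
  expect_equal(prior_predictive(x, hp2), dstudentt(x, p))
})

test_that("predictive densities integrate to one and behave in the kappa1 limits", {
  hp <- test_hp(d = 1, kappa1 = 0.05)
  cl <- list(suffstats(matrix(c(0.5, 1.2, 0.8), 3, 1)),
             suffstats(matrix(c(-1, -1.4), 2, 1)))
  # quadrature over +-12 posterior scale units
  p <- class_predictive(cl, hp)
  width <- 12 * sqrt(p$scale[1, 1] * p$dof / (p$dof - 2))
  grid <- seq(p$center - width, p$center + width, length.out = 20001)
  int <- sum(dstudentt(matrix(grid), p, log = FALSE)) * diff(grid[1:2])
  expect_equal(int, 1, tolerance = 1e-3)
  intl <- sum(exp(vapply(grid, local_cluster_predictive, numeric(1),
                         cluster_stats = cl[[1]], class_stats_excl = cl[2],
                         hp = hp))) * diff(grid[1:2])
  expect_equal(intl, 1, tolerance = 1e-3)

  # kappa1 -> infinity: joining a cluster collapses to the plain NIW
  # predictive of the pooled class data (no random effects)
  hpinf <- test_hp(d = 2, kappa1 = 1e8)
  pb <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(6) + 2, 3, 2))
  cl2 <- lapply(pb, suffstats)
  pooled <- suffstats(do.call(rbind, pb))
  x <- c(0.3, 0.5)
  expect_equal(local_cluster_predictive(x, cl2[[1]], cl2[2], hpinf),
               dstudentt(x, class_predictive(list(pooled), hpinf)),
               tolerance = 1e-6)

  # monotone effect of kappa1: a point far from the cluster mean but near
  # the class posterior mean gains density as random effects shrink
  hpgrid <- c(0.05, 0.2, 1, 5, 50)
  clf <- list(suffstats(matrix(c(4, 4.4, 3.8, 4.1), 4, 1)))
  ctx <- list(suffstats(matrix(rnorm(30, 0, 1), 30, 1)))
  vals <- vapply(hpgrid, function(k1)
    local_cluster_predictive(0.1, clf[[1]], ctx, test_hp(d = 1, kappa1 = k1)),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("predictives agree with Monte-Carlo integration of the hierarchy", {
  # moderate draw counts here; the full 1e6-draw suite runs in the
  # acceptance tests
  hp <- test_hp(d = 1, kappa1 = 0.05)
  pb <- list(matrix(c(0.6, 1.1, 0.9, 1.4, 0.8), 5, 1))
  for (x in c(0.2, 1.0, 2.5)) {
    mc <- oracle_mc_vec(x, pb, 0, hp, ndraws = 2e5)
    expect_lt(abs(exp(dstudentt(x, class_predictive(lapply(pb, suffstats), hp))) -
                  mc$est), 3 * mc$se)
  }
  mcp <- oracle_mc_vec(0.7, list(), 0, hp, ndraws = 2e5)
  expect_lt(abs(exp(prior_predictive(0.7, hp)) - mcp$est), 3 * mcp$se)
})

test_that("joint set likelihood obeys the chain rule and exchangeability", {
  set.seed(11)
  hp <- test_hp(d = 2, kappa1 = 0.3)
  ctx <- list(suffstats(matrix(rnorm(10), 5, 2)))
  x <- c(0.2, -0.4)
  # singleton set equals the one-point class predictive
  expect_equal(joint_set_log_likelihood(x, ctx, hp),
               dstudentt(x, class_predictive(ctx, hp)))
  set4 <- matrix(rnorm(8), 4, 2)
  j0 <- joint_set_log_likelihood(set4, ctx, hp)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2)))
    expect_equal(joint_set_log_likelihood(set4[perm, ], ctx, hp), j0,
                 tolerance = 1e-9)
  # equals the difference of closed-form class marginals
  aug <- c(ctx, list(suffstats(set4)))
  expect_equal(j0, class_log_marginal(aug, hp) - class_log_marginal(ctx, hp),
               tolerance = 1e-9)
  # brute-force oracle on 4 points with empty context
  j1 <- joint_set_log_likelihood(set4, NULL, hp)
  expect_equal(j1, oracle_class_marginal(list(set4), hp), tolerance = 1e-9)
  expect_error(joint_set_log_likelihood(matrix(0, 0, 2), ctx, hp), "non-empty")
})

test_that("degenerate inputs are regularised by the prior, errors are clear", {
  hp <- test_hp(d = 2)
  dup <- suffstats(matrix(rep(c(1, 1), 5), 5, 2, byrow = TRUE))
  # duplicate points give a rank-deficient scatter; the IW prior keeps the
  # posterior proper
  expect_true(is.finite(class_log_marginal(list(dup), hp)))
  expect_true(is.finite(dstudentt(c(1, 1), class_predictive(list(dup), hp))))
  expect_error(local_cluster_predictive(c(0, 0), suffstats(d = 2), NULL, hp),
               "non-empty")
})
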