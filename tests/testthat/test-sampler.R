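test_that("gibbs schedule is validated and defaults to 1000/750/50/5", {
  ctrl <- aspire_control()
  expect_equal(ctrl$n_sweeps, 1000L)
  expect_equal(ctrl$burn_in, 750L)
  expect_equal(ctrl$thin, 50L)
  expect_equal(ctrl$n_saved, 5L)
  expect_error(aspire_control(n_sweeps = 100, burn_in = 100), "burn_in")
  expect_error(aspire_control(n_sweeps = 100, burn_in = 50, thin = 20,
                              n_saved = 5), "infeasible")
})

test_that("fits are deterministic given the seed and recover separated blobs", {
  b <- make_blob_batch(J = 3, seed = 4)
  f1 <- aspire(b, kappa1 = 5, control = fast_control(seed = 9))
  f2 <- aspire(b, kappa1 = 5, control = fast_control(seed = 9))
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$trace, f2$trace)
  f3 <- aspire(b, kappa1 = 5, control = fast_control(seed = 10))
  expect_false(identical(f3$trace$log_likelihood, f1$trace$log_likelihood))

  # 10-sigma separation: exactly two global clusters, split along the truth
  expect_equal(n_clusters(prune_small_clusters(f1)), 2)
  truth <- rep(rep(1:2, each = 60), 3)
  expect_gt(adjusted_rand(unlist(f1$labels), truth), 0.99)
})

test_that("state bookkeeping is exact: C++ likelihood equals the R closed form", {
  b <- make_blob_batch(J = 2, n_per_blob = 40, seed = 6)
  fit <- aspire(b, kappa1 = 0.3, control = fast_control(seed = 3, n_sweeps = 100,
                                                        burn_in = 50, thin = 10))
  tl <- fit$final_state$cluster_labels
  cl <- fit$final_state$class_labels
  pooled <- do.call(rbind, fit$batch)
  llr <- 0
  for (k in unique(cl)) {
    cls <- lapply(unique(tl[cl == k]), function(t)
      suffstats(pooled[tl == t & cl == k, , drop = FALSE]))
    llr <- llr + class_log_marginal(cls, fit$hyper)
  }
  expect_equal(llr, tail(fit$trace$log_likelihood, 1), tolerance = 1e-8)
  # count conservation
  expect_equal(length(unlist(fit$labels)), sum(vapply(b, nrow, integer(1))))
  for (j in seq_along(b)) expect_equal(length(fit$labels[[j]]), nrow(b[[j]]))
})

test_that("degenerate priors and degenerate batches behave as forced", {
  # a single event: one cluster, one class
  one <- list(matrix(c(0.5, 0.5), 1, 2))
  f <- aspire(one, kappa1 = 1, control = fast_control(n_sweeps = 20,
                                                      burn_in = 10, thin = 2))
  expect_equal(n_clusters(f), 1)
  expect_equal(unlist(f$labels), 1, ignore_attr = TRUE)

  # alpha = 0: no new local clusters can open after initialisation
  b <- make_blob_batch(J = 1, n_per_blob = 30, centers = list(c(0, 0)), seed = 2)
  hp <- default_hyperparams(b, kappa1 = 1)
  hp$alpha <- 0
  fa <- aspire(b, hyper = hp, control = fast_control(n_sweeps = 30, burn_in = 10,
                                                     thin = 4))
  expect_equal(max(unlist(fa$labels)), 1)
})

test_that("the strict event loop stays within the current class", {
  b <- make_blob_batch(J = 2, n_per_blob = 30, seed = 8)
  ctrl <- fast_control(seed = 5, n_sweeps = 40, burn_in = 20, thin = 4)
  ctrl$strict_t_loop <- TRUE
  f <- aspire(b, kappa1 = 0.5, control = ctrl)
  # still a valid state with full label coverage
  expect_equal(length(unlist(f$labels)), 120)
  expect_true(all(unlist(f$labels) >= 1))
})

test_that("single-sample partition frequencies match exhaustive enumeration", {
  # scaled-down version of the exactness check (the full 1e5-sweep run is in
  # the acceptance suite): total-variation comparison on 5 events
  set.seed(5)
  X <- matrix(c(-1.2, 0.3, 1.1, 2.0, -0.4, 0.8, -1.5, 0.2, 1.9, -0.7), 5, 2)
  hp <- test_hp(d = 2, kappa0 = 0.5, kappa1 = 0.4)
  law <- aspire_partition_law(X, hp)
  set.seed(77)
  raw <- aspire:::.cpp_aspire_gibbs(list(X), unclass(hp), 20000, 2000, 1, 1,
                                    "crp", FALSE, TRUE)
  emp <- table(raw$partition_t[-(1:2000)]) / (20000 - 2000)
  f <- as.numeric(emp[names(law)])
  f[is.na(f)] <- 0
  tv <- sum(abs(f - law)) / 2
  expect_lt(tv, 0.02)
})

test_that("pooled DPGMM matches its own exhaustive partition law and merges under tiny alpha", {
  set.seed(9)
  X <- matrix(c(-1.0, 0.2, 1.3, 0.6, -0.5), 5, 1)
  hp <- test_hp(d = 1, kappa0 = 0.8, kappa1 = 1)
  law <- dpgmm_partition_law(X, hp)
  set.seed(21)
  raw <- aspire:::.cpp_dpgmm_gibbs(X, unclass(hp), 40000, 4000, 1, 1, TRUE)
  emp <- table(raw$partition_t[-(1:4000)]) / (40000 - 4000)
  f <- as.numeric(emp[names(law)])
  f[is.na(f)] <- 0
  expect_lt(sum(abs(f - law)) / 2, 0.02)

  # two pooled well-separated blobs -> 2 clusters
  b <- make_blob_batch(J = 2, n_per_blob = 50, seed = 3)
  fd <- dpgmm(b, control = fast_control(seed = 2))
  expect_equal(n_clusters(prune_small_clusters(fd)), 2)

  # alpha ~ 0 forces a single cluster on a unimodal blob
  b1 <- list(matrix(rnorm(200), 100, 2))
  hp1 <- default_hyperparams(b1)
  hp1$alpha <- 1e-9
  f1 <- dpgmm(b1, hyper = hp1, control = fast_control(seed = 2, n_sweeps = 40,
                                                      burn_in = 20, thin = 4))
  expect_equal(n_clusters(f1), 1)
})

test_that("label alignment and consensus follow mode with last-draw ties", {
  # identical draws up to permutation: consensus equals draw 1
  d1 <- c(1, 1, 2, 2, 3)
  d2 <- c(2, 2, 3, 3, 1)  # same partition, permuted labels
  expect_equal(relabel_and_consensus(list(d1, d2)), d1)
  expect_equal(relabel_and_consensus(list(d1)), d1)
  # mode across aligned draws
  d3 <- c(1, 1, 2, 2, 2)  # event 5 disagrees
  expect_equal(relabel_and_consensus(list(d1, d1, d3))[5], 3)
  # tie broken towards the last draw
  expect_equal(relabel_and_consensus(list(d1, d3))[5], 2)
  expect_error(relabel_and_consensus(list()), "no saved draws")
})

test_that("small-cluster pruning drops classes under the size threshold", {
  b <- make_blob_batch(J = 2, n_per_blob = 50, seed = 13)
  fit <- aspire(b, kappa1 = 0.5, control = fast_control(seed = 4))
  expect_equal(n_clusters(prune_small_clusters(fit, 0)), n_clusters(fit))
  expect_error(prune_small_clusters(fit, 1), "threshold")

  # synthetic count check: sizes {900, 96, 4} of 1000 at the 0.5% default
  fake <- fit
  fake$summaries_all <- NULL
  fake$summaries <- lapply(seq_len(3), function(k)
    list(class_id = k, mean = c(0, 0), covariance = diag(2),
         total_count = c(900, 96, 4)[k], per_sample_counts = c(900, 96, 4)[k]))
  fake$batch <- list(matrix(0, 1000, 2))
  pr <- prune_small_clusters(fake, 0.005)
  expect_equal(n_clusters(pr), 2)
  expect_equal(pr$pruned, c(FALSE, FALSE, TRUE))
})

test_that("kappa1 selection returns the grid argmax of the Gibbs likelihood", {
  b <- make_blob_batch(J = 2, n_per_blob = 30, seed = 17)
  res <- select_kappa1(b, grid = 0.25, control = fast_control(n_sweeps = 30,
                                                              burn_in = 15,
                                                              thin = 3))
  expect_equal(res$kappa1, 0.25)              # grid of one returns that value
  expect_equal(nrow(res$scores), 1)
  res2 <- select_kappa1(b, grid = c(0.1, 1), control = fast_control(
    n_sweeps = 40, burn_in = 20, thin = 4))
  expect_equal(res2$kappa1,
               res2$scores$kappa1[which.max(res2$scores$log_likelihood)])
  expect_error(select_kappa1(b, grid = numeric(0)), "non-empty")
})

test_that("model methods: print, summary, coef, logLik, predict, simulate", {
  b <- make_blob_batch(J = 2, n_per_blob = 40, seed = 19)
  fit <- aspire(b, kappa1 = 0.5, control = fast_control(seed = 6))
  expect_output(print(fit), "global clusters")
  s <- summary(fit)
  expect_s3_class(s, "summary.aspire")
  expect_equal(s$K, n_clusters(fit))
  co <- coef(fit)
  expect_length(co$means, n_clusters(fit))
  expect_true(all(vapply(co$covariances, function(S)
    all(eigen(S, TRUE, TRUE)$values > 0), logical(1))))
  expect_s3_class(logLik(fit), "logLik")

  # prediction assigns new points near a centre to that centre's class
  mu1 <- fit$summaries[[1]]$mean
  pred <- predict(fit, rbind(mu1, mu1 + 0.1))
  expect_equal(pred, c(1, 1))

  sim <- simulate(fit, nsim = 2, seed = 3, n_per_sample = 50)
  expect_length(sim$batch, 2)
  expect_equal(nrow(sim$batch[[1]]), 50)
})

test_that("Gibbs likelihood selects small kappa1 under strong random effects", {
  # batches generated with kappa1 = 0.05 (strong per-sample mean shifts)
  gp <- list(means = list(c(0, 0), c(14, 0), c(0, 14)),
             covs = rep(list(diag(2)), 3))
  hp0 <- test_hp(d = 2, kappa0 = 0.01, kappa1 = 0.05)
  sel <- vapply(1:10, function(s) {
    sim <- simulate_from_model(K = 3, J = 8, n_per_sample = 250, hp = hp0,
                               seed = 300 + s, global_params = gp)
    select_kappa1(sim$batch,
                  control = aspire_control(n_sweeps = 150, burn_in = 100,
                                           thin = 10, n_saved = 5,
                                           seed = 700 + s))$kappa1
  }, numeric(1))
  expect_gte(sum(sel <= 0.25), 8)
})
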