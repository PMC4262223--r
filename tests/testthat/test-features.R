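test_that("cluster proportions renormalise over surviving classes", {
  b <- make_blob_batch(J = 2, n_per_blob = 50, seed = 23)
  fit <- aspire(b, kappa1 = 0.5, control = fast_control(seed = 7))
  p <- cluster_proportions(fit, prune_threshold = 0)
  expect_equal(unname(rowSums(p)), rep(1, 2))
  expect_true(all(p >= 0 & p <= 1))

  # single class: row of 1.0
  one <- list(matrix(rnorm(60), 30, 2))
  f1 <- aspire(one, kappa1 = 1, control = fast_control(n_sweeps = 30,
                                                       burn_in = 15, thin = 3))
  if (n_clusters(f1) == 1)
    expect_equal(as.numeric(cluster_proportions(f1, 0)), 1)

  # synthetic counts (900, 96, 4): the 0.5% rule drops the third class and
  # rows renormalise to (900, 96)/996
  fake <- fit
  fake$labels <- list(s1 = rep(1:3, c(900, 96, 4)))
  fake$batch <- list(s1 = matrix(0, 1000, 2))
  pr <- cluster_proportions(fake, prune_threshold = 0.005)
  expect_equal(as.numeric(pr), c(900 / 996, 96 / 996))
  # counts (50, 50): equal proportions
  fake$labels <- list(s1 = rep(1:2, each = 50))
  fake$batch <- list(s1 = matrix(0, 100, 2))
  expect_equal(as.numeric(cluster_proportions(fake, 0)), c(0.5, 0.5))
})

test_that("uniform simplex sampling is Dirichlet(1, ..., 1)", {
  expect_equal(formals(sample_uniform_simplex)$N, 50000)
  expect_equal(sample_uniform_simplex(1, 10), matrix(1, 10, 1))
  x <- sample_uniform_simplex(3, 1e5, seed = 3)
  expect_equal(unname(rowSums(x)), rep(1, 1e5), tolerance = 1e-12)
  # column means ~ 1/3 with known Dirichlet variance 2/9/N... sd = sqrt(1/18/N)
  se <- sqrt(1 / 3 * 2 / 3 / 4) / sqrt(1e5)
  expect_true(all(abs(colMeans(x) - 1 / 3) < 3 * se))
  # marginals are Beta(1, K - 1)
  ks <- suppressWarnings(stats::ks.test(x[, 1], stats::pbeta, 1, 2))
  expect_gt(ks$p.value, 0.01)
  # identical seeds reproduce
  expect_identical(x, sample_uniform_simplex(3, 1e5, seed = 3))
})

test_that("Mann-Whitney AUC counts ties as one half and checks inputs", {
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mann_whitney(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # pairs: (3>1), (3>2), (2>1), (2=2 -> 1/2) => 3.5/4
  expect_equal(auc_mann_whitney(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               0.875)
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)), "undefined")
  # invariance under strictly monotone transforms
  set.seed(31)
  sc <- rnorm(40)
  fl <- rep(c(TRUE, FALSE), 20)
  a0 <- auc_mann_whitney(sc, fl)
  expect_equal(auc_mann_whitney(exp(sc), fl), a0)
  expect_equal(auc_mann_whitney(rank(sc), fl), a0)
  # agreement with an established implementation
  skip_if_not_installed("pROC")
  pr <- as.numeric(pROC::auc(pROC::roc(fl, sc, direction = "<", quiet = TRUE)))
  expect_equal(a0, pr)
})

test_that("one-class training separates a vertex from the uniform cloud", {
  set.seed(41)
  # negatives concentrated near a vertex of the 4-simplex
  neg <- sample_uniform_simplex(4, 12, seed = 2) * 0.08
  neg[, 1] <- 0
  neg[, 1] <- 1 - rowSums(neg)
  oc <- train_one_class(neg, n_positive = 4000, seed = 5,
                        n_tune_positive = 1000)
  pos_test <- sample_uniform_simplex(4, 500, seed = 99)
  sneg <- predict(oc, neg)
  spos <- predict(oc, pos_test)
  expect_lt(max(sneg), stats::median(spos))
  # affine decision function: weights/bias reproduce the svm scores
  expect_equal(unname(drop(pos_test %*% oc$weights + oc$bias)),
               unname(spos), tolerance = 1e-8)

  # cost grid of one value is chosen as-is; same seed reproduces weights
  oc1 <- train_one_class(neg, n_positive = 1000, cost_grid = 7, seed = 3)
  expect_equal(oc1$cost, 7)
  oc2 <- train_one_class(neg, n_positive = 1000, cost_grid = 7, seed = 3)
  expect_equal(oc1$weights, oc2$weights, tolerance = 1e-10)

  expect_error(train_one_class(neg[1, , drop = FALSE]), "at least 2")
  expect_warning(train_one_class(neg[c(1, 1), ], n_positive = 500,
                                 cost_grid = 1, seed = 1), "identical")
})

test_that("score_and_auc reports oriented scores", {
  neg <- sample_uniform_simplex(3, 10, seed = 7) * 0.05
  neg[, 1] <- 1 - rowSums(neg[, -1, drop = FALSE])
  oc <- train_one_class(neg, n_positive = 2000, cost_grid = 1, seed = 2)
  test <- rbind(neg[1:3, ], sample_uniform_simplex(3, 3, seed = 8))
  res <- score_and_auc(oc, test, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_length(res$scores, 6)
  expect_equal(res$auc, 1)
})

test_that("compositional PCA separates compositional groups and validates input", {
  # clr rows sum to zero before projection
  set.seed(51)
  p <- sample_uniform_simplex(4, 20, seed = 3)
  clr <- log(p) - rowMeans(log(p))
  expect_equal(unname(rowSums(clr)), rep(0, 20), tolerance = 1e-9)

  expect_error(clr_pca_2d(p[, 1:2]), "at least 3")

  # identical rows map to identical coordinates
  pp <- rbind(p, p[1, ], p[1, ])
  co <- clr_pca_2d(pp)
  expect_equal(co[21, ], co[22, ], ignore_attr = TRUE)

  # two compositional clusters are recovered by 2-means on the coordinates
  g1 <- matrix(c(0.7, 0.2, 0.05, 0.05), 20, 4, byrow = TRUE) +
    matrix(runif(4 * 20, 0, 0.02), 20, 4)
  g2 <- matrix(c(0.05, 0.05, 0.2, 0.7), 20, 4, byrow = TRUE) +
    matrix(runif(4 * 20, 0, 0.02), 20, 4)
  feats <- rbind(g1, g2)
  feats <- feats / rowSums(feats)
  coords <- clr_pca_2d(feats)
  km <- stats::kmeans(coords, 2, nstart = 10)
  expect_gt(adjusted_rand(km$cluster, rep(1:2, each = 20)), 0.9)

  # zeros handled by multiplicative replacement
  pz <- p
  pz[1, 1] <- 0
  pz[1, ] <- pz[1, ] / sum(pz[1, ])
  expect_true(all(is.finite(clr_pca_2d(pz))))
})

test_that("supervised classification is seeded and near chance under shuffling", {
  set.seed(61)
  f1 <- matrix(c(0.8, 0.15, 0.05), 50, 3, byrow = TRUE) +
    matrix(runif(150, 0, 0.02), 50, 3)
  f2 <- matrix(c(0.2, 0.15, 0.65), 50, 3, byrow = TRUE) +
    matrix(runif(150, 0, 0.02), 50, 3)
  feats <- rbind(f1, f2)
  feats <- feats / rowSums(feats)
  labs <- rep(c(FALSE, TRUE), each = 50)
  res <- supervised_classify(feats, labs, seed = 5, n_rep = 5)
  expect_equal(res$accuracy, 1)            # perfectly separable
  res2 <- supervised_classify(feats, labs, seed = 5, n_rep = 5)
  expect_identical(res$per_rep, res2$per_rep)

  shuf <- sample(labs)
  res3 <- supervised_classify(feats, shuf, seed = 7, n_rep = 10)
  expect_lt(abs(res3$accuracy - 0.5), 0.1)  # prevalence baseline 0.5
  expect_error(supervised_classify(feats, rep(TRUE, 100)), "both classes")
})
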