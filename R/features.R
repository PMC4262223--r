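#' Per-sample global-cluster proportion features
#'
#' Characterises each sample by the vector of proportions of its events in
#' the recovered global clusters — the compositional feature vector used for
#' anomaly detection. Classes holding (strictly) less than `prune_threshold`
#' of all events are excluded and each row is renormalised over the
#' surviving classes.
#'
#' @param fit A fitted `"aspire"` object.
#' @param prune_threshold Fraction in `[0, 1)`; classes below it are
#'   excluded (0 keeps everything).
#' @return A `J x K` matrix of class `"aspire_proportions"`; rows (samples)
#'   sum to 1. Attribute `n_events` carries each sample's surviving event
#'   count (used for zero replacement in [clr_pca_2d()]).
#' @export
cluster_proportions <- function(fit, prune_threshold = 0.005) {
  stopifnot(inherits(fit, "aspire"))
  if (prune_threshold < 0 || prune_threshold >= 1)
    stop("'prune_threshold' must be in [0, 1)")
  counts <- t(vapply(fit$labels, function(l)
    tabulate(l, nbins = max(unlist(fit$labels))), numeric(max(unlist(fit$labels)))))
  total <- sum(counts)
  keep <- colSums(counts) >= prune_threshold * total & colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  surv <- rowSums(counts)
  if (any(surv == 0))
    stop("sample(s) with no events in surviving clusters: ",
         paste(names(fit$labels)[surv == 0], collapse = ", "))
  p <- counts / surv
  dimnames(p) <- list(names(fit$labels), paste0("class", which(keep)))
  structure(p, n_events = surv, class = c("aspire_proportions", class(p)))
}

#' Uniform samples from the probability simplex
#'
#' Draws `N` vectors uniformly from the `K-1` simplex, i.e. from a
#' `Dirichlet(1, ..., 1)` distribution — the synthetic "positive"
#' (anomalous-like) class of the one-class classifier. Generated as
#' normalised standard-exponential variates.
#'
#' @param K Number of parts (clusters).
#' @param N Number of draws (the one-class training default is 50000).
#' @param seed Integer seed.
#' @return An `N x K` matrix; rows sum to 1.
#' @export
sample_uniform_simplex <- function(K, N = 50000, seed = 1L) {
  stopifnot(K >= 1, N >= 1)
  set.seed(seed)
  g <- matrix(stats::rexp(N * K), N, K)
  g / rowSums(g)
}

#' Train the one-class anomaly detector by simplex resampling
#'
#' One-class classification by resampling: a large set of vectors drawn
#' uniformly from the proportion simplex serves as the "positive"
#' (potentially anomalous) class and the normal samples' proportion vectors
#' as the "negative" class; a binary linear-kernel support-vector machine is
#' trained to separate them. The SVM cost parameter is tuned on a held-out
#' fraction of the training data (by held-out AUC by default). Scores are
#' oriented so that larger means more anomalous.
#'
#' @param normal_features Proportion matrix of the normal samples
#'   (rows = samples), e.g. from [cluster_proportions()].
#' @param n_positive Number of uniform simplex draws.
#' @param cost_grid Candidate SVM cost values.
#' @param holdout_fraction Fraction of the training data held out for cost
#'   selection.
#' @param seed Integer seed (simplex draws and holdout split).
#' @param tune_metric Held-out score used to pick the cost.
#' @param n_tune_positive Number of positives used during cost tuning
#'   (subsampled for speed; the final model is refit on all positives).
#' @return An object of class `"aspire_oneclass"`: the fitted SVM, the
#'   selected cost, the linear weights/bias, and the score orientation.
#' @export
train_one_class <- function(normal_features, n_positive = 50000,
                            cost_grid = c(0.01, 0.1, 1, 10, 100),
                            holdout_fraction = 0.25, seed = 1L,
                            tune_metric = c("auc", "accuracy"),
                            n_tune_positive = 5000) {
  tune_metric <- match.arg(tune_metric)
  neg <- as.matrix(normal_features)
  if (nrow(neg) < 2) stop("need at least 2 normal samples")
  K <- ncol(neg)
  if (nrow(unique(neg)) == 1)
    warning("all normal feature vectors are identical; model may be degenerate")
  pos <- sample_uniform_simplex(K, n_positive, seed = seed)
  set.seed(seed + 1L)
  cost <- cost_grid[1]
  if (length(cost_grid) > 1) {
    ptune <- pos[sample.int(n_positive, min(n_tune_positive, n_positive)), ,
                 drop = FALSE]
    vp <- sample.int(nrow(ptune), max(1, round(holdout_fraction * nrow(ptune))))
    vn <- sample.int(nrow(neg), max(1, round(holdout_fraction * nrow(neg))))
    if (length(vn) >= nrow(neg)) vn <- 1L  # keep at least one negative in train
    scores <- vapply(cost_grid, function(cc) {
      m <- fit_linear_svm(ptune[-vp, , drop = FALSE], neg[-vn, , drop = FALSE], cc)
      sc <- svm_scores(m, rbind(ptune[vp, , drop = FALSE],
                                neg[vn, , drop = FALSE]))
      truth <- rep(c(TRUE, FALSE), c(length(vp), length(vn)))
      if (tune_metric == "auc") auc_mann_whitney(sc, truth)
      else mean((sc > 0) == truth)
    }, numeric(1))
    # with few negatives the validation score often ties across the whole
    # grid (every uniform positive outranks every held-out normal); among
    # tied costs fall back to the one closest to the default cost 1, so
    # selection departs from the default only when validation justifies it
    tied <- which(scores >= max(scores) - 1e-12)
    cost <- cost_grid[tied[which.min(abs(log(cost_grid[tied])))]]
  }
  final <- fit_linear_svm(pos, neg, cost)
  w <- drop(t(final$fit$coefs) %*% final$fit$SV) * final$sign
  b <- -final$fit$rho * final$sign
  structure(list(svm = final, cost = cost, weights = w, bias = b,
                 n_positive = n_positive, train_seed = seed, K = K),
            class = "aspire_oneclass")
}

## linear SVM with positive/negative design; returns fit plus the sign that
## orients decision values as "higher = more positive-like".  The classes are
## weighted inversely to their sizes: with tens of thousands of resampled
## positives against a handful of normal samples an unweighted hinge loss
## simply ignores the negatives.
fit_linear_svm <- function(pos, neg, cost) {
  x <- rbind(pos, neg)
  y <- factor(rep(c("positive", "negative"), c(nrow(pos), nrow(neg))),
              levels = c("positive", "negative"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = c(positive = 1,
                                      negative = nrow(pos) / nrow(neg)))
  dv <- drop(attr(stats::predict(fit, x[c(1, nrow(x)), , drop = FALSE],
                                 decision.values = TRUE), "decision.values"))
  # orient: first row is a positive, last a negative
  sgn <- if (dv[1] >= dv[2]) 1 else -1
  list(fit = fit, sign = sgn)
}

svm_scores <- function(model, x) {
  dv <- attr(stats::predict(model$fit, as.matrix(x), decision.values = TRUE),
             "decision.values")
  drop(dv) * model$sign
}

#' @export
print.aspire_oneclass <- function(x, ...) {
  cat("One-class linear SVM (simplex resampling)\n")
  cat(sprintf("  K = %d clusters, %d positives, cost = %g\n",
              x$K, x$n_positive, x$cost))
  invisible(x)
}

#' Anomaly scores for new samples
#'
#' @param object An `"aspire_oneclass"` model.
#' @param newdata Proportion matrix (rows = samples) over the same clusters.
#' @param ... Unused.
#' @return Numeric scores; larger means more anomalous.
#' @export
predict.aspire_oneclass <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$K)
    stop("feature dimension mismatch: model has K = ", object$K)
  stats::setNames(svm_scores(object$svm, newdata), rownames(newdata))
}

#' Score samples and compute the ROC AUC
#'
#' @param model An `"aspire_oneclass"` model.
#' @param test_features Proportion matrix of the test samples.
#' @param anomaly_flags Logical (or 0/1) vector aligned with the rows of
#'   `test_features`; `TRUE` = anomalous.
#' @return A list with `scores` and `auc`.
#' @export
score_and_auc <- function(model, test_features, anomaly_flags) {
  scores <- predict(model, test_features)
  list(scores = scores, auc = auc_mann_whitney(scores, anomaly_flags))
}

#' Area under the ROC curve (Mann-Whitney rank statistic)
#'
#' The probability that a randomly chosen anomalous sample scores higher
#' than a randomly chosen normal one, with ties counted 1/2; computed from
#' mid-ranks.
#'
#' @param scores Numeric scores (higher = more anomalous).
#' @param anomalous Logical (or 0/1) vector; `TRUE` = anomalous.
#' @return The AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, anomalous) {
  anomalous <- as.logical(anomalous)
  if (length(scores) != length(anomalous))
    stop("'scores' and 'anomalous' lengths differ")
  n1 <- sum(anomalous)
  n0 <- sum(!anomalous)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: need both anomalous and normal samples")
  r <- rank(scores)  # mid-ranks: ties count 1/2
  (sum(r[anomalous]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Supervised classification of samples from proportion features
#'
#' The fully supervised variant: with both normal and anomalous samples
#' labelled, a linear-kernel SVM is trained on the proportion vectors of a
#' training split and its accuracy evaluated on the held-out split,
#' repeated `n_rep` times with different seeded splits (mean and standard
#' deviation reported).
#'
#' @param features Proportion matrix (rows = samples).
#' @param labels Logical (or 0/1) vector; `TRUE` = anomalous.
#' @param train_fraction Fraction of samples in each training split
#'   (stratified by class).
#' @param seed Integer seed; repetition `r` uses `seed + r - 1`.
#' @param n_rep Number of repetitions.
#' @param cost SVM cost.
#' @return A list with `accuracy` (mean), `sd`, and `per_rep` (data frame).
#' @export
supervised_classify <- function(features, labels, train_fraction = 0.7,
                                seed = 1L, n_rep = 10, cost = 1) {
  x <- as.matrix(features)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("supervised classification needs both classes")
  acc <- vapply(seq_len(n_rep), function(r) {
    set.seed(seed + r - 1L)
    tr <- unlist(lapply(split(seq_along(labels), labels), function(idx)
      sample(idx, max(1, round(train_fraction * length(idx))))))
    if (length(unique(labels[tr])) < 2 || length(tr) >= length(labels))
      stop("degenerate split: training set lacks a class or test set is empty")
    y <- factor(labels[tr], levels = c(FALSE, TRUE))
    fit <- e1071::svm(x[tr, , drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, x[-tr, , drop = FALSE])
    mean(pred == factor(labels[-tr], levels = c(FALSE, TRUE)))
  }, numeric(1))
  list(accuracy = mean(acc), sd = stats::sd(acc),
       per_rep = data.frame(rep = seq_len(n_rep), accuracy = acc))
}
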