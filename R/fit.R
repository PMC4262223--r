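#' Gibbs sampler schedule
#'
#' Default schedule: 1000 sweeps, the first 750 discarded as burn-in, and
#' five posterior draws saved, one every 50 sweeps thereafter. The saved
#' draws feed the label-switching resolution and the consensus (modal)
#' labelling.
#'
#' @param n_sweeps Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before any draw is saved
#'   (`burn_in < n_sweeps`).
#' @param thin Gap between saved draws.
#' @param n_saved Number of saved draws (`n_saved * thin <= n_sweeps -
#'   burn_in`).
#' @param seed Integer seed; the entire run is reproducible given the seed.
#' @param init Initialisation. `"dpgmm"` (default) warm-starts by fitting a
#'   plain DP Gaussian mixture within each sample and then coalescing the
#'   resulting local clusters into classes — this seeds whole, coherent
#'   local clusters and avoids a metastable fragmented mode that incremental
#'   Gibbs cannot escape when random effects are strong. `"crp"` seeds
#'   assignments sequentially from the predictive probabilities; `"single"`
#'   starts from one local cluster per sample in a single class.
#' @param strict_t_loop If `TRUE`, the event loop only proposes local
#'   clusters of the event's current class (a literal reading of the
#'   assignment rule, kept for comparison; it cannot move single events
#'   between classes and is not ergodic on its own).
#' @param trace_partitions Record the canonical event partition after every
#'   sweep (only sensible for very small problems; used by the exactness
#'   tests).
#' @return A validated list of class `"aspire_control"`.
#' @export
aspire_control <- function(n_sweeps = 1000, burn_in = 750, thin = 50,
                           n_saved = 5, seed = 1L,
                           init = c("dpgmm", "crp", "single"),
                           strict_t_loop = FALSE, trace_partitions = FALSE) {
  init <- match.arg(init)
  if (burn_in >= n_sweeps) stop("'burn_in' must be smaller than 'n_sweeps'")
  if (n_saved < 1 || thin < 1) stop("'n_saved' and 'thin' must be >= 1")
  if (n_saved * thin > n_sweeps - burn_in)
    stop("schedule infeasible: n_saved * thin > n_sweeps - burn_in")
  structure(list(n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_saved = as.integer(n_saved), seed = as.integer(seed),
                 init = init, strict_t_loop = isTRUE(strict_t_loop),
                 trace_partitions = isTRUE(trace_partitions)),
            class = "aspire_control")
}

#' Fit the hierarchical random-effects mixture to a batch of samples
#'
#' Jointly clusters the events of every sample and matches the discovered
#' local clusters across samples into global clusters (meta-clusters),
#' modelling the sample-to-sample displacement of local cluster means as
#' Gaussian random effects scaled by `kappa1`. Inference is a collapsed
#' Gibbs sampler alternating (i) a loop reassigning every event to a local
#' cluster of its sample and (ii) a loop reassigning every local cluster to
#' a global class, both under Chinese-restaurant-franchise priors with all
#' Gaussian parameters integrated out analytically.
#'
#' After the run, the class labels of the saved draws are aligned by greedy
#' maximum-overlap matching to resolve label switching, and each event
#' receives the modal label across the aligned draws. Per-class posterior
#' mean and covariance estimates are computed from the consensus labelling.
#'
#' @param x A batch: list of numeric event matrices (rows = cells, columns =
#'   channels), or a single matrix.
#' @param kappa1 Random-effects scaling used when `hyper` is `NULL`; smaller
#'   values allow larger sample-to-sample displacement of cluster means.
#'   See [select_kappa1()] for data-driven selection.
#' @param hyper An [aspire_hyper()] object, or `NULL` for
#'   [default_hyperparams()].
#' @param control An [aspire_control()] schedule.
#' @param gibbs_likelihood How to report the Gibbs likelihood (joint
#'   sampling likelihood of all events given their assignments):
#'   `"averaged"` over saved draws (default) or at the `"final"` state.
#'
#' @return An object of class `"aspire"` with elements `labels` (per-sample
#'   list of consensus global-cluster labels, 1..K sorted by descending
#'   cluster size), `summaries` (per-class list: `class_id`, `mean`,
#'   `covariance`, `total_count`, `per_sample_counts`), `saved_draws`,
#'   `logLik`, `trace` (per-sweep class count and log likelihood), `hyper`,
#'   `control`, and the input `batch`.
#' @examples
#' set.seed(1)
#' b <- lapply(1:3, function(j) rbind(matrix(rnorm(60), 30, 2),
#'                                    matrix(rnorm(60, 6), 30, 2)))
#' fit <- aspire(b, kappa1 = 0.5,
#'               control = aspire_control(n_sweeps = 60, burn_in = 30,
#'                                        thin = 5, n_saved = 5, seed = 7))
#' fit
#' @export
aspire <- function(x, kappa1 = 0.05, hyper = NULL,
                   control = aspire_control(),
                   gibbs_likelihood = c("averaged", "final")) {
  gibbs_likelihood <- match.arg(gibbs_likelihood)
  batch <- as_batch(x)
  if (is.null(hyper)) hyper <- default_hyperparams(batch, kappa1 = kappa1)
  stopifnot(inherits(hyper, "aspire_hyper"), inherits(control, "aspire_control"))
  set.seed(control$seed)
  raw <- .cpp_aspire_gibbs(unname(batch), unclass(hyper), control$n_sweeps,
                           control$burn_in, control$thin, control$n_saved,
                           control$init, control$strict_t_loop,
                           control$trace_partitions)
  finish_fit(raw, batch, hyper, control, gibbs_likelihood,
             model = "aspire")
}

## Shared post-processing for both samplers.
finish_fit <- function(raw, batch, hyper, control, gibbs_likelihood, model) {
  nj <- vapply(batch, nrow, integer(1))
  labels_flat <- relabel_and_consensus(raw$saved_class_labels)
  # order classes by descending total size and relabel 1..K
  sizes <- sort(table(labels_flat), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  labels_flat <- unname(remap[as.character(labels_flat)])
  labels <- split(labels_flat, rep(seq_along(batch), nj))
  names(labels) <- names(batch)

  summaries <- class_summaries(batch, labels, hyper)
  ll <- if (gibbs_likelihood == "averaged") mean(raw$saved_loglik)
        else raw$trace_loglik[length(raw$trace_loglik)]
  trace <- data.frame(sweep = seq_along(raw$trace_K),
                      n_classes = raw$trace_K,
                      log_likelihood = raw$trace_loglik)
  if (!is.null(raw$trace_nclusters))
    trace$n_local_clusters <- raw$trace_nclusters
  out <- list(labels = labels, summaries = summaries,
              saved_draws = raw$saved_class_labels,
              saved_loglik = raw$saved_loglik,
              final_state = list(class_labels = raw$final_class_labels,
                                 cluster_labels = raw$final_cluster_labels),
              logLik = ll, trace = trace, hyper = hyper, control = control,
              batch = batch, model = model, pruned = NULL)
  if (!is.null(raw$partition_t)) {
    out$partition_t <- raw$partition_t
    out$partition_c <- raw$partition_c
  }
  class(out) <- "aspire"
  out
}

## Posterior NIW summaries of each consensus class, with local clusters taken
## as the (sample x class) groups.
class_summaries <- function(batch, labels, hyper) {
  K <- max(unlist(labels))
  J <- length(batch)
  d <- hyper$d
  lapply(seq_len(K), function(k) {
    clusters <- list()
    counts <- integer(J)
    for (j in seq_len(J)) {
      idx <- labels[[j]] == k
      counts[j] <- sum(idx)
      if (counts[j] > 0)
        clusters[[length(clusters) + 1]] <- suffstats(batch[[j]][idx, , drop = FALSE])
    }
    post <- class_posterior(clusters, hyper)
    covariance <- post$Lambda / (post$m_n - d - 1)
    list(class_id = k, mean = post$mu_n, covariance = covariance,
         total_count = sum(counts), per_sample_counts = counts)
  })
}

#' Align saved draws and compute consensus labels
#'
#' Resolves label switching across saved Gibbs draws by greedily matching
#' each draw's class labels to the first draw on the event-level contingency
#' table (largest overlap first; unmatched classes keep fresh labels), then
#' assigns each event the modal label across the aligned draws. Ties are
#' broken towards the label in the last saved draw.
#'
#' @param saved_draws List of integer label vectors over the same events.
#' @return Integer vector of consensus labels.
#' @export
relabel_and_consensus <- function(saved_draws) {
  if (length(saved_draws) == 0) stop("no saved draws")
  ref <- as.integer(saved_draws[[1]])
  aligned <- vapply(saved_draws, function(lab) {
    align_labels_to(as.integer(lab), ref)
  }, integer(length(ref)))
  aligned <- matrix(aligned, nrow = length(ref))
  last <- aligned[, ncol(aligned)]
  apply_consensus(aligned, last)
}

align_labels_to <- function(lab, ref) {
  labs <- sort(unique(lab))
  refs <- sort(unique(ref))
  tab <- table(factor(lab, labs), factor(ref, refs))
  map <- rep(NA_integer_, length(labs))
  used <- logical(length(refs))
  ord <- order(as.vector(tab), decreasing = TRUE)
  for (o in ord) {
    if (tab[o] == 0) break
    i <- (o - 1) %% nrow(tab) + 1
    j <- (o - 1) %/% nrow(tab) + 1
    if (!is.na(map[i]) || used[j]) next
    map[i] <- refs[j]
    used[j] <- TRUE
  }
  if (anyNA(map))
    map[is.na(map)] <- max(refs, map, na.rm = TRUE) + seq_len(sum(is.na(map)))
  map[match(lab, labs)]
}

apply_consensus <- function(aligned, last) {
  vapply(seq_len(nrow(aligned)), function(i) {
    tab <- table(aligned[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) as.integer(top)
    else if (as.character(last[i]) %in% top) last[i]
    else as.integer(top[1])
  }, integer(1))
}

#' @export
print.aspire <- function(x, ...) {
  K <- length(x$summaries)
  cat(if (x$model == "dpgmm") "Pooled Dirichlet-process Gaussian mixture"
      else "Hierarchical random-effects mixture (collapsed Gibbs)", "\n")
  cat(sprintf("  %d samples, %d events, %d global clusters\n",
              length(x$batch), sum(vapply(x$batch, nrow, integer(1))), K))
  cat(sprintf("  Gibbs likelihood: %.2f  (schedule %d/%d, thin %d, %d draws)\n",
              x$logLik, x$control$n_sweeps, x$control$burn_in,
              x$control$thin, x$control$n_saved))
  invisible(x)
}

#' @export
summary.aspire <- function(object, ...) {
  tab <- data.frame(
    class = vapply(object$summaries, `[[`, integer(1), "class_id"),
    total_count = vapply(object$summaries, `[[`, numeric(1), "total_count"),
    t(vapply(object$summaries, `[[`, numeric(object$hyper$d), "mean"))
  )
  names(tab)[-(1:2)] <- paste0("mean_", seq_len(object$hyper$d))
  if (!is.null(object$pruned)) tab$pruned <- object$pruned
  structure(list(table = tab, K = nrow(tab), logLik = object$logLik,
                 props = cluster_proportions(object, prune_threshold = 0)),
            class = "summary.aspire")
}

#' @export
print.summary.aspire <- function(x, ...) {
  cat("Global clusters:\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat("\nPer-sample proportions (first rows):\n")
  print(utils::head(round(x$props, 3)))
  invisible(x)
}

#' @export
coef.aspire <- function(object, ...) {
  list(means = lapply(object$summaries, `[[`, "mean"),
       covariances = lapply(object$summaries, `[[`, "covariance"))
}

#' @export
logLik.aspire <- function(object, ...) {
  structure(object$logLik, class = "logLik", df = NA_integer_,
            nobs = sum(vapply(object$batch, nrow, integer(1))))
}

#' Classify new events under a fitted model
#'
#' Assigns each new event to the global cluster with the highest posterior
#' predictive density (a fresh-local-cluster predictive per class, so a new
#' sample's random effect is accounted for).
#'
#' @param object A fitted `"aspire"` object.
#' @param newdata Numeric matrix of events (columns as in the fit).
#' @param ... Unused.
#' @return Integer vector of class labels.
#' @export
predict.aspire <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  hp <- object$hyper
  dens <- vapply(seq_along(object$summaries), function(k) {
    cls <- lapply(which_clusters(object, k), suffstats)
    dstudentt(newdata, class_predictive(cls, hp), log = TRUE)
  }, numeric(nrow(newdata)))
  dens <- matrix(dens, nrow = nrow(newdata))
  max.col(dens, ties.method = "first")
}

which_clusters <- function(object, k) {
  out <- list()
  for (j in seq_along(object$batch)) {
    idx <- object$labels[[j]] == k
    if (any(idx)) out[[length(out) + 1]] <- object$batch[[j]][idx, , drop = FALSE]
  }
  out
}

#' Plot a fitted batch model
#'
#' Scatter plot of (two channels of) the pooled events coloured by consensus
#' global cluster, with 2-standard-deviation ellipses of the estimated
#' cluster distributions.
#'
#' @param x A fitted `"aspire"` object.
#' @param dims Two channel indices to plot.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.aspire <- function(x, dims = c(1, 2), ...) {
  pooled <- do.call(rbind, x$batch)[, dims, drop = FALSE]
  lab <- unlist(x$labels)
  cols <- grDevices::hcl.colors(max(lab), "Dark 3")
  graphics::plot(pooled, col = cols[lab], pch = 16, cex = 0.4,
                 xlab = paste("channel", dims[1]),
                 ylab = paste("channel", dims[2]), ...)
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- rbind(cos(th), sin(th))
  for (s in x$summaries) {
    E <- s$mean[dims] + 2 * t(chol(s$covariance[dims, dims])) %*% circ
    graphics::lines(t(E), col = cols[s$class_id], lwd = 2)
  }
  invisible(x)
}

#' Simulate a new batch from a fitted model
#'
#' Draws a synthetic batch from the fitted global clusters: per sample,
#' local-cluster means are displaced from the estimated global means by the
#' fitted random-effects kernel and events are drawn from the local
#' Gaussians, with class weights set to the fitted pooled proportions.
#'
#' @param object A fitted `"aspire"` object.
#' @param nsim Number of samples in the simulated batch.
#' @param seed Integer seed.
#' @param n_per_sample Events per simulated sample.
#' @param ... Unused.
#' @return A list with `batch` and `truth` as in [simulate_from_model()].
#' @export
simulate.aspire <- function(object, nsim = 1, seed = 1L,
                            n_per_sample = 1000, ...) {
  sizes <- vapply(object$summaries, `[[`, numeric(1), "total_count")
  simulate_from_model(
    K = length(object$summaries), J = nsim, n_per_sample = n_per_sample,
    hp = object$hyper, class_weights = sizes / sum(sizes), seed = seed,
    global_params = list(
      means = lapply(object$summaries, `[[`, "mean"),
      covs = lapply(object$summaries, `[[`, "covariance")))
}
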