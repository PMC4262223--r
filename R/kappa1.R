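#' Select the random-effects scaling by Gibbs likelihood
#'
#' Runs the sampler once per candidate `kappa1` and returns the value that
#' maximises the Gibbs likelihood — the joint sampling likelihood of all
#' events given their assignments, averaged over the saved draws (or taken
#' at the final state). The default candidate grid is
#' `{0.05, 0.1, 0.25, 0.5, 1}`.
#'
#' @inheritParams aspire
#' @param grid Numeric vector of candidate `kappa1` values.
#' @return A list with `kappa1` (the selected value), `scores` (a data frame
#'   of per-candidate Gibbs log likelihoods), and `fits` (the fitted models,
#'   named by candidate).
#' @export
select_kappa1 <- function(x, grid = c(0.05, 0.1, 0.25, 0.5, 1),
                          hyper = NULL, control = aspire_control(),
                          gibbs_likelihood = c("averaged", "final")) {
  if (length(grid) == 0) stop("'grid' must be non-empty")
  gibbs_likelihood <- match.arg(gibbs_likelihood)
  batch <- as_batch(x)
  if (is.null(hyper)) hyper <- default_hyperparams(batch)
  fits <- lapply(grid, function(k1) {
    hp <- hyper
    hp$kappa1 <- k1
    aspire(batch, hyper = hp, control = control,
           gibbs_likelihood = gibbs_likelihood)
  })
  names(fits) <- format(grid)
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  list(kappa1 = grid[which.max(ll)],
       scores = data.frame(kappa1 = grid, log_likelihood = ll,
                           row.names = NULL),
       fits = fits)
}

#' Drop global clusters below a size threshold
#'
#' Flags classes whose total event count is strictly below
#' `threshold_fraction` of all events in the batch. Pruned classes are
#' removed from the reported summaries and cluster counts; their events keep
#' their labels but are excluded when compositional features are built (the
#' remaining proportions are renormalised by [cluster_proportions()]).
#'
#' @param fit A fitted `"aspire"` object.
#' @param threshold_fraction Fraction of total events in `[0, 1)`;
#'   the default 0.005 drops clusters holding less than 0.5% of all cells.
#' @return The fit with a logical `pruned` flag per class and `summaries`
#'   restricted to surviving classes (kept in full under `summaries_all`).
#' @export
prune_small_clusters <- function(fit, threshold_fraction = 0.005) {
  stopifnot(inherits(fit, "aspire"))
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must be in [0, 1)")
  all_summaries <- if (is.null(fit$summaries_all)) fit$summaries
                   else fit$summaries_all
  total <- sum(vapply(fit$batch, nrow, integer(1)))
  counts <- vapply(all_summaries, `[[`, numeric(1), "total_count")
  pruned <- counts < threshold_fraction * total
  fit$summaries_all <- all_summaries
  fit$summaries <- all_summaries[!pruned]
  fit$pruned <- pruned
  fit$prune_threshold <- threshold_fraction
  fit
}

#' Number of (surviving) global clusters
#'
#' @param fit A fitted `"aspire"` object, possibly after
#'   [prune_small_clusters()].
#' @return Integer count of reported global clusters.
#' @export
n_clusters <- function(fit) {
  stopifnot(inherits(fit, "aspire"))
  length(fit$summaries)
}
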