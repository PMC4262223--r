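#' Pooled Dirichlet-process Gaussian mixture baseline
#'
#' Concatenates all samples into one event matrix and fits an ordinary
#' Dirichlet-process Gaussian mixture by collapsed Gibbs sampling under the
#' same Normal-inverse-Wishart base distribution — no hierarchy and no
#' random effects. Each mixture component is reported directly as a global
#' cluster. This is the classical pooled-data strategy that the hierarchical
#' model improves upon when cluster locations drift between samples.
#'
#' @inheritParams aspire
#' @return An `"aspire"` object with `model = "dpgmm"`; per-sample labels
#'   refer to the pooled components.
#' @seealso [aspire()] for the hierarchical random-effects model.
#' @export
dpgmm <- function(x, hyper = NULL, control = aspire_control(),
                  gibbs_likelihood = c("averaged", "final")) {
  gibbs_likelihood <- match.arg(gibbs_likelihood)
  batch <- as_batch(x)
  if (is.null(hyper)) hyper <- default_hyperparams(batch)
  stopifnot(inherits(hyper, "aspire_hyper"), inherits(control, "aspire_control"))
  pooled <- do.call(rbind, batch)
  set.seed(control$seed)
  raw <- .cpp_dpgmm_gibbs(pooled, unclass(hyper), control$n_sweeps,
                          control$burn_in, control$thin, control$n_saved,
                          control$trace_partitions)
  finish_fit(raw, batch, hyper, control, gibbs_likelihood, model = "dpgmm")
}
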