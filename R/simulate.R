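#' Specification of the 25-sample synthetic benchmark
#'
#' Builds the generator specification for the standard synthetic benchmark:
#' 25 two-dimensional samples of 1000 events each — 10 normal samples drawn
#' from 3 normal global clusters, and three groups of 5 anomalous samples:
#' group 1 keeps the normal clusters but perturbs their mixing proportions;
#' group 2 adds three isolated rare populations of exactly `rare_pop_size`
#' events each (normal clusters at normal proportions otherwise); group 3
#' simulates measurement artifacts with clusters derived from the normal
#' ones by a mean shift and halved per-dimension standard deviations. Every
#' sample's local cluster means are displaced from the global means by the
#' random-effects kernel `N(mu_k, Sigma_k / kappa1_gen)`.
#'
#' The cluster geometry (means, covariances, proportion vectors, artifact
#' shift) lives in a single YAML configuration file shipped with the package;
#' pass `config` to substitute your own.
#'
#' @param seed Integer seed.
#' @param n_samples_normal Number of normal samples.
#' @param n_anomalous_per_group Samples per anomaly group.
#' @param events_per_sample Events per sample.
#' @param rare_pop_size Events in each rare population.
#' @param kappa1_gen Random-effects scaling used in generation.
#' @param config Path to the YAML geometry file.
#' @return A list of class `"benchmark25_spec"`.
#' @export
benchmark25_spec <- function(seed = 1L, n_samples_normal = 10,
                             n_anomalous_per_group = 5,
                             events_per_sample = 1000, rare_pop_size = 5,
                             kappa1_gen = 0.05,
                             config = system.file("extdata",
                                                  "benchmark25_config.yaml",
                                                  package = "aspire")) {
  geo <- yaml::read_yaml(config)
  nm <- lapply(geo$normal_clusters$means, as.numeric)
  nc <- lapply(geo$normal_clusters$covs, function(m) do.call(rbind, m))
  rm_ <- lapply(geo$rare_clusters$means, as.numeric)
  rc <- lapply(geo$rare_clusters$covs, function(m) do.call(rbind, m))
  sds <- lapply(nc, function(S) sqrt(diag(S)))
  am <- Map(function(mu, sd) mu + geo$artifact$shift_sd * sd, nm, sds)
  ac <- lapply(nc, function(S) S * geo$artifact$sd_scale^2)
  np <- as.numeric(geo$normal_proportions)
  if (abs(sum(np) - 1) > 1e-9) stop("normal proportions must sum to 1")
  if (rare_pop_size < 1) stop("'rare_pop_size' must be >= 1")
  if (kappa1_gen <= 0) stop("'kappa1_gen' must be > 0")
  structure(list(
    seed = as.integer(seed),
    n_samples_normal = n_samples_normal,
    n_anomalous_per_group = n_anomalous_per_group,
    events_per_sample = events_per_sample,
    rare_pop_size = rare_pop_size,
    kappa1_gen = kappa1_gen,
    dim = length(nm[[1]]),
    global_means = c(nm, rm_, am),
    global_covs = c(nc, rc, ac),
    normal_proportions = np,
    group1_proportions = as.numeric(geo$group1_proportions)
  ), class = "benchmark25_spec")
}

#' Simulate the 25-sample benchmark batch
#'
#' Draws the full benchmark described in [benchmark25_spec()] and returns the
#' batch together with complete ground truth. Global clusters are numbered
#' 1–3 (normal), 4–6 (rare populations), 7–9 (artifact clusters).
#'
#' @param spec A [benchmark25_spec()] object.
#' @return A list with `batch` (named list of event matrices) and `truth`,
#'   itself a list with `labels` (per-sample true global-cluster labels),
#'   `manifest` (data frame: sample, group, anomaly flag), `means`, `covs`,
#'   and `local_means` (per sample, per present cluster).
#' @examples
#' sim <- simulate_benchmark25(benchmark25_spec(seed = 7))
#' length(sim$batch)            # 25 samples
#' table(sim$truth$manifest$group)
#' @export
simulate_benchmark25 <- function(spec = benchmark25_spec()) {
  stopifnot(inherits(spec, "benchmark25_spec"))
  set.seed(spec$seed)
  groups <- c(rep("normal", spec$n_samples_normal),
              rep("proportion-shift", spec$n_anomalous_per_group),
              rep("rare-population", spec$n_anomalous_per_group),
              rep("artifact", spec$n_anomalous_per_group))
  J <- length(groups)
  n <- spec$events_per_sample
  batch <- vector("list", J)
  labels <- vector("list", J)
  local_means <- vector("list", J)
  for (j in seq_len(J)) {
    present <- switch(groups[j],
      "normal" = ,
      "proportion-shift" = 1:3,
      "rare-population" = 1:6,
      "artifact" = 7:9)
    counts <- switch(groups[j],
      "normal" = stats::rmultinom(1, n, spec$normal_proportions)[, 1],
      "proportion-shift" = stats::rmultinom(1, n, spec$group1_proportions)[, 1],
      "rare-population" = c(
        stats::rmultinom(1, n - 3 * spec$rare_pop_size,
                         spec$normal_proportions)[, 1],
        rep(spec$rare_pop_size, 3)),
      "artifact" = stats::rmultinom(1, n, spec$normal_proportions)[, 1])
    loc <- lapply(seq_along(present), function(i) {
      k <- present[i]
      rmvn(1, spec$global_means[[k]],
           spec$global_covs[[k]] / spec$kappa1_gen)[1, ]
    })
    names(loc) <- as.character(present)
    X <- do.call(rbind, lapply(seq_along(present), function(i) {
      if (counts[i] == 0) return(matrix(0, 0, spec$dim))
      rmvn(counts[i], loc[[i]], spec$global_covs[[present[i]]])
    }))
    lab <- rep(present, counts)
    perm <- sample.int(nrow(X))
    batch[[j]] <- X[perm, , drop = FALSE]
    labels[[j]] <- lab[perm]
    local_means[[j]] <- loc
  }
  names(batch) <- sprintf("sample%02d", seq_len(J))
  manifest <- data.frame(sample_id = names(batch), group = groups,
                         anomalous = groups != "normal")
  list(batch = batch,
       truth = list(labels = labels, manifest = manifest,
                    means = spec$global_means, covs = spec$global_covs,
                    local_means = local_means, spec = spec))
}

#' Simulate a batch from the full generative model
#'
#' Forward simulation of the hierarchical random-effects mixture: global
#' cluster parameters \eqn{(\mu_k, \Sigma_k)} are drawn from the
#' Normal-inverse-Wishart base distribution (or fixed via `global_params`),
#' each sample assigns its events to classes by `class_weights`, and within
#' each (sample, class) the events fall into local clusters generated by a
#' truncated stick-breaking Dirichlet process with concentration `hp$alpha`,
#' each local cluster mean displaced from the global mean by
#' `N(mu_k, Sigma_k / kappa1)`.
#'
#' @param K Number of global clusters.
#' @param J Number of samples.
#' @param n_per_sample Events per sample.
#' @param hp An [aspire_hyper()] object (supplies `kappa1`, `alpha` and the
#'   base distribution).
#' @param class_weights Simplex vector of class proportions shared by all
#'   samples (default uniform).
#' @param seed Integer seed.
#' @param global_params Optional list with `means` and `covs` (lists of
#'   length `K`) to fix the global clusters instead of drawing them.
#' @param max_local Stick-breaking truncation per (sample, class).
#' @return A list with `batch` and `truth` (`labels`, `means`, `covs`,
#'   `local_means`).
#' @export
simulate_from_model <- function(K, J, n_per_sample, hp,
                                class_weights = rep(1 / K, K), seed = 1L,
                                global_params = NULL, max_local = 20) {
  stopifnot(K >= 1, J >= 1, inherits(hp, "aspire_hyper"))
  if (abs(sum(class_weights) - 1) > 1e-9 || length(class_weights) != K)
    stop("'class_weights' must be a length-K simplex vector")
  set.seed(seed)
  d <- hp$d
  if (is.null(global_params)) {
    covs <- lapply(seq_len(K), function(k) riw_draw(hp$Sigma0, hp$m))
    means <- lapply(seq_len(K), function(k)
      rmvn(1, hp$mu0, covs[[k]] / hp$kappa0)[1, ])
  } else {
    means <- lapply(global_params$means, as.numeric)
    covs <- lapply(global_params$covs, as.matrix)
  }
  batch <- vector("list", J)
  labels <- vector("list", J)
  local_means <- vector("list", J)
  for (j in seq_len(J)) {
    kcount <- stats::rmultinom(1, n_per_sample, class_weights)[, 1]
    X <- matrix(0, 0, d)
    lab <- integer(0)
    lm_j <- list()
    for (k in seq_len(K)) {
      if (kcount[k] == 0) next
      w <- stick_breaking(hp$alpha, max_local)
      tcount <- stats::rmultinom(1, kcount[k], w)[, 1]
      mus <- lapply(seq_len(max_local), function(t)
        if (tcount[t] > 0) rmvn(1, means[[k]], covs[[k]] / hp$kappa1)[1, ])
      for (t in which(tcount > 0)) {
        X <- rbind(X, rmvn(tcount[t], mus[[t]], covs[[k]]))
        lab <- c(lab, rep(k, tcount[t]))
      }
      lm_j[[as.character(k)]] <- mus[!vapply(mus, is.null, logical(1))]
    }
    perm <- sample.int(nrow(X))
    batch[[j]] <- X[perm, , drop = FALSE]
    labels[[j]] <- lab[perm]
    local_means[[j]] <- lm_j
  }
  names(batch) <- sprintf("sample%02d", seq_len(J))
  list(batch = batch,
       truth = list(labels = labels, means = means, covs = covs,
                    local_means = local_means,
                    class_weights = class_weights))
}

## truncated stick-breaking weights (remaining mass folded into last stick)
stick_breaking <- function(alpha, n_sticks) {
  v <- stats::rbeta(n_sticks, 1, alpha)
  v[n_sticks] <- 1
  w <- v * cumprod(c(1, 1 - v[-n_sticks]))
  w / sum(w)
}

rmvn <- function(n, mu, Sigma) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol(Sigma), 2, mu, `+`)
}

riw_draw <- function(Sigma0, m) {
  solve(stats::rWishart(1, df = m, Sigma = solve(Sigma0))[, , 1])
}
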