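## small shared utilities for the test suite

## adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

## a quick, well-separated multi-sample batch for sampler tests
make_blob_batch <- function(J = 3, n_per_blob = 60, centers = list(c(0, 0), c(8, 8)),
                            seed = 1) {
  set.seed(seed)
  lapply(seq_len(J), function(j)
    do.call(rbind, lapply(centers, function(cc)
      sweep(matrix(stats::rnorm(n_per_blob * 2), n_per_blob, 2), 2, cc, `+`))))
}

fast_control <- function(seed = 1, n_sweeps = 80, burn_in = 40, thin = 8) {
  aspire_control(n_sweeps = n_sweeps, burn_in = burn_in, thin = thin,
                 n_saved = 5, seed = seed)
}

test_hp <- function(d = 2, kappa0 = 0.5, kappa1 = 0.4, m = d + 2) {
  aspire_hyper(mu0 = rep(0, d), Sigma0 = diag(d), m = m,
               kappa0 = kappa0, kappa1 = kappa1)
}
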