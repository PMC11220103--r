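# small parameter sets and matrices used across tests

`%||%` <- function(a, b) if (is.null(a)) b else a

gamma_params <- function(m = 3, theta = 0.2, d = 0.5, k_max = 2,
                         alpha = NULL, beta = NULL, modality = "RNA") {
  cp_params("gamma", theta = theta, d = d, k_max = k_max,
            alpha = alpha %||% seq(80, 120, length.out = m),
            beta = beta %||% rep(1, m), modality = modality)
}

gaussian_params <- function(m = 3, theta = 0.2, d = 0.5, k_max = 2,
                            modality = "ADT") {
  cp_params("gaussian-diag", theta = theta, d = d, k_max = k_max,
            mu = seq(90, 110, length.out = m),
            var = seq(40, 60, length.out = m), modality = modality)
}

tiny_counts <- function(values, modality = "RNA", barcodes = NULL,
                        features = NULL) {
  values <- as.matrix(values)
  count_matrix(values,
               barcodes %||% sprintf("BC%02d", seq_len(nrow(values))),
               features %||% sprintf("G%02d", seq_len(ncol(values))),
               modality)
}

# brute-force Bayes posterior: direct density products, no log-space tricks
brute_force_posterior <- function(params, X) {
  X <- as.matrix(X)
  pi_ <- truncated_poisson_pmf(params$theta, params$k_max)
  t(apply(X, 1, function(x) {
    num <- vapply(0:params$k_max, function(k) {
      dens <- exp(conditional_logdensity(params, k, x))
      pi_[k + 1] * prod(dens)
    }, numeric(1))
    num / sum(num)
  }))
}

# random valid small parameter sets for oracle comparisons
random_small_params <- function(seed) {
  set.seed(seed)
  m <- sample(1:3, 1)
  fam <- sample(c("gamma", "gaussian-diag"), 1)
  if (fam == "gamma") {
    cp_params("gamma", theta = runif(1, 0.05, 0.5), d = runif(1, -1, 2),
              k_max = 2, alpha = runif(m, 20, 200), beta = runif(m, 0.5, 2))
  } else {
    cp_params("gaussian-diag", theta = runif(1, 0.05, 0.5),
              d = runif(1, -1, 2), k_max = 2, mu = runif(m, 50, 150),
              var = runif(m, 20, 100))
  }
}

central_diff_grad <- function(fn, par, eps = 1e-5) {
  vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- eps
    (fn(par + e) - fn(par - e)) / (2 * eps)
  }, numeric(1))
}
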