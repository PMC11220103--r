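#' Decline factor for multi-cell droplets
#'
#' When a droplet holds k + 1 cells, each cell contributes less material than
#' a lone cell would (the "decline effect"). The factor
#' \deqn{f(d, k) = \frac{1}{k+1} + \left(1 - \frac{1}{k+1}\right)
#'   \frac{1}{1 + e^{-d}}}
#' multiplies the per-cell expectation, so the droplet-level expectation is
#' `(k + 1) * f(d, k)` times the singlet expectation — strictly between 1 and
#' k + 1 times it for every finite `d` and `k >= 1`, and exactly 1 at `k = 0`.
#'
#' @param d Decline parameter, any finite real; shared by all droplets of a
#'   modality.
#' @param k Number of extra cells, integer >= 0. Vectorized over both.
#' @return `f(d, k)` in (0, 1].
#' @export
decline_factor <- function(d, k) {
  stopifnot(all(is.finite(d)), all(k >= 0))
  1 / (k + 1) + (1 - 1 / (k + 1)) * stats::plogis(d)
}

#' Right-truncated Poisson prior over extra-cell counts
#'
#' The number of extra cells K in a droplet is Poisson(theta) truncated to
#' `0..k_max` and renormalized; by default triplets (`k_max = 2`) are the
#' largest modeled multiplet.
#'
#' @param theta Poisson rate, > 0.
#' @param k_max Largest modeled extra-cell count, integer >= 1.
#' @return Probability vector of length `k_max + 1`, summing to 1.
#' @export
truncated_poisson_pmf <- function(theta, k_max = 2L) {
  stopifnot(theta > 0, k_max >= 1)
  w <- stats::dpois(0:k_max, theta)
  w / sum(w)
}

# per-class scale factors a_k = f(d,k)*(k+1) and their d-derivative
.scale_factors <- function(d, k_max) {
  k <- 0:k_max
  s <- stats::plogis(d)
  list(a = decline_factor(d, k) * (k + 1), da_dd = k * s * (1 - s))
}

#' Conditional per-feature log-density given the extra-cell count
#'
#' Given K = k, droplet-level stable-feature values are distributed as the sum
#' of k + 1 i.i.d. per-cell contributions with decline-scaled means:
#' Gamma(`f(d,k) (k+1) alpha_i`, `beta_i`) for the gamma family,
#' Normal(`f(d,k) (k+1) mu_i`, `(k+1) sigma2_i`) for the diagonal gaussian
#' family, and multivariate Normal(`f(d,k) (k+1) mu`, `(k+1) Sigma`) for the
#' full-covariance gaussian. Gamma densities are evaluated at
#' `max(x, zero_offset)` so that observed zeros (allowed by the 50% zero
#' screen) keep the likelihood finite.
#'
#' @param params A `cp_params` object (see [cp_params()]).
#' @param k Extra-cell count in `0..k_max`.
#' @param x Numeric vector of stable-feature values for one droplet.
#' @return Per-feature log-density vector for the gamma and diagonal gaussian
#'   families; a single joint log-density for the full-covariance family.
#' @export
conditional_logdensity <- function(params, k, x) {
  stopifnot(inherits(params, "cp_params"))
  if (k < 0 || k > params$k_max) stop("k outside [0, k_max]", call. = FALSE)
  m <- length(params$feature_names)
  if (length(x) != m) stop("x length does not match feature set", call. = FALSE)
  a <- decline_factor(params$d, k) * (k + 1)
  switch(params$family,
    gamma = stats::dgamma(pmax(x, params$zero_offset),
                          shape = a * params$alpha, rate = params$beta,
                          log = TRUE),
    `gaussian-diag` = stats::dnorm(x, mean = a * params$mu,
                                   sd = sqrt((k + 1) * params$var), log = TRUE),
    `gaussian-mvg` = .mvn_logdensity(matrix(x, nrow = 1), a * params$mu,
                                     sqrt(k + 1) * params$chol)
  )
}

# log MVN density; L is a lower Cholesky factor of the covariance
.mvn_logdensity <- function(X, mean, L) {
  m <- length(mean)
  Y <- forwardsolve(L, t(X) - mean)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(Y^2))
}

# list over k = 0..k_max of n x m conditional log-density matrices
# (n-vectors of joint log densities for the mvg family)
.logdens_by_k <- function(params, X) {
  k_max <- params$k_max
  sf <- .scale_factors(params$d, k_max)
  lapply(0:k_max, function(k) {
    a <- sf$a[k + 1]
    switch(params$family,
      gamma = {
        Xo <- pmax(X, params$zero_offset)
        shape <- a * params$alpha
        cst <- shape * log(params$beta) - lgamma(shape)
        sweep(log(Xo), 2, shape - 1, "*") -
          sweep(Xo, 2, params$beta, "*") +
          matrix(cst, nrow(X), ncol(X), byrow = TRUE)
      },
      `gaussian-diag` = {
        v <- (k + 1) * params$var
        r <- sweep(X, 2, a * params$mu, "-")
        sweep(-r^2, 2, 2 * v, "/") -
          matrix(0.5 * log(2 * pi * v), nrow(X), ncol(X), byrow = TRUE)
      },
      `gaussian-mvg` = .mvn_logdensity(X, a * params$mu,
                                       sqrt(k + 1) * params$chol)
    )
  })
}

# per-droplet joint log-density matrix: n x (k_max + 1)
.joint_logdens <- function(params, X) {
  ld <- .logdens_by_k(params, X)
  if (params$family == "gaussian-mvg") {
    do.call(cbind, ld)
  } else {
    do.call(cbind, lapply(ld, rowSums))
  }
}

#' Negative joint log-likelihood of the compound Poisson mixture
#'
#' The likelihood treats droplets as independent and stable features as
#' independent conditional on the extra-cell count K, so each observation
#' contributes \eqn{\log \sum_k P_T(K=k)\, f(x \mid K=k)}; the truncated
#' Poisson supplies the mixture weights.
#'
#' @param params A `cp_params` object.
#' @param x Droplets x stable-features numeric matrix (raw scale).
#' @return The scalar negative log-likelihood.
#' @export
joint_negloglik <- function(params, x) {
  stopifnot(inherits(params, "cp_params"), is.matrix(x))
  if (any(!is.finite(x))) stop("non-finite data", call. = FALSE)
  if (params$family == "gamma" && any(x < 0)) {
    stop("gamma family requires non-negative data", call. = FALSE)
  }
  logpi <- log(truncated_poisson_pmf(params$theta, params$k_max))
  ld <- .logdens_by_k(params, x)
  if (params$family == "gaussian-mvg") {
    L <- do.call(cbind, ld)
    L <- sweep(L, 2, logpi, "+")
    -sum(.row_logsumexp(L))
  } else {
    acc <- 0
    M <- Reduce(pmax, Map(`+`, ld, logpi))
    s <- 0 * M
    for (k in seq_along(ld)) s <- s + exp(ld[[k]] + logpi[k] - M)
    -sum(M + log(s))
  }
}

.row_logsumexp <- function(L) {
  M <- as.vector(do.call(pmax, lapply(asplit(L, 2), as.vector)))
  M + log(rowSums(exp(L - M)))
}
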