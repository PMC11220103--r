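#' Fitted marginal CDF of one stable feature
#'
#' The marginal CDF under the fitted mixture:
#' `F(x) = sum_k P_T(K = k) CDF(x | K = k)`, using the same conditional
#' families (and, for gamma, the same zero-offset convention) as the
#' likelihood, so goodness-of-fit sees exactly the data the model saw.
#'
#' @param params A [cp_params()] or `cp_fit`.
#' @param feature_index Column index of the feature.
#' @param x Evaluation points (vectorized).
#' @return CDF values in \[0, 1\].
#' @export
fitted_marginal_cdf <- function(params, feature_index, x) {
  if (inherits(params, "cp_fit")) params <- params$params
  stopifnot(inherits(params, "cp_params"))
  i <- as.integer(feature_index)
  pi_ <- truncated_poisson_pmf(params$theta, params$k_max)
  a <- decline_factor(params$d, 0:params$k_max) * (0:params$k_max + 1)
  out <- numeric(length(x))
  for (ki in seq_along(pi_)) {
    k <- ki - 1
    comp <- switch(params$family,
      gamma = stats::pgamma(pmax(x, params$zero_offset),
                            shape = a[ki] * params$alpha[i],
                            rate = params$beta[i]),
      `gaussian-diag` = stats::pnorm(x, mean = a[ki] * params$mu[i],
                                     sd = sqrt((k + 1) * params$var[i])),
      `gaussian-mvg` = stats::pnorm(x, mean = a[ki] * params$mu[i],
                                    sd = sqrt((k + 1) * params$cov[i, i]))
    )
    out <- out + pi_[ki] * comp
  }
  out
}

#' Kolmogorov–Smirnov distance between data and the fitted marginal
#'
#' Two-sided KS statistic `sup_x |F_n(x) - F(x)|`, where the supremum over a
#' right-continuous fitted CDF is attained at the sorted sample points
#' (checking the empirical CDF and its left limit at each point).
#'
#' @param sample Observed values of one stable feature across droplets.
#' @param params A [cp_params()] or `cp_fit`.
#' @param feature_index Which feature the sample belongs to.
#' @return KS statistic in \[0, 1\].
#' @export
ks_statistic <- function(sample, params, feature_index) {
  stopifnot(length(sample) >= 1)
  n <- length(sample)
  xs <- sort(unique(sample))
  Fn <- cumsum(tabulate(match(sort(sample), xs), nbins = length(xs))) / n
  Fn_left <- c(0, Fn[-length(Fn)])
  Fhat <- fitted_marginal_cdf(params, feature_index, xs)
  max(abs(Fn - Fhat), abs(Fn_left - Fhat))
}

#' Modality-level goodness-of-fit report
#'
#' Computes the KS statistic for every stable feature, averages them, and
#' reports `GOF = 1 / mean(KS)`. A GOF above 3 indicates a good fit and
#' reliable predictions; the flag is carried downstream as the modality's
#' overall integration weight. The GOF is capped at 1e6 in the (theoretically
#' impossible for finite samples) case of a zero mean KS, keeping the
#' softmax finite.
#'
#' @param fit A `cp_fit` or [cp_params()].
#' @param x Droplets x stable-features matrix the model was fitted to.
#' @return A `gof_report`: list with `ks` (tibble: `feature`, `ks`),
#'   `mean_ks`, `gof`, `reliable` (`gof > 3`), `modality`.
#' @export
gof_modality <- function(fit, x) {
  params <- if (inherits(fit, "cp_fit")) fit$params else fit
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(params$feature_names))
  ks <- vapply(seq_len(ncol(x)), function(i) {
    ks_statistic(x[, i], params, i)
  }, numeric(1))
  mean_ks <- mean(ks)
  gof <- if (mean_ks > 0) 1 / mean_ks else 1e6
  gof <- min(gof, 1e6)
  structure(
    list(ks = tibble::tibble(feature = params$feature_names, ks = ks),
         mean_ks = mean_ks, gof = gof, reliable = gof > 3,
         modality = params$modality),
    class = "gof_report"
  )
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("<gof_report> %s: mean KS = %.4f, GOF = %.2f (%s)\n",
              x$modality, x$mean_ks, x$gof,
              if (x$reliable) "reliable" else "low - interpret with caution"))
  invisible(x)
}
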