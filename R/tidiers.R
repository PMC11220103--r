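#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy a fitted compound Poisson modality model
#'
#' @param x A `cp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per stable feature: the family's per-feature
#'   parameters and the implied singlet mean (`alpha/beta` or `mu`).
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, ...) {
  p <- x$params
  out <- tibble::tibble(feature = p$feature_names)
  if (p$family == "gamma") {
    out$alpha <- p$alpha
    out$beta <- p$beta
    out$singlet_mean <- p$alpha / p$beta
  } else {
    out$mu <- p$mu
    out$var <- if (p$family == "gaussian-diag") p$var else diag(p$cov)
    out$singlet_mean <- p$mu
  }
  out
}

#' Glance at a fitted compound Poisson modality model
#'
#' @param x A `cp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `modality`, `family`, `theta`, `d`, `k_max`,
#'   `n_droplets`, `n_features`, `logLik`, `converged`, and the implied
#'   expected multiplet fraction `1 - P_T(K = 0)`.
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    modality = p$modality, family = p$family, theta = p$theta, d = p$d,
    k_max = p$k_max, n_droplets = x$n, n_features = x$m, logLik = x$loglik,
    converged = x$diagnostics$converged,
    multiplet_fraction = 1 - truncated_poisson_pmf(p$theta, p$k_max)[1]
  )
}

#' @method tidy multiplet_detection
#' @export
tidy.multiplet_detection <- function(x, ...) x$predictions

#' @method glance multiplet_detection
#' @export
glance.multiplet_detection <- function(x, ...) {
  gof <- vapply(x$gof, function(g) g$gof, numeric(1))
  tibble::tibble(
    n_droplets = nrow(x$predictions),
    modalities = paste(names(x$fits), collapse = "+"),
    multiplet_fraction = mean(x$predictions$call == "multiplet"),
    min_gof = min(gof), max_gof = max(gof)
  )
}

#' Plot a fitted stable-feature mixture against the data
#'
#' Overlays the fitted mixture components (singlet, doublet, triplet
#' conditional densities weighted by the truncated Poisson prior) on a
#' histogram of one stable feature.
#'
#' @param object A `cp_fit`.
#' @param x Droplets x stable-features matrix the model was fitted to.
#' @param feature Feature index (or name) to display.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cp_fit
#' @export
autoplot.cp_fit <- function(object, x, feature = 1, ..., bins = 60) {
  p <- object$params
  i <- if (is.character(feature)) match(feature, p$feature_names) else feature
  vals <- as.matrix(x)[, i]
  pi_ <- truncated_poisson_pmf(p$theta, p$k_max)
  grid <- seq(min(vals), max(vals), length.out = 400)
  marg <- .marginal_params(p)[[i]]
  dens <- purrr::map_dfr(0:p$k_max, function(kk) {
    tibble::tibble(
      x = grid,
      density = pi_[kk + 1] * exp(conditional_logdensity_grid(marg, kk, grid)),
      k = factor(kk, 0:p$k_max)
    )
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(value = vals),
      ggplot2::aes(x = .data$value, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density, colour = .data$k)) +
    ggplot2::labs(x = p$feature_names[i], y = "density",
                  colour = "extra cells k",
                  title = sprintf("%s: fitted mixture for %s",
                                  p$modality, p$feature_names[i])) +
    ggplot2::theme_minimal()
}

# vectorized single-feature conditional density over a grid
conditional_logdensity_grid <- function(marg, k, grid) {
  vapply(grid, function(g) conditional_logdensity(marg, k, g), numeric(1))
}

#' Plot per-feature goodness-of-fit
#'
#' @param object A `gof_report`.
#' @param ... Unused.
#' @return A ggplot object: per-feature KS statistics with the modality mean.
#' @method autoplot gof_report
#' @export
autoplot.gof_report <- function(object, ...) {
  ggplot2::ggplot(object$ks,
                  ggplot2::aes(x = stats::reorder(.data$feature, .data$ks),
                               y = .data$ks)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_ks, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "KS statistic",
                  title = sprintf("%s: GOF = %.2f", object$modality,
                                  object$gof)) +
    ggplot2::theme_minimal()
}

#' Plot the posterior singlet-probability distribution
#'
#' @param object A `posterior_table`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object with the 0.5 classification boundary marked.
#' @method autoplot posterior_table
#' @export
autoplot.posterior_table <- function(object, ..., bins = 50) {
  ggplot2::ggplot(tibble::tibble(p_singlet = object$probs[, 1]),
                  ggplot2::aes(x = .data$p_singlet)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "P(singlet | data)", y = "droplets",
                  title = sprintf("posterior (%s)", object$source)) +
    ggplot2::theme_minimal()
}
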