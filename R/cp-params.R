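#' Parameter set of a compound Poisson modality model
#'
#' Bundles everything needed to evaluate one modality's mixture: the truncated
#' Poisson rate `theta`, the decline parameter `d`, the truncation `k_max`,
#' and the per-feature contribution-distribution parameters of the chosen
#' family.
#'
#' @param family `"gamma"` (RNA/ATAC counts), `"gaussian-diag"` (ADT,
#'   independent features; the default ADT family), or `"gaussian-mvg"` (ADT
#'   with a full covariance, for small panels of correlated tags).
#' @param theta Truncated Poisson rate, > 0.
#' @param d Decline parameter, finite real.
#' @param k_max Largest modeled extra-cell count (default 2: up to triplets).
#' @param alpha,beta Per-feature Gamma shape/rate (gamma family), all > 0.
#' @param mu Per-feature means (gaussian families).
#' @param var Per-feature variances (gaussian-diag), all > 0.
#' @param cov Positive-definite covariance matrix (gaussian-mvg).
#' @param feature_names Character vector naming the stable features.
#' @param modality Modality tag (`"RNA"`, `"ADT"`, `"ATAC"`).
#' @param zero_offset Gamma densities/CDFs are evaluated at
#'   `max(x, zero_offset)` (default 0.5, a half-count continuity correction)
#'   so zeros keep the likelihood finite. Ignored by gaussian families.
#'
#' @return An object of class `cp_params`.
#' @export
cp_params <- function(family = c("gamma", "gaussian-diag", "gaussian-mvg"),
                      theta, d, k_max = 2L,
                      alpha = NULL, beta = NULL, mu = NULL, var = NULL,
                      cov = NULL, feature_names = NULL,
                      modality = "RNA", zero_offset = 0.5) {
  family <- match.arg(family)
  stopifnot(is.finite(theta), theta > 0, is.finite(d), k_max >= 1)
  p <- list(family = family, theta = theta, d = d, k_max = as.integer(k_max),
            modality = modality, zero_offset = zero_offset)
  if (family == "gamma") {
    stopifnot(!is.null(alpha), !is.null(beta), length(alpha) == length(beta),
              all(alpha > 0), all(beta > 0))
    p$alpha <- alpha
    p$beta <- beta
    m <- length(alpha)
  } else if (family == "gaussian-diag") {
    stopifnot(!is.null(mu), !is.null(var), length(mu) == length(var),
              all(var > 0))
    p$mu <- mu
    p$var <- var
    m <- length(mu)
  } else {
    stopifnot(!is.null(mu), !is.null(cov), is.matrix(cov),
              nrow(cov) == length(mu), isSymmetric(unname(cov)))
    ch <- tryCatch(chol(cov), error = function(e) {
      stop("`cov` must be positive-definite", call. = FALSE)
    })
    p$mu <- mu
    p$cov <- cov
    p$chol <- t(ch) # lower factor
    m <- length(mu)
  }
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(m))
  stopifnot(length(feature_names) == m)
  p$feature_names <- feature_names
  structure(p, class = "cp_params")
}

#' @export
print.cp_params <- function(x, ...) {
  cat(sprintf(
    "<cp_params> %s (%s): %d features, theta = %.4f, d = %.3f, k_max = %d\n",
    x$modality, x$family, length(x$feature_names), x$theta, x$d, x$k_max))
  invisible(x)
}

#' Serialize fitted parameters to JSON
#'
#' Writes a versioned JSON document holding the family, theta, d, k_max,
#' per-feature parameters and feature names, enabling reproducible re-scoring
#' of new droplets without refitting.
#'
#' @param params A `cp_params` object.
#' @param path Output JSON path.
#' @return `params`, invisibly.
#' @export
write_cp_params <- function(params, path) {
  stopifnot(inherits(params, "cp_params"))
  doc <- list(format_version = 1L, family = params$family,
              modality = params$modality, theta = params$theta, d = params$d,
              k_max = params$k_max, zero_offset = params$zero_offset,
              feature_names = params$feature_names)
  for (f in c("alpha", "beta", "mu", "var")) doc[[f]] <- params[[f]]
  if (!is.null(params$cov)) doc$cov <- params$cov
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(params)
}

#' @rdname write_cp_params
#' @export
read_cp_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp_params(family = doc$family, theta = doc$theta, d = doc$d,
            k_max = doc$k_max, alpha = doc$alpha, beta = doc$beta,
            mu = doc$mu, var = doc$var,
            cov = if (!is.null(doc$cov)) as.matrix(doc$cov),
            feature_names = doc$feature_names, modality = doc$modality,
            zero_offset = doc$zero_offset)
}
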