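#' Overall modality weights from goodness-of-fit
#'
#' The overall weight of a modality equals its GOF; the ATAC modality is
#' down-weighted by `lambda` (default 0.5) because ATAC-based predictions
#' generally lack sensitivity.
#'
#' @param gof_by_modality Named numeric vector or list mapping modality
#'   (`RNA`, `ADT`, `ATAC`) to its GOF value (> 0).
#' @param lambda_atac ATAC down-weighting factor in \[0, 1\].
#' @return Named numeric vector of overall weights, same modalities as input.
#' @export
overall_weights <- function(gof_by_modality, lambda_atac = 0.5) {
  w <- unlist(gof_by_modality)
  stopifnot(all(w > 0), lambda_atac >= 0, lambda_atac <= 1)
  if ("ATAC" %in% names(w)) w[["ATAC"]] <- lambda_atac * w[["ATAC"]]
  w
}

# multiplet-leaning step: 0 if the singlet probability exceeds 1/2, else 1
.u_step <- function(p) ifelse(p > 0.5, 0L, 1L)

#' Droplet-specific modality consistency
#'
#' For each droplet, the fraction of stable features whose single-feature
#' singlet/multiplet call (posterior computed from that feature alone, using
#' the full-data parameter estimates) agrees with the whole-modality call.
#' Both calls use the step `u(p) = 0` if `p > 1/2`, else 1, applied to the
#' singlet posterior probability. For the full-covariance gaussian family the
#' single-feature posteriors use the per-feature marginal normals.
#'
#' @param fit A `cp_fit` or [cp_params()].
#' @param x Droplets x stable-features matrix.
#' @param posterior The modality's `posterior_table` for `x` (computed if
#'   omitted).
#' @return Numeric vector of consistencies `R_j` in \[0, 1\], one per droplet
#'   (each a multiple of `1/m`).
#' @export
feature_consistency <- function(fit, x, posterior = NULL) {
  params <- if (inherits(fit, "cp_fit")) fit$params else fit
  x <- as.matrix(x)
  m <- ncol(x)
  stopifnot(m == length(params$feature_names))
  if (is.null(posterior)) posterior <- cp_posterior(params, x)
  stopifnot(nrow(posterior$probs) == nrow(x))
  u_mod <- .u_step(posterior$probs[, 1])

  marg <- .marginal_params(params)
  agree <- matrix(0L, nrow(x), m)
  for (i in seq_len(m)) {
    post_i <- cp_posterior(marg[[i]], x[, i, drop = FALSE])
    agree[, i] <- as.integer(.u_step(post_i$probs[, 1]) == u_mod)
  }
  rowMeans(agree)
}

# single-feature parameter slices (marginal normals for the mvg family)
.marginal_params <- function(params) {
  m <- length(params$feature_names)
  lapply(seq_len(m), function(i) {
    switch(params$family,
      gamma = cp_params("gamma", theta = params$theta, d = params$d,
                        k_max = params$k_max, alpha = params$alpha[i],
                        beta = params$beta[i],
                        feature_names = params$feature_names[i],
                        modality = params$modality,
                        zero_offset = params$zero_offset),
      `gaussian-diag` = cp_params("gaussian-diag", theta = params$theta,
                                  d = params$d, k_max = params$k_max,
                                  mu = params$mu[i], var = params$var[i],
                                  feature_names = params$feature_names[i],
                                  modality = params$modality),
      `gaussian-mvg` = cp_params("gaussian-diag", theta = params$theta,
                                 d = params$d, k_max = params$k_max,
                                 mu = params$mu[i], var = params$cov[i, i],
                                 feature_names = params$feature_names[i],
                                 modality = params$modality)
    )
  })
}

#' Per-droplet softmax modality weights
#'
#' The droplet-specific weight of modality q is
#' `softmax(W^(q) * R_j^(q))` across the available modalities, computed with
#' max-subtraction for numerical stability. Weights are positive and sum to 1
#' for every droplet.
#'
#' @param overall Named vector of overall modality weights
#'   (see [overall_weights()]).
#' @param consistency Droplets x modalities matrix (columns named like
#'   `overall`) of consistencies `R_j^(q)`.
#' @return Droplets x modalities matrix of weights, rows summing to 1.
#' @export
droplet_weights <- function(overall, consistency) {
  consistency <- as.matrix(consistency)
  mods <- names(overall)
  stopifnot(!is.null(mods), all(mods %in% colnames(consistency)))
  scores <- sweep(consistency[, mods, drop = FALSE], 2, overall[mods], "*")
  mx <- apply(scores, 1, max)
  e <- exp(scores - mx)
  w <- e / rowSums(e)
  colnames(w) <- mods
  w
}

#' Combine per-modality posteriors into a final posterior
#'
#' The combined posterior is the per-droplet weighted sum of the modality
#' posteriors, `P(K = k | x_j) = sum_q w_j^(q) P^(q)(K = k | x_j)` — a convex
#' combination, so rows automatically stay on the simplex.
#'
#' @param posteriors Named list of `posterior_table`s sharing droplet order
#'   and `k_max`.
#' @param weights Droplets x modalities matrix with rows summing to 1
#'   (columns matching `names(posteriors)`), or omitted for a single modality.
#' @return A `posterior_table` with `source = "combined"`.
#' @export
combine_posteriors <- function(posteriors, weights = NULL) {
  stopifnot(length(posteriors) >= 1)
  k_max <- posteriors[[1]]$k_max
  n <- nrow(posteriors[[1]]$probs)
  for (p in posteriors) {
    stopifnot(inherits(p, "posterior_table"), p$k_max == k_max,
              nrow(p$probs) == n)
  }
  if (is.null(weights)) {
    stopifnot(length(posteriors) == 1)
    weights <- matrix(1, n, 1, dimnames = list(NULL, names(posteriors)))
  }
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == n,
            all(names(posteriors) %in% colnames(weights)))
  probs <- matrix(0, n, k_max + 1)
  for (q in names(posteriors)) {
    probs <- probs + weights[, q] * posteriors[[q]]$probs
  }
  colnames(probs) <- paste0("k", 0:k_max)
  rownames(probs) <- rownames(posteriors[[1]]$probs)
  structure(list(probs = probs, k_max = k_max, source = "combined"),
            class = "posterior_table")
}
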