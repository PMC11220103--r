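#' Per-droplet posterior over the number of extra cells
#'
#' Applies Bayes' rule in log space: for each droplet j,
#' `P(K = k | x_j) = P_T(K = k) prod_i f(x_ij | k) / sum_s P_T(K = s)
#' prod_i f(x_ij | s)`, with log-sum-exp normalization so extreme droplets
#' never underflow to NaN.
#'
#' @param fit A `cp_fit` from [fit_cp()], or a bare [cp_params()] object.
#' @param x Droplets x stable-features matrix on the raw scale.
#' @param source Label recorded with the table (defaults to the params'
#'   modality).
#' @return A `posterior_table`: list with `probs` (n x (k_max + 1) matrix,
#'   rows summing to 1, row names carrying barcodes when `x` has them),
#'   `k_max`, and `source`.
#' @export
cp_posterior <- function(fit, x, source = NULL) {
  params <- if (inherits(fit, "cp_fit")) fit$params else fit
  stopifnot(inherits(params, "cp_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$feature_names)) {
    stop("data does not match the stable-feature dimension", call. = FALSE)
  }
  logpi <- log(truncated_poisson_pmf(params$theta, params$k_max))
  L <- sweep(.joint_logdens(params, x), 2, logpi, "+")
  probs <- exp(L - .row_logsumexp(L))
  probs <- probs / rowSums(probs)
  colnames(probs) <- paste0("k", 0:params$k_max)
  rownames(probs) <- rownames(x)
  structure(list(probs = probs, k_max = params$k_max,
                 source = source %||% params$modality),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("<posterior_table> %s: %d droplets, k_max = %d\n",
              x$source, nrow(x$probs), x$k_max))
  invisible(x)
}

#' Classify droplets from a posterior table
#'
#' A droplet is called a singlet when `P(K = 0) >= 0.5` (boundary inclusive)
#' and a multiplet otherwise; `predicted_k` is the posterior mode, with ties
#' broken toward the smaller k (the conservative call).
#'
#' @param posterior A `posterior_table` from [cp_posterior()] or
#'   [combine_posteriors()].
#' @return A tibble: `barcode` (when available), `p_singlet`, `predicted_k`,
#'   `call` in `{"singlet", "multiplet"}`.
#' @export
classify_droplets <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_table"))
  probs <- posterior$probs
  p0 <- unname(probs[, 1])
  pred_k <- max.col(probs, ties.method = "first") - 1L
  tbl <- tibble::tibble(
    p_singlet = p0,
    predicted_k = pred_k,
    call = ifelse(p0 >= 0.5, "singlet", "multiplet")
  )
  if (!is.null(rownames(probs))) {
    tbl <- dplyr::bind_cols(tibble::tibble(barcode = rownames(probs)), tbl)
  }
  tbl
}
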