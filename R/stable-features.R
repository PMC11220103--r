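#' Select stable features for multiplet detection
#'
#' Stable features are features whose abundance varies little across cells, so
#' their per-droplet totals track the number of cells in the droplet rather
#' than the cell type. Selection has two steps: (i) screen out features whose
#' proportion of zero values across droplets exceeds 50%; (ii) rank the
#' survivors by the mean/SD ratio of their `log1p`-transformed values
#' (log1p damps outlier expression when scoring; the model itself is always
#' fitted on the raw scale) and keep the top `n` (or top fraction).
#'
#' Boundary conventions: a feature with zero-proportion exactly 0.5 is kept by
#' the screen; constant features (SD = 0, ratio undefined) are dropped since
#' they carry no information and break maximum-likelihood fitting; score ties
#' are broken by feature name so selection is deterministic; a fractional
#' request resolves to `max(1, floor(frac * m_surviving))`.
#'
#' @param counts A [count_matrix()].
#' @param n Number of features to keep (default 300, the usual choice for RNA
#'   and ATAC gene activity). Ignored when `frac` is given.
#' @param frac Fraction of screen-surviving features to keep (e.g. 0.10 for
#'   ADT panels, whose size varies between experiments).
#'
#' @return A tibble with one row per feature: `feature`, `zero_proportion`,
#'   `stability_score` (mean/SD of log1p values; `NA` for constant features),
#'   `selected`. The selected features, in descending score order, are in
#'   `attr(, "selected_features")`.
#' @export
select_stable_features <- function(counts, n = 300, frac = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  x <- counts$values
  zero_prop <- colMeans(x == 0)
  lx <- log1p(x)
  mu <- colMeans(lx)
  sd_ <- apply(lx, 2, stats::sd)
  score <- ifelse(sd_ > 0, mu / sd_, NA_real_)

  pass_screen <- zero_prop <= 0.5
  candidate <- pass_screen & !is.na(score)
  if (!any(candidate)) {
    stop("no feature passes the zero-proportion screen with positive SD",
         call. = FALSE)
  }
  m_surv <- sum(candidate)
  n_keep <- if (!is.null(frac)) {
    stopifnot(frac > 0, frac <= 1)
    max(1L, floor(frac * m_surv))
  } else {
    stopifnot(n >= 1)
    min(as.integer(n), m_surv)
  }

  tbl <- tibble::tibble(
    feature = counts$features,
    zero_proportion = unname(zero_prop),
    stability_score = unname(score)
  )
  ranked <- tbl |>
    dplyr::filter(pass_screen, !is.na(.data$stability_score)) |>
    dplyr::arrange(dplyr::desc(.data$stability_score), .data$feature)
  keep <- ranked$feature[seq_len(n_keep)]
  tbl$selected <- tbl$feature %in% keep
  attr(tbl, "selected_features") <- keep
  attr(tbl, "modality") <- counts$modality
  class(tbl) <- c("stable_features", class(tbl))
  tbl
}

#' Extract the stable-feature submatrix
#'
#' @param counts A [count_matrix()].
#' @param features A `stable_features` table from [select_stable_features()],
#'   or a character vector of feature names.
#' @return A numeric droplets x selected-features matrix (raw values), columns
#'   in descending stability order.
#' @export
stable_values <- function(counts, features) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- if (inherits(features, "stable_features")) {
    attr(features, "selected_features")
  } else {
    as.character(features)
  }
  missing <- setdiff(keep, counts$features)
  if (length(missing) > 0L) {
    stop("features not present in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts$values[, keep, drop = FALSE]
}
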