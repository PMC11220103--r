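#' Simulate droplets from the generative compound Poisson model
#'
#' Draws the extra-cell count K of each droplet from the truncated Poisson
#' prior (shared across modalities: a droplet's occupancy is a physical fact,
#' not a modality property), then for every droplet draws K + 1 i.i.d.
#' per-cell contributions from the k-conditional family — Gamma/Gaussian with
#' decline-scaled means — and sums them feature-wise. The sampler uses named
#' substreams (labels, then per-modality contributions) derived from `seed`,
#' so adding a modality never perturbs the labels or other modalities' draws.
#'
#' @param params_by_modality Named list of [cp_params()] (names become
#'   modality tags); the occupancy draw uses `theta`/`k_max` of the first.
#' @param n Number of droplets.
#' @param seed Integer seed (mandatory: identical spec implies identical
#'   output).
#' @param round_counts Round gamma draws to integers, mimicking on-disk count
#'   matrices (default `FALSE`: the model treats data as continuous).
#' @return List with `matrices` (named list of [count_matrix()]) and `labels`
#'   (tibble: `barcode`, `k`, `call`).
#' @export
simulate_droplets <- function(params_by_modality, n, seed,
                              round_counts = FALSE) {
  if (inherits(params_by_modality, "cp_params")) {
    params_by_modality <- stats::setNames(list(params_by_modality),
                                          params_by_modality$modality)
  }
  stopifnot(length(params_by_modality) >= 1, !is.null(names(params_by_modality)),
            n >= 1)
  seed <- as.integer(seed)
  p1 <- params_by_modality[[1]]

  set.seed(seed %% 2147483647L)
  pmf <- truncated_poisson_pmf(p1$theta, p1$k_max)
  k_lab <- sample(0:p1$k_max, n, replace = TRUE, prob = pmf)
  barcodes <- sprintf("droplet_%0*d", nchar(n), seq_len(n))

  matrices <- purrr::imap(params_by_modality, function(params, tag) {
    idx <- match(tag, names(params_by_modality))
    set.seed((seed + 1000L * idx) %% 2147483647L)
    X <- .draw_droplet_sums(params, k_lab)
    if (round_counts && params$family == "gamma") X <- round(X)
    count_matrix(X, barcodes, params$feature_names,
                 modality = if (tag %in% c("RNA", "ADT", "ATAC")) tag else params$modality)
  })

  list(matrices = matrices,
       labels = tibble::tibble(barcode = barcodes, k = k_lab,
                               call = ifelse(k_lab == 0, "singlet", "multiplet")))
}

# sum K_j + 1 per-cell contributions per droplet, grouped by occupancy class
.draw_droplet_sums <- function(params, k_lab) {
  n <- length(k_lab)
  m <- length(params$feature_names)
  X <- matrix(0, n, m)
  for (k in sort(unique(k_lab))) {
    rows <- which(k_lab == k)
    n_cells <- length(rows) * (k + 1)
    f <- decline_factor(params$d, k)
    cells <- switch(params$family,
      gamma = matrix(stats::rgamma(n_cells * m,
                                   shape = rep(f * params$alpha, each = n_cells),
                                   rate = rep(params$beta, each = n_cells)),
                     n_cells, m),
      `gaussian-diag` = matrix(stats::rnorm(n_cells * m,
                                            mean = rep(f * params$mu, each = n_cells),
                                            sd = rep(sqrt(params$var), each = n_cells)),
                               n_cells, m),
      `gaussian-mvg` = {
        Z <- matrix(stats::rnorm(n_cells * m), n_cells, m)
        sweep(Z %*% t(params$chol), 2, f * params$mu, "+")
      }
    )
    grp <- rep(seq_along(rows), each = k + 1)
    X[rows, ] <- rowsum(cells, grp)
  }
  X
}

#' Build artificial multiplets by summing observed singlet profiles
#'
#' Mirrors the standard simulation design for benchmarking multiplet
#' detectors: starting from droplets known to be singlets, a chosen fraction
#' of output droplets are doublets (element-wise sums of 2 sampled singlet
#' profiles) and triplets (sums of 3); the remainder are unmodified singlets.
#' Constituents are sampled with replacement across multiplets but are
#' distinct within a multiplet. In homotypic mode all constituents of every
#' artificial multiplet carry the given cell-type label. When several
#' modalities are supplied the same constituent singlets are summed in every
#' modality.
#'
#' @param singlets A [count_matrix()] of singlet droplets, or a named list of
#'   them sharing barcodes/order (one per modality).
#' @param doublet_rate,triplet_rate Fractions of output droplets that are
#'   artificial doublets/triplets (typical study ranges: 5–30% and 2–8%).
#'   Counts are `round(rate * n_out)`, with the singlet remainder absorbing
#'   rounding.
#' @param cell_labels Optional per-droplet cell-type labels (required for
#'   homotypic mode).
#' @param homotypic_label Optional label restricting multiplet constituents to
#'   one cell type.
#' @param seed Integer seed.
#' @param n_out Number of output droplets (default: number of input singlets).
#' @return List with `matrices` (named list of [count_matrix()], or a single
#'   one if a single matrix was given) and `labels` (tibble: `barcode`, `k`,
#'   `call`, `constituents` — semicolon-joined source barcodes).
#' @export
simulate_artificial_multiplets <- function(singlets, doublet_rate,
                                           triplet_rate = 0,
                                           cell_labels = NULL,
                                           homotypic_label = NULL,
                                           seed = 1L, n_out = NULL) {
  single_input <- inherits(singlets, "count_matrix")
  mats <- if (single_input) list(X = singlets) else singlets
  stopifnot(length(mats) >= 1)
  bc <- mats[[1]]$barcodes
  for (cm in mats) stopifnot(identical(cm$barcodes, bc))
  n_in <- length(bc)
  if (is.null(n_out)) n_out <- n_in
  stopifnot(doublet_rate >= 0, triplet_rate >= 0,
            doublet_rate + triplet_rate < 1)
  n_d <- round(doublet_rate * n_out)
  n_t <- round(triplet_rate * n_out)
  n_s <- n_out - n_d - n_t

  pool <- seq_len(n_in)
  if (!is.null(homotypic_label)) {
    stopifnot(!is.null(cell_labels), length(cell_labels) == n_in)
    pool <- which(cell_labels == homotypic_label)
    if (length(pool) == 0L) {
      stop("homotypic label absent from `cell_labels`", call. = FALSE)
    }
  }
  if (length(pool) < 3 && n_t > 0) {
    stop("not enough singlets to form triplets", call. = FALSE)
  }
  if (length(pool) < 2 && n_d > 0) {
    stop("not enough singlets to form doublets", call. = FALSE)
  }

  set.seed((as.integer(seed) + 2000L) %% 2147483647L)
  constituents <- c(
    lapply(seq_len(n_s), function(i) sample(seq_len(n_in), 1L)),
    lapply(seq_len(n_d), function(i) sample(pool, 2L)),
    lapply(seq_len(n_t), function(i) sample(pool, 3L))
  )
  k_lab <- rep(c(0L, 1L, 2L), c(n_s, n_d, n_t))
  out_bc <- sprintf("droplet_%0*d", nchar(n_out), seq_len(n_out))

  out_mats <- purrr::map(mats, function(cm) {
    X <- t(vapply(constituents, function(idx) {
      colSums(cm$values[idx, , drop = FALSE])
    }, numeric(ncol(cm$values))))
    count_matrix(X, out_bc, cm$features, cm$modality)
  })

  labels <- tibble::tibble(
    barcode = out_bc, k = k_lab,
    call = ifelse(k_lab == 0, "singlet", "multiplet"),
    constituents = vapply(constituents, function(idx) {
      paste(bc[idx], collapse = ";")
    }, character(1))
  )
  list(matrices = if (single_input) out_mats[[1]] else out_mats,
       labels = labels)
}
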