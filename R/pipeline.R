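#' End-to-end multiplet detection
#'
#' Runs the full four-step procedure: (1) align droplets and select stable
#' features per modality, (2) fit the compound Poisson mixture and infer
#' per-droplet posteriors per modality, (3) evaluate goodness-of-fit, and
#' (4) integrate modalities with GOF- and consistency-based softmax weights.
#' With a single modality the integration step degenerates and the combined
#' posterior equals that modality's posterior.
#'
#' @param counts A [count_matrix()] or named list of them (names are ignored;
#'   modality tags come from the objects).
#' @param families Optional named list/vector overriding the per-modality
#'   contribution family (defaults: gamma for RNA and ATAC, gaussian-diag for
#'   ADT; `"gaussian-mvg"` is an ADT opt-in).
#' @param n_stable_rna,n_stable_atac Number of stable features for RNA/ATAC
#'   (default 300).
#' @param adt_stable_frac Fraction of screen-surviving ADT features kept
#'   (default 0.10).
#' @param k_max Largest modeled extra-cell count (default 2).
#' @param lambda_atac ATAC down-weighting factor (default 0.5).
#' @param zero_offset Gamma zero-handling offset (default 0.5).
#' @param control Optimizer controls passed to [fit_cp()].
#' @param seed Integer seed for optimizer restarts.
#' @param verbose Print a short log as stages complete.
#'
#' @return An object of class `multiplet_detection`: `predictions` (tibble,
#'   one row per droplet with per-modality posteriors, GOF, per-droplet
#'   weights, combined posteriors, `predicted_k`, `call`), `fits`, `gof`,
#'   `posteriors`, `combined`, `weights` (list: `overall`, `consistency`,
#'   `droplet`), `stable_features`, and `log` (character vector).
#' @export
detect_multiplets <- function(counts, families = NULL,
                              n_stable_rna = 300, n_stable_atac = 300,
                              adt_stable_frac = 0.10,
                              k_max = 2L, lambda_atac = 0.5,
                              zero_offset = 0.5, control = list(),
                              seed = 1L, verbose = FALSE) {
  if (inherits(counts, "count_matrix")) counts <- list(counts)
  stopifnot(length(counts) >= 1)
  mods <- vapply(counts, function(cm) cm$modality, character(1))
  if (anyDuplicated(mods)) stop("duplicate modality tags", call. = FALSE)
  names(counts) <- mods
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  counts <- align_droplets(counts)
  barcodes <- counts[[1]]$barcodes
  n <- length(barcodes)
  say("aligned %d droplets across %s", n, paste(mods, collapse = "+"))

  default_family <- c(RNA = "gamma", ATAC = "gamma", ADT = "gaussian-diag")
  sf <- list(); fits <- list(); gofs <- list(); posts <- list()
  Xs <- list()
  for (q in mods) {
    sf[[q]] <- if (q == "ADT") {
      select_stable_features(counts[[q]], frac = adt_stable_frac)
    } else {
      select_stable_features(counts[[q]],
                             n = if (q == "RNA") n_stable_rna else n_stable_atac)
    }
    Xs[[q]] <- stable_values(counts[[q]], sf[[q]])
    say("%s: %d stable features selected", q, ncol(Xs[[q]]))
    family <- (families[[q]] %||% default_family[[q]]) %||% "gamma"
    fits[[q]] <- fit_cp(Xs[[q]], family = family, modality = q, k_max = k_max,
                        zero_offset = zero_offset, control = control,
                        seed = seed)
    say("%s: fitted %s model, -logLik = %.2f, theta = %.4f, d = %.3f",
        q, family, -fits[[q]]$loglik, fits[[q]]$params$theta,
        fits[[q]]$params$d)
    gofs[[q]] <- gof_modality(fits[[q]], Xs[[q]])
    say("%s: GOF = %.2f (mean KS = %.4f)", q, gofs[[q]]$gof, gofs[[q]]$mean_ks)
    if (!gofs[[q]]$reliable) {
      warning(sprintf("%s GOF = %.2f <= 3: fit may be unreliable", q,
                      gofs[[q]]$gof))
    }
    posts[[q]] <- cp_posterior(fits[[q]], Xs[[q]])
  }

  if (length(mods) > 1) {
    ow <- overall_weights(
      stats::setNames(vapply(gofs, function(g) g$gof, numeric(1)), mods),
      lambda_atac = lambda_atac)
    consistency <- vapply(mods, function(q) {
      feature_consistency(fits[[q]], Xs[[q]], posts[[q]])
    }, numeric(n))
    dw <- droplet_weights(ow, consistency)
    combined <- combine_posteriors(posts, dw)
  } else {
    ow <- stats::setNames(gofs[[1]]$gof, mods)
    consistency <- matrix(1, n, 1, dimnames = list(NULL, mods))
    dw <- matrix(1, n, 1, dimnames = list(NULL, mods))
    combined <- combine_posteriors(posts, dw)
  }

  calls <- classify_droplets(combined)
  say("called %.1f%% of droplets multiplet",
      100 * mean(calls$call == "multiplet"))

  pred <- tibble::tibble(barcode = barcodes)
  for (q in mods) {
    pq <- posts[[q]]$probs
    colnames(pq) <- paste0(q, "_", colnames(pq))
    pred <- dplyr::bind_cols(pred, tibble::as_tibble(pq))
    pred[[paste0(q, "_gof")]] <- gofs[[q]]$gof
    pred[[paste0(q, "_weight")]] <- dw[, q]
  }
  pc <- combined$probs
  colnames(pc) <- paste0("combined_", colnames(pc))
  pred <- dplyr::bind_cols(pred, tibble::as_tibble(pc))
  pred$predicted_k <- calls$predicted_k
  pred$call <- calls$call

  structure(
    list(predictions = pred, fits = fits, gof = gofs, posteriors = posts,
         combined = combined, stable_features = sf,
         weights = list(overall = ow, consistency = consistency,
                        droplet = dw),
         log = log_lines),
    class = "multiplet_detection"
  )
}

#' @export
print.multiplet_detection <- function(x, ...) {
  cat(sprintf("<multiplet_detection> %d droplets, modalities: %s\n",
              nrow(x$predictions), paste(names(x$fits), collapse = ", ")))
  cat(sprintf("  multiplet calls: %d (%.1f%%)\n",
              sum(x$predictions$call == "multiplet"),
              100 * mean(x$predictions$call == "multiplet")))
  invisible(x)
}
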