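#' Construct a per-modality droplet-by-feature count matrix
#'
#' A `count_matrix` is the basic input container: a dense droplets x features
#' matrix of non-negative values together with unique droplet barcodes, unique
#' feature names, and a modality tag. RNA and ATAC gene-activity values are
#' raw (or near-raw) counts; ADT values may be any non-negative measurements.
#'
#' @param values Numeric matrix, droplets as rows and features as columns.
#'   All entries must be finite and non-negative.
#' @param barcodes Character vector of unique droplet identifiers, one per row.
#' @param features Character vector of unique feature identifiers, one per
#'   column.
#' @param modality One of `"RNA"`, `"ADT"`, `"ATAC"`.
#'
#' @return An object of class `count_matrix`: a list with elements `values`,
#'   `barcodes`, `features`, `modality`. Row and column names of `values` are
#'   set to the identifiers.
#' @export
count_matrix <- function(values, barcodes, features,
                         modality = c("RNA", "ADT", "ATAC")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must have at least one droplet and one feature", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite with no missing entries", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("`values` must be non-negative", call. = FALSE)
  }
  barcodes <- as.character(barcodes)
  features <- as.character(features)
  if (length(barcodes) != nrow(values)) {
    stop("length of `barcodes` must match the number of rows", call. = FALSE)
  }
  if (length(features) != ncol(values)) {
    stop("length of `features` must match the number of columns", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes", call. = FALSE)
  if (anyDuplicated(features)) stop("duplicate feature names", call. = FALSE)
  dimnames(values) <- list(barcodes, features)
  structure(
    list(values = values, barcodes = barcodes, features = features,
         modality = modality),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d droplets x %d features\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a count matrix from disk
#'
#' Reads either a MatrixMarket triplet layout (`matrix.mtx` with companion
#' `barcodes.tsv` and `features.tsv`, the 10x convention with features as rows
#' on disk) or a dense delimited file with a header row and an identifier
#' column. The on-disk orientation is declared explicitly and never guessed;
#' the returned matrix is always droplets x features.
#'
#' @param path For `layout = "mtx"`, the directory holding `matrix.mtx`,
#'   `barcodes.tsv` and `features.tsv`; for `layout = "dense"`, the delimited
#'   file itself (`.csv` comma, otherwise tab).
#' @param layout `"mtx"` for MatrixMarket triplet, `"dense"` for delimited.
#' @param modality Modality tag passed to [count_matrix()].
#' @param orientation `"droplets"` if droplets are rows on disk, `"features"`
#'   if features are rows (the 10x mtx convention). Default `"features"` for
#'   mtx and `"droplets"` for dense.
#'
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, layout = c("mtx", "dense"),
                        modality = c("RNA", "ADT", "ATAC"),
                        orientation = NULL) {
  layout <- match.arg(layout)
  modality <- match.arg(modality)
  if (is.null(orientation)) {
    orientation <- if (layout == "mtx") "features" else "droplets"
  }
  orientation <- match.arg(orientation, c("droplets", "features"))

  if (layout == "mtx") {
    mtx_file <- file.path(path, "matrix.mtx")
    bc_file <- file.path(path, "barcodes.tsv")
    ft_file <- file.path(path, "features.tsv")
    missing <- c(mtx_file, bc_file, ft_file)[!file.exists(c(mtx_file, bc_file, ft_file))]
    if (length(missing) > 0L) {
      stop("missing file(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(mtx_file))
    barcodes <- readr::read_tsv(bc_file, col_names = FALSE,
                                show_col_types = FALSE)[[1]]
    features <- readr::read_tsv(ft_file, col_names = FALSE,
                                show_col_types = FALSE)[[1]]
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
    row_ids <- as.character(tbl[[1]])
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- row_ids
    if (orientation == "droplets") {
      barcodes <- row_ids
      features <- colnames(m)
    } else {
      features <- row_ids
      barcodes <- colnames(m)
    }
  }

  if (orientation == "features") m <- t(m)
  if (length(barcodes) != nrow(m) || length(features) != ncol(m)) {
    stop("identifier lists do not match matrix dimensions", call. = FALSE)
  }
  count_matrix(m, barcodes, features, modality)
}

#' Restrict count matrices to their shared droplets
#'
#' The model fits all modalities on the same droplet set, so modalities are
#' restricted to the intersection of their barcodes, in a single shared
#' (lexicographically sorted) order. Sorting fixes the droplet order before
#' any fitting, making downstream results deterministic.
#'
#' @param matrices A list of [count_matrix()] objects.
#' @return A list of `count_matrix` objects with identical `barcodes`.
#' @export
align_droplets <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  shared <- purrr::reduce(purrr::map(matrices, "barcodes"), intersect)
  if (length(shared) == 0L) {
    stop("no droplet barcodes shared across all matrices", call. = FALSE)
  }
  shared <- sort(shared)
  purrr::map(matrices, function(cm) {
    count_matrix(cm$values[shared, , drop = FALSE], shared, cm$features,
                 cm$modality)
  })
}

#' Write (and read back) per-droplet prediction tables
#'
#' Predictions are serialized as TSV with full double precision, so a
#' round-trip read reproduces every numeric column exactly.
#'
#' @param predictions A tibble with one row per droplet, as produced by
#'   [detect_multiplets()].
#' @param path Output file path.
#' @return `predictions`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(is.data.frame(predictions), nrow(predictions) >= 1L)
  readr::write_tsv(predictions, path)
  invisible(predictions)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
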