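#' Labelled tabular dataset
#'
#' The basic container consumed by every model in the package: an `N x D`
#' numeric feature matrix with integer class labels in `0..K-1`. Class counts
#' `N_k` are stored alongside because the reward weights and the
#' cost-sensitive baseline both derive from them.
#'
#' @param features numeric matrix (`N x D`), all values finite.
#' @param labels integer vector of class indices in `0..K-1`, or a factor /
#'   character vector which is mapped to indices in first-appearance order.
#' @param K number of classes; defaults to `max(labels) + 1`. Classes must all
#'   be present at least once.
#' @param label_map optional character vector giving the original level for
#'   each class index (names for reporting; filled automatically for
#'   factor/character labels).
#'
#' @return an object of class `labeled_dataset` with fields `features`,
#'   `labels`, `class_counts`, `K`, `D`, `n`, `label_map`.
#' @export
labeled_dataset <- function(features, labels, K = NULL, label_map = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.character(labels) || is.factor(labels)) {
    lev <- unique(as.character(labels))
    if (is.null(label_map)) label_map <- lev
    labels <- match(as.character(labels), lev) - 1L
  }
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features has ", nrow(features), " rows but labels has length ", length(labels))
  if (nrow(features) == 0L) stop("empty dataset")
  if (any(!is.finite(features)))
    stop("features contain non-finite values; impute or drop them upstream")
  if (any(labels < 0L)) stop("negative label index")
  if (is.null(K)) K <- max(labels) + 1L
  K <- as.integer(K)
  if (any(labels >= K)) stop("label index >= K (", K, ")")
  counts <- tabulate(labels + 1L, nbins = K)
  if (any(counts == 0L))
    stop("class(es) ", paste(which(counts == 0L) - 1L, collapse = ", "),
         " absent from the data; every class must be present at least once")
  if (is.null(label_map)) label_map <- as.character(seq_len(K) - 1L)
  structure(
    list(features = features, labels = labels, class_counts = counts,
         K = K, D = ncol(features), n = nrow(features),
         label_map = as.character(label_map)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, %d classes\n", x$n, x$D, x$K))
  prev <- x$class_counts / x$n
  for (k in seq_len(x$K))
    cat(sprintf("  class %d (%s): n=%d (%.1f%%)\n", k - 1L, x$label_map[k],
                x$class_counts[k], 100 * prev[k]))
  invisible(x)
}

#' Read a labelled dataset from CSV
#'
#' Expects a header row; every column other than the label column is treated
#' as a numeric feature. String labels are mapped to class indices in
#' first-appearance order and the mapping is persisted to a JSON sidecar
#' (`<path>.labels.json`) so that a saved model and its data stay in sync.
#'
#' @param path CSV file path.
#' @param label_col name of the label column (default `"label"`).
#' @param write_sidecar write the label-mapping sidecar (default TRUE when the
#'   labels are non-integer).
#' @return a [labeled_dataset].
#' @export
read_dataset_csv <- function(path, label_col = "label", write_sidecar = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found in ", path)
  y <- df[[label_col]]
  x <- as.matrix(df[setdiff(names(df), label_col)])
  if (is.character(y) || is.factor(y)) {
    lev <- unique(as.character(y))
    ds <- labeled_dataset(x, y, label_map = lev)
    if (write_sidecar) {
      sidecar <- paste0(path, ".labels.json")
      jsonlite::write_json(
        list(label_col = label_col,
             classes = data.frame(index = seq_along(lev) - 1L, level = lev)),
        sidecar, auto_unbox = TRUE)
    }
    ds
  } else {
    labeled_dataset(x, as.integer(y))
  }
}

#' Write a labelled dataset to CSV
#'
#' Inverse of [read_dataset_csv()]: features as numeric columns plus one label
#' column. Original label levels (if any) are written back so the round trip
#' is lossless.
#'
#' @param dataset a [labeled_dataset].
#' @param path output CSV path.
#' @param label_col label column name.
#' @export
write_dataset_csv <- function(dataset, path, label_col = "label") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(dataset$features)
  if (is.null(colnames(dataset$features)))
    names(df) <- paste0("x", seq_len(dataset$D))
  labs <- dataset$label_map[dataset$labels + 1L]
  # keep integer labels integer so read.csv round-trips without a sidecar
  if (identical(dataset$label_map, as.character(seq_len(dataset$K) - 1L)))
    labs <- dataset$labels
  df[[label_col]] <- labs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Standardise features to zero mean / unit variance (optional upstream step)
#' @param x feature matrix.
#' @param center,scale vectors from a training split; computed when NULL.
#' @return list with `x`, `center`, `scale`.
#' @keywords internal
zscale <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"), center = center, scale = scale)
}
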