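#' Build a wells-by-samples profile matrix
#'
#' Stacks raw MI vectors (one row per well) with optional block-mean
#' downsampling: with `downsample_factor = k`, each output column is the
#' mean of k consecutive MI samples (a trailing partial block is dropped).
#' At 25 Hz, `k = 25` gives per-second means.
#'
#' @param traces list of [well_trace()] or numeric vectors, equal lengths
#' @param classes character/factor label per well
#' @param downsample_factor positive integer block size (default 1)
#' @return A `profile_matrix`: numeric matrix with `rownames` = well index
#'   and a `classes` attribute (factor).
#' @export
build_profile_matrix <- function(traces, classes, downsample_factor = 1L) {
  vecs <- lapply(traces, function(tr) if (inherits(tr, "well_trace")) tr$mi else tr)
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) stop("all traces must have the same length")
  if (length(classes) != length(vecs)) stop("one class label per trace required")
  k <- as.integer(downsample_factor)
  stopifnot(k >= 1L)
  n_blocks <- lens[1] %/% k
  if (n_blocks < 1L) stop("downsample factor exceeds trace length")
  m <- do.call(rbind, lapply(vecs, function(v) {
    if (k == 1L) v else colMeans(matrix(v[seq_len(n_blocks * k)], nrow = k))
  }))
  rownames(m) <- names(vecs) %||% as.character(seq_along(vecs))
  if (anyNA(m)) stop("profile matrix contains missing values")
  structure(m, classes = factor(classes), class = c("profile_matrix", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-forest classification of behavioral profiles
#'
#' Fits a multiclass random forest (500 trees by default) under stratified
#' k-fold cross-validation and returns the out-of-sample confusion matrix
#' (rows = true class, columns = predicted) with per-class recall. Results
#' are deterministic under `seed` and independent of any parallelism.
#'
#' @param matrix a [build_profile_matrix()] result (or a plain matrix with
#'   `classes` passed separately)
#' @param classes class labels; defaults to the matrix's `classes` attribute
#' @param n_trees number of trees (default 500)
#' @param cv_folds stratified folds (default 5); every class must have at
#'   least `cv_folds` wells
#' @param seed RNG seed
#' @return list: `counts` (true x predicted matrix), `recall` (named),
#'   `accuracy`, `folds`, `n_trees`.
#' @export
classify_profiles <- function(matrix, classes = attr(matrix, "classes"),
                              n_trees = 500L, cv_folds = 5L, seed = 1L) {
  y <- factor(classes)
  x <- unclass(matrix)
  attr(x, "classes") <- NULL
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab < cv_folds)) {
    stop("every class needs at least cv_folds wells; short: ",
         paste(names(tab)[tab < cv_folds], collapse = ", "))
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                      ntree = n_trees)
    pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
  }
  counts <- table(true = y, predicted = pred)
  recall <- diag(counts) / rowSums(counts)
  list(counts = unclass(counts), recall = recall,
       accuracy = sum(diag(counts)) / length(y),
       folds = cv_folds, n_trees = n_trees)
}
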