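#' 2-D stochastic neighbor embedding of behavioral profiles
#'
#' Exact (dense) t-SNE: Gaussian input affinities calibrated per point to a
#' target perplexity by binary search, Student-t output kernel, gradient
#' descent with momentum and early exaggeration. O(n^2) per iteration,
#' intended for the tens-to-hundreds of wells produced by plate screens.
#' Deterministic under `seed`. Duplicate profiles describe the same point in
#' behavior space: unique rows are embedded and duplicates share their
#' first occurrence's coordinates exactly.
#'
#' @param matrix a [build_profile_matrix()] result or plain numeric matrix
#'   (rows = wells)
#' @param perplexity target perplexity; must satisfy `3 * perplexity < n - 1`
#' @param seed RNG seed
#' @param n_iter gradient-descent iterations (default 500)
#' @param learning_rate step size (default `max(n / 12, 50)`)
#' @param init `"pca"` (default) initializes from the first two principal
#'   components scaled small, making the layout reproducible across seeds;
#'   `"random"` uses a seeded Gaussian start.
#' @return numeric `n x 2` matrix of embedding coordinates, rownames kept.
#' @export
embed_2d <- function(matrix, perplexity = 30, seed = 1L, n_iter = 500L,
                     learning_rate = NULL, init = c("pca", "random")) {
  init <- match.arg(init)
  x <- unclass(matrix)
  attr(x, "classes") <- NULL
  n_all <- nrow(x)
  if (n_all < 3L) stop("need at least 3 wells to embed")
  if (perplexity >= n_all) stop("perplexity must be smaller than the number of wells")
  # identical profiles are one point in behavior space: embed unique rows
  # and give duplicates the shared coordinate
  key <- apply(x, 1L, paste, collapse = "\r")
  first <- match(key, key)
  uniq <- which(first == seq_len(n_all))
  if (length(uniq) < 3L) {
    y_all <- base::matrix(0, n_all, 2L,
                          dimnames = list(rownames(x), c("dim1", "dim2")))
    return(y_all)
  }
  x <- x[uniq, , drop = FALSE]
  n <- nrow(x)
  if (3 * perplexity > n - 1) perplexity <- (n - 1) / 3
  if (is.null(learning_rate)) learning_rate <- max(n / 12, 50)

  # squared euclidean distances
  ss <- rowSums(x^2)
  d2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(x), 0)
  diag(d2) <- 0

  P <- .perplexity_affinities(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  if (init == "pca") {
    xc <- sweep(x, 2L, colMeans(x))
    sv <- svd(xc, nv = 0L)
    k <- min(2L, ncol(sv$u))
    y <- matrix(0, n, 2L)
    y[, seq_len(k)] <- sv$u[, seq_len(k), drop = FALSE] *
      rep(sv$d[seq_len(k)], each = n)
    # fix the SVD sign ambiguity so the start is reproducible
    for (j in 1:2) if (y[which.max(abs(y[, j])), j] < 0) y[, j] <- -y[, j]
    scale <- max(stats::sd(y[, 1]), .Machine$double.eps)
    y <- y / scale * 1e-4
  } else {
    y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
  }
  gains <- matrix(1, n, 2L)
  inc <- matrix(0, n, 2L)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    exaggeration <- if (it <= 100L) 12 else 1
    yss <- rowSums(y^2)
    num <- 1 / (1 + pmax(outer(yss, yss, "+") - 2 * tcrossprod(y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (exaggeration * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% y - W %*% y)
    gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8), 0.01)
    inc <- momentum * inc - learning_rate * gains * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
    if (it == 250L) momentum <- 0.8
  }
  y_all <- y[match(first, uniq), , drop = FALSE]
  rownames(y_all) <- if (!is.null(rownames(x))) rownames(unclass(matrix)) else NULL
  colnames(y_all) <- c("dim1", "dim2")
  y_all
}

# Binary-search per-point Gaussian bandwidths to the target perplexity
.perplexity_affinities <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; p <- w } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
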