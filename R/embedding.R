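#' Delay-coordinate state-space embedding
#'
#' Reconstructs state-space vectors from a scalar series by the method of
#' delays: vector `i` (1-based) is `(x[i], x[i + tau], ..., x[i + (m-1)*tau])`,
#' giving `N - (m - 1) * tau` vectors for a series of length `N`.
#'
#' @param signal An [ts_signal()] object or numeric vector.
#' @param m Embedding dimension (positive integer).
#' @param tau Time delay in samples (positive integer).
#' @return An object of class `embedding`: a numeric matrix with one row per
#'   state vector and `m` columns, with attributes `m`, `tau` and
#'   `baseline_removed`.
#' @examples
#' emb <- embed_signal(ts_signal(1:10, fs = 1), m = 3, tau = 1)
#' nrow(emb)  # 8
#' @seealso [embed_baseline()] for the baseline-removed variant used by
#'   fuzzy entropy, [distance_matrix()].
#' @export
embed_signal <- function(signal, m, tau = 1L) {
  x <- as_ts_signal(signal, fs = 1)$samples
  m <- check_count(m, "m")
  tau <- check_count(tau, "tau")
  n_vec <- length(x) - (m - 1L) * tau
  if (n_vec < 2L)
    stop(sprintf(
      "insufficient length: N = %d allows %d embedding vectors for m = %d, tau = %d (need >= 2)",
      length(x), max(n_vec, 0L), m, tau))
  mat <- vapply(seq_len(m) - 1L,
                function(k) x[seq_len(n_vec) + k * tau],
                numeric(n_vec))
  if (n_vec == 1L) mat <- matrix(mat, nrow = 1L)
  new_embedding(mat, m, tau, baseline_removed = FALSE)
}

#' Baseline-removed embedding for fuzzy entropy
#'
#' Forms the `N - m + 1` consecutive-sample vectors of order `m` and removes
#' from each its own mean (the local baseline), so every returned vector sums
#' to zero. This is the vector construction fuzzy entropy similarity degrees
#' are computed on; it uses consecutive samples (delay fixed at 1).
#'
#' @inheritParams embed_signal
#' @return An `embedding` with `N - m + 1` zero-mean rows of length `m`.
#' @examples
#' embed_baseline(ts_signal(c(1, 3, 2, 4), fs = 1), m = 2)
#' @export
embed_baseline <- function(signal, m) {
  x <- as_ts_signal(signal, fs = 1)$samples
  m <- check_count(m, "m")
  n_vec <- length(x) - m + 1L
  if (n_vec < 2L)
    stop(sprintf(
      "insufficient length: N = %d yields %d baseline-removed vectors of order m = %d (need >= 2)",
      length(x), max(n_vec, 0L), m))
  mat <- vapply(seq_len(m) - 1L,
                function(k) x[seq_len(n_vec) + k],
                numeric(n_vec))
  if (n_vec == 1L) mat <- matrix(mat, nrow = 1L)
  mat <- mat - rowMeans(mat)
  new_embedding(mat, m, 1L, baseline_removed = TRUE)
}

new_embedding <- function(mat, m, tau, baseline_removed) {
  structure(mat, m = as.integer(m), tau = as.integer(tau),
            baseline_removed = baseline_removed,
            class = c("embedding", "matrix", "array"))
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d vectors, m = %d, tau = %d%s\n",
              nrow(x), attr(x, "m"), attr(x, "tau"),
              if (isTRUE(attr(x, "baseline_removed"))) ", baseline removed" else ""))
  invisible(x)
}

#' Condensed inter-vector distance matrix
#'
#' Computes pairwise distances between all unordered pairs `i < j` of
#' embedding vectors. Self-distances are excluded: both entropy estimators
#' take their empirical distance distribution over off-diagonal elements
#' only, and including the zero diagonal would spike the first histogram
#' bin.
#'
#' @param emb An [embed_signal()] / [embed_baseline()] result, or a plain
#'   numeric matrix of row vectors.
#' @param metric `"chebyshev"` (maximum absolute component difference; used
#'   by fuzzy and distribution entropy) or `"euclidean"` (used by
#'   modified-distribution entropy).
#' @return An object of class `distance_matrix`: a numeric vector of the
#'   `n * (n - 1) / 2` condensed distances ordered by `i` then `j`
#'   (column-major lower triangle, as [stats::dist()]), with attributes
#'   `metric` and `n_vectors`.
#' @examples
#' d <- distance_matrix(rbind(c(0, 0), c(3, 4)), "euclidean")
#' as.numeric(d)  # 5
#' @export
distance_matrix <- function(emb, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.matrix(emb)) stop("emb must be an embedding or numeric matrix")
  if (nrow(emb) < 2L)
    stop("need at least 2 vectors to form pairwise distances, got ", nrow(emb))
  d <- stats::dist(emb, method = if (metric == "chebyshev") "maximum" else "euclidean")
  structure(as.numeric(d), metric = metric, n_vectors = nrow(emb),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s, %d vectors, %d pairwise distances\n",
              attr(x, "metric"), attr(x, "n_vectors"), length(x)))
  invisible(x)
}

# positive integer scalar check shared by embedding/entropy code
check_count <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
      v != as.integer(v))
    stop(name, " must be a single positive integer")
  as.integer(v)
}
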