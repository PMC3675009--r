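#' Principal-component embedding of distance-matrix rows
#'
#' Each row of a subset's distance matrix describes how one structure
#' differs from all others on that subset; the rows are highly redundant,
#' so a principal-component projection retains most of the information in a
#' handful of dimensions.  To keep heavily crystallised sequences from
#' dominating the fit, rows are weighted inversely by the number of
#' structures sharing their sequence.
#'
#' The retained dimensionality is the smallest reaching `variance_target`
#' (default 0.90), capped at `d_max` (default 10).  Component signs follow
#' a canonical convention (largest-magnitude loading positive) so repeated
#' runs are byte-identical.
#'
#' @param dm symmetric N x N distance matrix (e.g. [distance_matrix()]).
#' @param weights optional non-negative row weights, length N (default
#'   equal weights).
#' @param variance_target fraction of (weighted) variance to retain.
#' @param d_max dimensionality cap.
#' @return a `triad_embedding`: list with `coordinates` (N x d matrix,
#'   rownames = structure ids), `explained_variance_fraction`, `d`.
#' @export
embed_rows <- function(dm, weights = NULL, variance_target = 0.90,
                       d_max = 10) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  assert_that(n >= 2L, "need at least 2 structures to embed")
  assert_that(max(abs(dm - t(dm))) < 1e-9, "distance matrix must be symmetric")
  w <- weights %||% rep(1, n)
  assert_that(length(w) == n && all(w > 0), "bad row weights")
  w <- w / sum(w)
  mu <- colSums(dm * w)
  xc <- sweep(dm, 2, mu)
  sv <- svd(xc * sqrt(w))
  ev <- sv$d^2
  total <- sum(ev)
  if (total <= .Machine$double.eps) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(dm), NULL))
    return(structure(list(coordinates = coords,
                          explained_variance_fraction = 1, d = 1L),
                     class = "triad_embedding"))
  }
  cum <- cumsum(ev) / total
  d <- min(max(1L, which(cum >= variance_target)[1]), d_max, n)
  V <- sv$v[, seq_len(d), drop = FALSE]
  # canonical sign: largest-magnitude loading of each component positive
  for (j in seq_len(d)) {
    pivot <- which.max(abs(V[, j]))
    if (V[pivot, j] < 0) V[, j] <- -V[, j]
  }
  coords <- xc %*% V
  rownames(coords) <- rownames(dm)
  structure(list(coordinates = coords,
                 explained_variance_fraction = cum[d], d = d),
            class = "triad_embedding")
}

#' @export
print.triad_embedding <- function(x, ...) {
  cat("<triad_embedding> ", nrow(x$coordinates), " points in ", x$d,
      " dims (", round(100 * x$explained_variance_fraction, 1),
      "% variance)\n", sep = "")
  invisible(x)
}

#' Silhouette scores in embedding space
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` with Euclidean
#' distance, where `a` is the mean distance to the point's own cluster and
#' `b` the smallest mean distance to another cluster.  Singleton clusters
#' score 0; with a single cluster every score is 0 by convention.
#'
#' @param coords N x d coordinate matrix.
#' @param assignments integer cluster ids (0-based), length N.
#' @return list with `per_point` (length N, in `[-1, 1]`) and
#'   `per_cluster` (named by cluster id, mean over members).
#' @export
silhouette_scores <- function(coords, assignments) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  assert_that(length(assignments) == n, "one assignment per point")
  ids <- sort(unique(assignments))
  k <- length(ids)
  per_cluster_of <- function(s) {
    vapply(ids, function(cl) mean(s[assignments == cl]), numeric(1)) |>
      setNames(ids)
  }
  if (k == 1L) {
    s <- rep(0, n)
    return(list(per_point = s, per_cluster = per_cluster_of(s)))
  }
  d2 <- outer(rowSums(coords^2), rep(1, n)) +
    outer(rep(1, n), rowSums(coords^2)) - 2 * coords %*% t(coords)
  dd <- sqrt(pmax(d2, 0))
  sizes <- table(factor(assignments, levels = ids))
  # mean distance from every point to every cluster
  member <- vapply(ids, function(cl) as.numeric(assignments == cl),
                   numeric(n))
  sums <- dd %*% member                      # n x k total distance
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(assignments[i], ids)
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1L)
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(per_point = s, per_cluster = per_cluster_of(s))
}
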