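# independent oracles and small fixture builders used across tests

# rotation matrix from Euler angles (z-y-x convention)
euler_rotation <- function(a, b, c) {
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(c), -sin(c)), c(0, sin(c), cos(c)))
  Rz %*% Ry %*% Rx
}

# brute-force least RMSD: dense Euler-angle grid refined by Nelder-Mead,
# fully independent of the package's closed-form solution
brute_lrmsd <- function(a, b, n_grid = 14) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  obj <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  best_val <- Inf
  best_p <- NULL
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) {
      best_val <- v
      best_p <- c(a1, a2, a3)
    }
  }
  opt <- stats::optim(best_p, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(best_val, opt$value)
}

random_rotation <- function() {
  euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi),
                 runif(1, 0, 2 * pi))
}

# hand-buildable clustering pass: one subset, explicit assignments and
# cluster silhouettes, for exercising HPC selection in isolation
fake_clusterings <- function(structure_ids, assignments,
                             cluster_sil = NULL, subset = c(0L, 1L, 2L)) {
  ids <- sort(unique(assignments))
  if (is.null(cluster_sil)) cluster_sil <- setNames(rep(0.5, length(ids)), ids)
  out <- tibble::tibble(
    subset_id = 1L, c1 = subset[1], c2 = subset[2], c3 = subset[3],
    K = length(ids), model = "VII",
    assignments = list(setNames(as.integer(assignments), structure_ids)),
    per_point_silhouette = list(rep(0.5, length(assignments))),
    per_cluster_mean_silhouette = list(cluster_sil))
  attr(out, "structure_ids") <- structure_ids
  class(out) <- c("triad_clusterings", class(out))
  out
}

# minimal aligned set: one structure per sequence, arbitrary geometry
toy_set <- function(sequence_ids, families = NULL, P = 3) {
  families <- families %||% rep("famA", length(sequence_ids))
  rows <- purrr::map2(sequence_ids, families, function(sq, fam) {
    tibble::tibble(structure_id = paste0(sq, "_x1"), sequence_id = sq,
                   family = fam, column = 0:(P - 1),
                   residue = rep("A", P),
                   x = seq_len(P) + match(sq, sequence_ids),
                   y = 0, z = 0)
  })
  aligned_structure_set(dplyr::bind_rows(rows), 0:(P - 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
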