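#' Gaussian-mixture clustering of an embedding
#'
#' Fits Gaussian mixtures over a grid of component counts and covariance
#' families and selects the model by BIC, so the number of clusters need
#' not be known beforehand.  Fitting goes through mclust, whose
#' deterministic model-based hierarchical initialisation makes repeated
#' runs reproducible.  Covariance families cover spherical, diagonal and
#' full shapes (mclust models VII, VVI, VVV; E/V in one dimension).  BIC
#' ties resolve to the smaller component count, then the simpler family.
#'
#' The K grid is explored in blocks and stops early once a whole block
#' fails to improve the best BIC, which skips most of the grid on the
#' common single-blob subsets without affecting the selected model.
#'
#' @param e a `triad_embedding` (or bare coordinate matrix).
#' @param k_max largest component count considered (default 25, capped at
#'   N - 1).
#' @param seed optional integer seed (fitting is deterministic either way;
#'   the seed guards any future stochastic initialisation).
#' @param subset optional column triple carried through to the result.
#' @return a `subset_clustering`: list with `assignments` (0-based integer
#'   cluster ids named by structure id), `K`, `model` (covariance family
#'   chosen), `bic`, `per_point_silhouette`, `per_cluster_mean_silhouette`,
#'   `subset`.
#' @export
cluster_gmm <- function(e, k_max = 25, seed = NULL, subset = NULL) {
  coords <- if (inherits(e, "triad_embedding")) e$coordinates else as.matrix(e)
  n <- nrow(coords)
  assert_that(n >= 2L, "need at least 2 points to cluster")
  fit <- if (is.null(seed)) {
    .fit_gmm_bic(coords, k_max)
  } else {
    with_seed(seed, .fit_gmm_bic(coords, k_max))
  }
  assignments <- fit$classification - 1L
  names(assignments) <- rownames(coords)
  sil <- silhouette_scores(coords, assignments)
  structure(list(assignments = assignments, K = fit$G, model = fit$model,
                 bic = fit$bic, coordinates = coords,
                 per_point_silhouette = sil$per_point,
                 per_cluster_mean_silhouette = sil$per_cluster,
                 subset = subset),
            class = "subset_clustering")
}

#' @export
print.subset_clustering <- function(x, ...) {
  cat("<subset_clustering> K = ", x$K, " (", x$model, "), N = ",
      length(x$assignments), "\n", sep = "")
  invisible(x)
}

# model preference order (simpler first) used for tie-breaking; the
# equal-variance spherical model (EII) is included because it is the only
# family that can represent singleton components (outlier conformations)
# without a degenerate covariance
.gmm_models <- function(d) {
  if (d == 1L) c("E", "V") else c("EII", "VII", "VVI", "VVV")
}

.fit_gmm_bic <- function(coords, k_max, block = 6L, patience = 1L) {
  n <- nrow(coords)
  d <- ncol(coords)
  x <- if (d == 1L) coords[, 1] else coords
  # degenerate: all points (nearly) identical -> one cluster
  if (max(apply(coords, 2, function(v) diff(range(v)))) < 1e-12) {
    return(list(classification = rep(1L, n), G = 1L, model = "EII",
                bic = NA_real_))
  }
  models <- .gmm_models(d)
  k_cap <- max(1L, min(k_max, n - 1L))
  best <- NULL
  blocks_since_improvement <- 0L
  g_lo <- 1L
  while (g_lo <= k_cap) {
    g_hi <- min(g_lo + block - 1L, k_cap)
    bic <- suppressWarnings(
      mclustBIC(x, G = g_lo:g_hi, modelNames = models,
                        verbose = FALSE))
    improved <- FALSE
    for (g in g_lo:g_hi) {
      for (m in models) {
        val <- tryCatch(bic[as.character(g), m], error = function(e) NA)
        if (is.null(val) || is.na(val)) next
        # strict improvement required, so ties keep smaller K / simpler family
        if (is.null(best) || val > best$bic + 1e-9) {
          best <- list(G = g, model = m, bic = val)
          improved <- TRUE
        }
      }
    }
    blocks_since_improvement <-
      if (improved) 0L else blocks_since_improvement + 1L
    if (blocks_since_improvement > patience) break
    g_lo <- g_hi + 1L
  }
  assert_that(!is.null(best), "all mixture fits failed")
  fit <- suppressWarnings(
    Mclust(x, G = best$G, modelNames = best$model, verbose = FALSE))
  assert_that(!is.null(fit), "refit of the selected mixture failed")
  list(classification = as.integer(fit$classification), G = fit$G,
       model = best$model, bic = best$bic)
}

#' Cluster every position subset of a structure set
#'
#' Runs the full combinatorial pass: for each 3-column subset of the site,
#' computes the pairwise substructure distance matrix, embeds its rows and
#' fits the BIC-selected Gaussian mixture.  Clusterings are unsupervised
#' and depend only on the structures, so one pass serves every compound
#' (and every cross-validation fold, which only re-masks labels).
#'
#' @param set an `aligned_set`.
#' @param subsets optional integer matrix of column triples (rows), e.g.
#'   from [enumerate_subsets()]; defaults to all
#'   `choose(P, 3)` subsets of `set$position_columns`.
#' @param matrix pharmacophore matrix.
#' @param w_struct,w_pharm distance-term weights.
#' @param variance_target,d_max embedding parameters (see [embed_rows()]).
#' @param k_max mixture-size cap (see [cluster_gmm()]).
#' @param seed master seed; each subset derives its own seed from it, so
#'   results are identical however the loop is partitioned.
#' @param progress print a progress line every 250 subsets.
#' @return a `triad_clusterings`: tibble with one row per subset
#'   (`subset_id`, `c1`, `c2`, `c3`, `K`, `model`) and list-columns
#'   `assignments`, `per_point_silhouette`, `per_cluster_mean_silhouette`;
#'   attribute `structure_ids` carries the common structure order.
#' @export
cluster_subsets <- function(set, subsets = NULL,
                            matrix = default_pharm_matrix(),
                            w_struct = 1, w_pharm = 1,
                            variance_target = 0.90, d_max = 10,
                            k_max = 25, seed = 1, progress = FALSE) {
  arrays <- as_site_arrays(set)
  if (is.null(subsets)) {
    subsets <- enumerate_subsets(set$position_columns, 3)
  }
  subsets <- base::matrix(as.integer(subsets), nrow = nrow(subsets))
  st <- structure_table(set)
  st <- st[match(arrays$structure_ids, st$structure_id), ]
  # overrepresentation correction: weight each structure by 1 / (number of
  # structures of the same sequence)
  seq_counts <- table(st$sequence_id)
  w <- 1 / as.numeric(seq_counts[st$sequence_id])
  rows <- vector("list", nrow(subsets))
  for (i in seq_len(nrow(subsets))) {
    sub <- subsets[i, ]
    dm <- distance_matrix(arrays, sub, matrix, w_struct, w_pharm)
    emb <- embed_rows(dm, weights = w, variance_target = variance_target,
                      d_max = d_max)
    # per-subset seed keyed by the column tuple itself, so any partition
    # of the subset loop (e.g. across workers) reproduces the same fits
    tuple_key <- (as.double(sub[1]) * 331 + sub[2]) * 331 + sub[3]
    cl <- cluster_gmm(emb, k_max = k_max,
                      seed = derive_seed(seed, tuple_key), subset = sub)
    rows[[i]] <- tibble::tibble(
      subset_id = i, c1 = sub[1], c2 = sub[2], c3 = sub[3],
      K = cl$K, model = cl$model,
      assignments = list(cl$assignments),
      per_point_silhouette = list(cl$per_point_silhouette),
      per_cluster_mean_silhouette = list(cl$per_cluster_mean_silhouette))
    if (progress && i %% 250L == 0L) {
      message("clustered ", i, "/", nrow(subsets), " subsets")
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "structure_ids") <- arrays$structure_ids
  class(out) <- c("triad_clusterings", class(out))
  out
}

#' Cluster membership tables
#'
#' Flattens a clustering pass into long tables used by the purity and
#' voting stages.
#'
#' @param clusterings a `triad_clusterings` from [cluster_subsets()].
#' @param set the `aligned_set` the pass was computed on.
#' @return list of tibbles: `structures` (subset_id, cluster_id,
#'   structure_id, sequence_id), `sequences` (distinct sequence-level
#'   membership), and `clusters` (subset_id, cluster_id,
#'   mean_silhouette).
#' @export
membership_tables <- function(clusterings, set) {
  ids <- attr(clusterings, "structure_ids")
  st <- structure_table(set)
  seq_of <- setNames(st$sequence_id, st$structure_id)
  n <- length(ids)
  structures <- tibble::tibble(
    subset_id = rep(clusterings$subset_id, each = n),
    structure_id = rep(ids, times = nrow(clusterings)),
    cluster_id = unlist(clusterings$assignments, use.names = FALSE))
  structures$sequence_id <- unname(seq_of[structures$structure_id])
  sequences <- dplyr::distinct(structures, .data$subset_id,
                               .data$cluster_id, .data$sequence_id)
  clusters <- clusterings |>
    dplyr::select("subset_id", "per_cluster_mean_silhouette") |>
    tibble::as_tibble() |>
    dplyr::mutate(cluster = purrr::map(.data$per_cluster_mean_silhouette,
                                       function(s) {
                                         tibble::tibble(
                                           cluster_id = as.integer(names(s)),
                                           mean_silhouette = unname(s))
                                       })) |>
    dplyr::select("subset_id", "cluster") |>
    tidyr::unnest("cluster")
  list(structures = structures, sequences = sequences, clusters = clusters)
}
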