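#' Label purity of a multiset
#'
#' Purity is the multiplicity of the most frequent known label divided by
#' the number of known labels; `"unknown"`/`NA` labels are disregarded.
#' Ties resolve by fixed label order (`"false"` before `"true"`, otherwise
#' alphabetical) so results are deterministic.
#'
#' @param labels character vector of labels (may include `"unknown"`/`NA`).
#' @return list with `purity` in (0, 1], `majority` label, `n_known`.
#' @export
#' @examples
#' label_purity(c("true", "true", "false"))          # 2/3, "true"
#' label_purity(c("AGC", "CAMK", "TK"))              # 1/3
#' label_purity(c("true", "true", "unknown", NA))    # 1.0, "true"
label_purity <- function(labels) {
  known <- labels[!is.na(labels) & labels != "unknown"]
  assert_that(length(known) > 0L, "no known labels in multiset")
  counts <- table(known)
  counts <- counts[order(-counts, names(counts))]
  list(purity = as.numeric(counts[1]) / length(known),
       majority = names(counts)[1],
       n_known = length(known))
}

# Per-cluster label statistics for one compound, sequence-weighted: each
# sequence contributes one known label regardless of how many structures it
# has.  Returns one row per cluster that has >= 1 known-label member.
.cluster_label_stats <- function(members, labels_by_seq,
                                 weight = c("sequence", "structure")) {
  weight <- match.arg(weight)
  unit <- if (weight == "sequence") "sequence_id" else "structure_id"
  m <- members
  m$label <- unname(labels_by_seq[m$sequence_id])
  m$label[is.na(m$label)] <- "unknown"
  known <- dplyr::filter(m, .data$label != "unknown")
  if (weight == "sequence") {
    known <- dplyr::distinct(known, .data$subset_id, .data$cluster_id,
                             .data$sequence_id, .data$label)
  }
  if (nrow(known) == 0L) {
    return(tibble::tibble(subset_id = integer(), cluster_id = integer(),
                          purity = numeric(), majority_label = character(),
                          n_known = integer()))
  }
  known |>
    dplyr::count(.data$subset_id, .data$cluster_id, .data$label) |>
    dplyr::group_by(.data$subset_id, .data$cluster_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label, .by_group = TRUE) |>
    dplyr::summarise(purity = .data$n[1] / sum(.data$n),
                     majority_label = .data$label[1],
                     n_known = sum(.data$n), .groups = "drop")
}

#' Select highly predictive clusters (HPCs)
#'
#' A cluster is highly predictive when its known labels are pure at or
#' above `purity_threshold` (default 1.0, the strictest possible), its
#' mean silhouette is at least `min_mean_silhouette` (default 0, removing
#' malformed clusters with negative scores), and it has at least one
#' known-label member.  Clusters whose members are all unlabeled are
#' skipped; their members can still receive votes as test points.
#'
#' Purity counting is sequence-weighted by default (one vote per sequence,
#' however many structures it has); structure-level counting is available
#' for ablation.
#'
#' @param clusterings a `triad_clusterings` (or precomputed
#'   [membership_tables()] list).
#' @param set the `aligned_set`.
#' @param labels label table tibble (`sequence_id`, `compound_id`,
#'   `label`).
#' @param compound_id compound whose labels to use.
#' @param purity_threshold minimum purity, in (0, 1].
#' @param min_mean_silhouette minimum cluster mean silhouette.
#' @param weight `"sequence"` (default) or `"structure"` purity counting.
#' @return tibble of HPC records: `subset_id`, `c1..c3`, `cluster_id`,
#'   `majority_label`, `purity`, `mean_silhouette`, `n_known`,
#'   `n_families`, and list-columns `member_sequence_ids`,
#'   `member_structure_ids`, `family_set`.
#' @export
select_hpcs <- function(clusterings, set, labels, compound_id,
                        purity_threshold = 1.0, min_mean_silhouette = 0.0,
                        weight = c("sequence", "structure")) {
  weight <- match.arg(weight)
  mem <- if (is.data.frame(clusterings)) {
    membership_tables(clusterings, set)
  } else clusterings
  lab <- compound_labels(labels, compound_id)
  stats <- .cluster_label_stats(mem$structures, lab, weight)
  stats <- dplyr::left_join(stats, mem$clusters,
                            by = c("subset_id", "cluster_id"))
  hpc <- dplyr::filter(stats,
                       .data$purity >= purity_threshold,
                       .data$mean_silhouette >= min_mean_silhouette,
                       .data$n_known >= 1L)
  st <- structure_table(set)
  fam_of <- setNames(st$family, st$sequence_id)
  members <- mem$structures |>
    dplyr::inner_join(hpc[, c("subset_id", "cluster_id")],
                      by = c("subset_id", "cluster_id")) |>
    dplyr::group_by(.data$subset_id, .data$cluster_id) |>
    dplyr::summarise(
      member_structure_ids = list(sort(unique(.data$structure_id))),
      member_sequence_ids = list(sort(unique(.data$sequence_id))),
      .groups = "drop")
  out <- dplyr::left_join(hpc, members, by = c("subset_id", "cluster_id"))
  out$family_set <- purrr::map(out$member_sequence_ids, function(sq) {
    fams <- unique(unname(fam_of[sq]))
    sort(fams[!is.na(fams) & fams != "unknown"])
  })
  out$n_families <- lengths(out$family_set)
  cols <- if (is.data.frame(clusterings)) {
    clusterings[, c("subset_id", "c1", "c2", "c3")]
  } else NULL
  if (!is.null(cols)) {
    out <- dplyr::left_join(out, tibble::as_tibble(cols), by = "subset_id")
  }
  dplyr::arrange(out, .data$subset_id, .data$cluster_id)
}

#' Affinity-vs-phylogenetic purity distribution
#'
#' For every cluster with a strict majority (> 0.5 purity) of `"true"`
#' affinity labels, emits its affinity purity and its phylogenetic purity
#' (fraction of the most frequent family among members).  These pairs form
#' the scatter used to count cross-family structural features.
#'
#' @inheritParams select_hpcs
#' @param families optional tibble (`sequence_id`, `family`) overriding
#'   the families stored in the set.
#' @return tibble: `subset_id`, `cluster_id`, `affinity_purity`,
#'   `phylo_purity`.
#' @export
purity_distribution <- function(clusterings, set, labels, compound_id,
                                families = NULL,
                                weight = c("sequence", "structure")) {
  weight <- match.arg(weight)
  mem <- if (is.data.frame(clusterings)) {
    membership_tables(clusterings, set)
  } else clusterings
  lab <- compound_labels(labels, compound_id)
  stats <- .cluster_label_stats(mem$structures, lab, weight)
  stats <- dplyr::filter(stats, .data$majority_label == "true",
                         .data$purity > 0.5)
  if (nrow(stats) == 0L) {
    return(tibble::tibble(subset_id = integer(), cluster_id = integer(),
                          affinity_purity = numeric(),
                          phylo_purity = numeric()))
  }
  st <- structure_table(set)
  if (!is.null(families)) {
    st$family <- families$family[match(st$sequence_id,
                                       families$sequence_id)]
  }
  fam_of <- setNames(st$family, st$sequence_id)
  phylo <- mem$sequences |>
    dplyr::inner_join(stats[, c("subset_id", "cluster_id")],
                      by = c("subset_id", "cluster_id")) |>
    dplyr::mutate(family = unname(fam_of[.data$sequence_id])) |>
    dplyr::filter(!is.na(.data$family), .data$family != "unknown") |>
    dplyr::count(.data$subset_id, .data$cluster_id, .data$family) |>
    dplyr::group_by(.data$subset_id, .data$cluster_id) |>
    dplyr::summarise(phylo_purity = max(.data$n) / sum(.data$n),
                     .groups = "drop")
  stats |>
    dplyr::select("subset_id", "cluster_id",
                  affinity_purity = "purity") |>
    dplyr::left_join(phylo, by = c("subset_id", "cluster_id"))
}

#' Count cross-family HPCs
#'
#' @param hpcs HPC table from [select_hpcs()].
#' @return tibble with one row: `n_true_hpcs` (HPCs whose majority label is
#'   `"true"`) and `n_cross_family` (the subset spanning two or more
#'   families).
#' @export
count_cross_family_hpcs <- function(hpcs) {
  true_hpcs <- dplyr::filter(hpcs, .data$majority_label == "true")
  tibble::tibble(n_true_hpcs = nrow(true_hpcs),
                 n_cross_family = sum(true_hpcs$n_families >= 2L))
}
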