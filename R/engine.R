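# Fast label-rescoring engine.
#
# The clustering pass is label-free, so cross-validation folds and
# permutation nulls only re-score cluster purities and votes under a new
# label assignment.  Doing that with grouped data-frame joins costs seconds
# per fold; this engine flattens the membership tables once into integer
# index vectors so each re-scoring is a handful of tabulate() passes.
# Results are identical to select_hpcs() + tally_votes() (asserted in the
# test suite).

#' Build a fast label-rescoring engine
#'
#' Flattens a clustering pass into integer membership indices so that HPC
#' selection and vote tallying under a new label assignment reduce to a few
#' `tabulate()` passes.  Used by [cross_validate()], where every fold (and
#' every permutation null) re-scores the same label-free clusterings.
#'
#' @param clusterings a `triad_clusterings` from [cluster_subsets()] (or a
#'   [membership_tables()] list).
#' @param set the `aligned_set` the pass was computed on.
#' @return an opaque engine list consumed by [engine_votes()] and
#'   [cross_validate()].
#' @export
vote_engine <- function(clusterings, set) {
  mem <- if (is.data.frame(clusterings)) {
    membership_tables(clusterings, set)
  } else clusterings
  cl <- mem$clusters
  cl$k <- seq_len(nrow(cl))
  key <- function(subset_id, cluster_id) {
    match(paste(subset_id, cluster_id),
          paste(cl$subset_id, cl$cluster_id))
  }
  seq_levels <- sort(unique(mem$sequences$sequence_id))
  struct_levels <- unique(mem$structures$structure_id)
  st <- structure_table(set)
  list(
    clusters = cl,
    n_clusters = nrow(cl),
    seq_k = key(mem$sequences$subset_id, mem$sequences$cluster_id),
    seq_i = match(mem$sequences$sequence_id, seq_levels),
    struct_k = key(mem$structures$subset_id, mem$structures$cluster_id),
    struct_i = match(mem$structures$structure_id, struct_levels),
    seq_levels = seq_levels,
    struct_levels = struct_levels,
    struct_seq = st$sequence_id[match(struct_levels, st$structure_id)],
    n_subsets = length(unique(cl$subset_id)))
}

# labels_by_seq: named character vector sequence -> true/false/unknown.
# Returns the vote table (same shape as tally_votes()) for all structures.
#' Vote table under a label assignment, via the rescoring engine
#'
#' @param engine a [vote_engine()].
#' @param labels_by_seq named character vector sequence ->
#'   `"true"`/`"false"`/`"unknown"`.
#' @param purity_threshold,min_mean_silhouette HPC selection settings, as
#'   in [select_hpcs()].
#' @return vote table with the same shape as [tally_votes()].
#' @export
engine_votes <- function(engine, labels_by_seq, purity_threshold = 1.0,
                         min_mean_silhouette = 0.0) {
  lab <- labels_by_seq[engine$seq_levels]
  is_true <- !is.na(lab) & lab == "true"
  is_false <- !is.na(lab) & lab == "false"
  M <- engine$n_clusters
  t_cnt <- tabulate(engine$seq_k[is_true[engine$seq_i]], nbins = M)
  f_cnt <- tabulate(engine$seq_k[is_false[engine$seq_i]], nbins = M)
  n_known <- t_cnt + f_cnt
  purity <- ifelse(n_known > 0, pmax(t_cnt, f_cnt) / n_known, 0)
  majority_true <- t_cnt > f_cnt          # tie resolves to false
  hpc <- n_known >= 1L & purity >= purity_threshold &
    engine$clusters$mean_silhouette >= min_mean_silhouette
  sk <- engine$struct_k
  n_struct <- length(engine$struct_levels)
  vt <- tabulate(engine$struct_i[hpc[sk] & majority_true[sk]],
                 nbins = n_struct)
  vf <- tabulate(engine$struct_i[hpc[sk] & !majority_true[sk]],
                 nbins = n_struct)
  tibble::tibble(
    structure_id = engine$struct_levels,
    sequence_id = engine$struct_seq,
    votes_true = as.integer(vt), votes_false = as.integer(vf),
    n_subsets = engine$n_subsets,
    no_evidence = vt + vf == 0L)
}
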