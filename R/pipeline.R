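#' Run the full analysis end to end
#'
#' One unsupervised clustering pass over all position subsets, then, per
#' compound (compounds are fully independent): HPC selection, vote
#' tallying, decision-boundary training on the labeled sequences,
#' predictions for every structure and sequence, cross-family HPC counts,
#' and (optionally) identity-clustered cross-validation.
#'
#' @param set an `aligned_set`.
#' @param labels label table tibble (`sequence_id`, `compound_id`,
#'   `label`).
#' @param compounds compounds to analyse (default: all in `labels`).
#' @param sequences optional named character vector of aligned domain
#'   sequences; required when `evaluate = TRUE` (identity folds are built
#'   from it).
#' @param evaluate run cross-validation per compound.
#' @param identity_threshold fold identity threshold.
#' @param purity_threshold,min_mean_silhouette HPC selection settings.
#' @param C SVM regularisation constant.
#' @param matrix,w_struct,w_pharm,variance_target,d_max,k_max clustering
#'   pass settings (see [cluster_subsets()]).
#' @param seed master seed.
#' @param out_dir optional output directory; per-compound CSVs and a JSON
#'   run manifest are written there.
#' @param progress forwarded to [cluster_subsets()].
#' @return a `triad_run`: list with `manifest`, `clusterings`, and
#'   `results` (per-compound list of `hpcs`, `cross_family`, `votes`,
#'   `predictions`, `sequence_predictions`, `eval`).
#' @export
triad_run <- function(set, labels, compounds = NULL, sequences = NULL,
                      evaluate = FALSE, identity_threshold = 0.70,
                      purity_threshold = 1.0, min_mean_silhouette = 0.0,
                      C = 1.0, matrix = default_pharm_matrix(),
                      w_struct = 1, w_pharm = 1, variance_target = 0.90,
                      d_max = 10, k_max = 25, seed = 1, out_dir = NULL,
                      progress = FALSE) {
  t0 <- Sys.time()
  validate_structure_set(set)
  compounds <- compounds %||% sort(unique(labels$compound_id))
  if (evaluate) {
    assert_that(!is.null(sequences),
                "evaluate = TRUE needs aligned domain sequences")
  }
  clusterings <- cluster_subsets(
    set, matrix = matrix, w_struct = w_struct, w_pharm = w_pharm,
    variance_target = variance_target, d_max = d_max, k_max = k_max,
    seed = seed, progress = progress)
  t_cluster <- Sys.time()
  mem <- membership_tables(clusterings, set)
  mem$subset_meta <- clusterings[, c("subset_id", "c1", "c2", "c3")]
  plan <- if (evaluate) {
    build_identity_folds(sequences, identity_threshold)
  } else NULL
  results <- list()
  for (cmp in compounds) {
    hpcs <- select_hpcs(mem, set, labels, cmp, purity_threshold,
                        min_mean_silhouette)
    hpcs <- dplyr::left_join(hpcs, tibble::as_tibble(mem$subset_meta),
                             by = "subset_id")
    cross <- count_cross_family_hpcs(hpcs)
    votes <- tally_votes(hpcs, mem, set)
    lab <- compound_labels(labels, cmp)
    votes$label <- unname(lab[votes$sequence_id])
    votes$label[is.na(votes$label)] <- "unknown"
    model <- tryCatch(train_decision_boundary(votes, C = C, seed = seed),
                      error = function(e) NULL)
    preds <- if (!is.null(model)) predict(model, votes) else NULL
    seq_preds <- if (!is.null(preds)) aggregate_to_sequence(preds) else NULL
    ev <- if (evaluate) {
      tryCatch(cross_validate(set, labels, cmp, plan,
                              clusterings = clusterings,
                              purity_threshold = purity_threshold,
                              min_mean_silhouette = min_mean_silhouette,
                              C = C, seed = seed),
               error = function(e) {
                 warning("evaluation failed for ", cmp, ": ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    } else NULL
    results[[cmp]] <- list(hpcs = hpcs, cross_family = cross,
                           votes = votes, model = model,
                           predictions = preds,
                           sequence_predictions = seq_preds, eval = ev)
  }
  st <- structure_table(set)
  manifest <- list(
    n_structures = nrow(st),
    n_sequences = length(unique(st$sequence_id)),
    n_positions = length(set$position_columns),
    n_subsets = nrow(clusterings),
    compounds = lapply(results, function(r) {
      list(n_hpcs = nrow(r$hpcs),
           n_true_hpcs = r$cross_family$n_true_hpcs,
           n_cross_family = r$cross_family$n_cross_family,
           n_no_evidence = sum(r$votes$no_evidence))
    }),
    seed = seed,
    parameters = list(purity_threshold = purity_threshold,
                      min_mean_silhouette = min_mean_silhouette,
                      w_struct = w_struct, w_pharm = w_pharm,
                      variance_target = variance_target, d_max = d_max,
                      k_max = k_max, C = C,
                      identity_threshold = identity_threshold),
    timing_s = list(
      clustering = as.numeric(difftime(t_cluster, t0, units = "secs")),
      total = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out <- structure(list(manifest = manifest, clusterings = clusterings,
                        results = results),
                   class = "triad_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.triad_run <- function(x, ...) {
  m <- x$manifest
  cat("<triad_run> ", m$n_structures, " structures, ", m$n_subsets,
      " subset clusterings, ", length(x$results), " compound(s)\n",
      sep = "")
  invisible(x)
}

#' Write run outputs as CSV + JSON
#'
#' @param run a `triad_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cmp in names(run$results)) {
    r <- run$results[[cmp]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", cmp)
    hpc_flat <- r$hpcs |>
      dplyr::mutate(
        member_sequence_ids = purrr::map_chr(.data$member_sequence_ids,
                                             paste, collapse = ";"),
        member_structure_ids = purrr::map_chr(.data$member_structure_ids,
                                              paste, collapse = ";"),
        family_set = purrr::map_chr(.data$family_set, paste,
                                    collapse = ";"),
        # columns reported 1-based in human-readable output
        c1 = .data$c1 + 1L, c2 = .data$c2 + 1L, c3 = .data$c3 + 1L)
    readr::write_csv(hpc_flat,
                     file.path(out_dir, paste0("hpcs_", safe, ".csv")),
                     progress = FALSE)
    if (!is.null(r$predictions)) {
      readr::write_csv(r$predictions,
                       file.path(out_dir,
                                 paste0("predictions_", safe, ".csv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Cross-family HPC report
#'
#' Aggregates per-compound true-HPC counts into the standard two-column
#' report (total true-HPCs, those spanning two or more families) with an
#' overall spanning percentage.
#'
#' @param counts tibble with `compound_id`, `n_true_hpcs`,
#'   `n_cross_family` (e.g. bound [count_cross_family_hpcs()] rows, or the
#'   packaged reference table from [reference_hpc_counts()]).
#' @return list with `per_compound` (the input plus `spanning_pct`) and
#'   `totals` (summed counts and overall percentage).
#' @export
report_cross_family <- function(counts) {
  counts <- tibble::as_tibble(counts)
  per <- dplyr::mutate(
    counts,
    spanning_pct = ifelse(.data$n_true_hpcs > 0,
                          100 * .data$n_cross_family / .data$n_true_hpcs,
                          NA_real_))
  totals <- list(
    n_true_hpcs = sum(counts$n_true_hpcs),
    n_cross_family = sum(counts$n_cross_family),
    spanning_pct = 100 * sum(counts$n_cross_family) /
      sum(counts$n_true_hpcs))
  list(per_compound = per, totals = totals)
}

#' Packaged reference tables from the published kinome analysis
#'
#' Transcriptions of the published per-inhibitor cross-family HPC counts
#' (38 kinase inhibitors) and the kinome dataset bookkeeping (structure /
#' sequence / annotation counts per family), shipped for arithmetic
#' cross-checks and as worked-example input.
#'
#' @return `reference_hpc_counts()`: tibble `compound_id`,
#'   `n_true_hpcs`, `n_cross_family`.
#' @export
reference_hpc_counts <- function() {
  readr::read_csv(system.file("extdata", "kinome_hpc_counts.csv",
                              package = "triadclust"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_hpc_counts
#' @return `reference_family_counts()`: tibble `family`, `n_structures`,
#'   `n_sequences`, `n_annotated_sequences`.
#' @export
reference_family_counts <- function() {
  readr::read_csv(system.file("extdata", "kinome_family_counts.csv",
                              package = "triadclust"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_hpc_counts
#' @return `reference_dataset_totals()`: tibble `quantity`, `value`
#'   (includes the annotated-structure count).
#' @export
reference_dataset_totals <- function() {
  readr::read_csv(system.file("extdata", "kinome_totals.csv",
                              package = "triadclust"),
                  show_col_types = FALSE, progress = FALSE)
}
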