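#' Tally HPC votes per structure
#'
#' Each time a structure falls inside an HPC it receives one vote for that
#' HPC's majority label; a structure belongs to at most one cluster per
#' subset, so its total votes are bounded by the number of subsets.
#' Structures that never fall inside any HPC end with all-zero votes and
#' are flagged (`no_evidence`); downstream metrics exclude them.
#'
#' @param hpcs HPC table from [select_hpcs()].
#' @param clusterings a `triad_clusterings` (or [membership_tables()]
#'   list).
#' @param set the `aligned_set`.
#' @param target_ids structure ids to tally (default all).
#' @return tibble: `structure_id`, `sequence_id`, `votes_true`,
#'   `votes_false`, `n_subsets`, `no_evidence`.
#' @export
tally_votes <- function(hpcs, clusterings, set, target_ids = NULL) {
  mem <- if (is.data.frame(clusterings)) {
    membership_tables(clusterings, set)
  } else clusterings
  n_subsets <- length(unique(mem$structures$subset_id))
  st <- structure_table(set)
  targets <- target_ids %||% st$structure_id
  base <- tibble::tibble(structure_id = targets,
                         sequence_id = st$sequence_id[
                           match(targets, st$structure_id)])
  if (nrow(hpcs) == 0L) {
    return(dplyr::mutate(base, votes_true = 0L, votes_false = 0L,
                         n_subsets = n_subsets, no_evidence = TRUE))
  }
  votes <- mem$structures |>
    dplyr::inner_join(
      hpcs[, c("subset_id", "cluster_id", "majority_label")],
      by = c("subset_id", "cluster_id")) |>
    dplyr::filter(.data$structure_id %in% targets) |>
    dplyr::count(.data$structure_id, .data$majority_label) |>
    tidyr::pivot_wider(names_from = "majority_label",
                       values_from = "n", values_fill = 0L)
  for (col in c("true", "false")) {
    if (!col %in% names(votes)) votes[[col]] <- 0L
  }
  base |>
    dplyr::left_join(votes[, c("structure_id", "true", "false")],
                     by = "structure_id") |>
    dplyr::mutate(votes_true = dplyr::coalesce(.data$true, 0L),
                  votes_false = dplyr::coalesce(.data$false, 0L),
                  n_subsets = n_subsets,
                  no_evidence = .data$votes_true + .data$votes_false == 0L,
                  .keep = "unused")
}

#' Train the vote-space decision boundary
#'
#' A linear-kernel support-vector machine separates the labeled vote
#' vectors; confidences come from a sigmoid (logistic) calibration fitted
#' on the training decision values.  Decision values are oriented so that
#' positive means `"true"`.
#'
#' @param votes vote table from [tally_votes()] with an added `label`
#'   column (`"true"`/`"false"`); zero-vote rows are dropped before
#'   training.
#' @param C SVM regularisation constant (default 1).
#' @param seed integer seed (training is deterministic; kept for metadata).
#' @return a `triad_svm` model object.
#' @export
train_decision_boundary <- function(votes, C = 1.0, seed = 1) {
  train <- dplyr::filter(votes, .data$label %in% c("true", "false"),
                         !.data$no_evidence)
  classes <- unique(train$label)
  if (length(classes) < 2L) {
    stop_triad("degenerate training set: only one class present (",
               paste(classes, collapse = ""), ")")
  }
  x <- as.matrix(train[, c("votes_true", "votes_false")])
  y <- factor(train$label, levels = c("false", "true"))
  fit <- with_seed(seed, e1071::svm(x, y, kernel = "linear", cost = C,
                                    scale = FALSE))
  dv <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                        "decision.values"))
  # libSVM's sign convention depends on class encounter order; orient so
  # that positive decision values mean "true"
  orient <- if (mean(dv[y == "true"]) >= mean(dv[y == "false"])) 1 else -1
  dv <- orient * dv
  calib <- suppressWarnings(
    glm((y == "true") ~ dv, family = binomial()))
  structure(list(fit = fit, orient = orient, calibration = calib,
                 C = C, seed = seed,
                 training_accuracy = mean((dv > 0) == (y == "true"))),
            class = "triad_svm")
}

#' @export
print.triad_svm <- function(x, ...) {
  cat("<triad_svm> linear-kernel decision boundary (C = ", x$C,
      "), training accuracy ", round(x$training_accuracy, 3), "\n",
      sep = "")
  invisible(x)
}

#' Predict labels from vote vectors
#'
#' Labels follow the side of the SVM hyperplane (exact ties resolve to
#' `"false"`, the conservative call for a binding claim); confidence is
#' the calibrated probability of `"true"`.  Zero-vote structures are
#' reported with `predicted_label = "no-evidence"` and `NA` decision
#' values.
#'
#' @param object a `triad_svm`.
#' @param votes vote table from [tally_votes()].
#' @param ... unused.
#' @return tibble: the vote columns plus `decision_value`, `confidence`,
#'   `predicted_label`.
#' @export
predict.triad_svm <- function(object, votes, ...) {
  out <- tibble::as_tibble(votes)
  out$decision_value <- NA_real_
  out$confidence <- NA_real_
  out$predicted_label <- "no-evidence"
  scored <- !out$no_evidence
  if (any(scored)) {
    x <- as.matrix(out[scored, c("votes_true", "votes_false")])
    dv <- object$orient *
      as.numeric(attr(predict(object$fit, x, decision.values = TRUE),
                      "decision.values"))
    out$decision_value[scored] <- dv
    out$confidence[scored] <- as.numeric(
      predict(object$calibration, data.frame(dv = dv), type = "response"))
    out$predicted_label[scored] <- ifelse(dv > 0, "true", "false")
  }
  out
}

#' Aggregate structure-level predictions to sequences
#'
#' A sequence's decision value is the mean over its scored structures
#' (label by sign, zero resolving to `"false"`); confidence is the mean
#' calibrated probability.  Sequences whose structures are all
#' `no-evidence` stay `"no-evidence"`.
#'
#' @param predictions structure-level prediction tibble from
#'   [predict.triad_svm()] (must carry `sequence_id`).
#' @return tibble: `sequence_id`, `n_structures`, `decision_value`,
#'   `confidence`, `predicted_label`.
#' @export
aggregate_to_sequence <- function(predictions) {
  predictions |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::summarise(
      n_structures = dplyr::n(),
      decision_value = if (all(is.na(.data$decision_value))) NA_real_
        else mean(.data$decision_value, na.rm = TRUE),
      confidence = if (all(is.na(.data$confidence))) NA_real_
        else mean(.data$confidence, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(predicted_label = dplyr::case_when(
      is.na(.data$decision_value) ~ "no-evidence",
      .data$decision_value > 0 ~ "true",
      TRUE ~ "false"))
}
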