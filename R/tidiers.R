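# broom-style accessors for fitted objects

#' Tidy a vote-space decision boundary
#'
#' @param x a `triad_svm`.
#' @param ... unused.
#' @return tibble of hyperplane terms (`votes_true`, `votes_false`,
#'   `bias`) with their oriented estimates.
#' @export
tidy.triad_svm <- function(x, ...) {
  w <- as.numeric(crossprod(x$fit$coefs, x$fit$SV)) * x$orient
  tibble::tibble(term = c("votes_true", "votes_false", "bias"),
                 estimate = c(w, -x$fit$rho * x$orient))
}

#' @rdname tidy.triad_svm
#' @export
glance.triad_svm <- function(x, ...) {
  tibble::tibble(training_accuracy = x$training_accuracy, C = x$C,
                 n_support_vectors = nrow(x$fit$SV))
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the pooled sequence-level predictions; `glance()` the
#' one-row metric summary.
#'
#' @param x a `triad_eval`.
#' @param ... unused.
#' @export
tidy.triad_eval <- function(x, ...) {
  tibble::as_tibble(x$predictions)
}

#' @rdname tidy.triad_eval
#' @export
glance.triad_eval <- function(x, ...) {
  tibble::tibble(compound_id = x$compound_id, roc_auc = x$roc_auc,
                 pr_auc = x$pr_auc, ef = x$ef$ef, ef_max = x$ef$ef_max,
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 n_skipped_folds = length(x$skipped_folds))
}

#' Tidy a subset clustering
#'
#' @param x a `subset_clustering`.
#' @param ... unused.
#' @return tibble: `structure_id`, `cluster`, `silhouette`.
#' @export
tidy.subset_clustering <- function(x, ...) {
  tibble::tibble(structure_id = names(x$assignments) %||%
                   as.character(seq_along(x$assignments)),
                 cluster = unname(x$assignments),
                 silhouette = x$per_point_silhouette)
}
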