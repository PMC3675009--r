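#' Pairwise sequence identity over an alignment
#'
#' Identity = matching residues / columns where neither sequence has a
#' gap, computed over the provided domain alignment.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric identity matrix in `[0, 1]` with unit diagonal.
#' @export
pairwise_identity <- function(seqs) {
  n <- length(seqs)
  assert_that(n >= 2L, "need at least 2 sequences")
  assert_that(length(unique(nchar(seqs))) == 1L,
              "aligned sequences must have equal length")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap <- chars %in% c("-", ".")
  dim(gap) <- dim(chars)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !gap[i, ] & !gap[j, ]
      id <- if (any(both)) mean(chars[i, both] == chars[j, both]) else 0
      m[i, j] <- id
      m[j, i] <- id
    }
  }
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Identity-clustered cross-validation folds
#'
#' Groups sequences by single-linkage at the identity threshold
#' (default 70%), so no test sequence shares at-or-above-threshold
#' identity with any training sequence; each resulting nr-cluster is one
#' fold.  Single linkage is exactly the closure that guarantees this
#' property.  The grouping is order-invariant.
#'
#' @param seqs named character vector of aligned domain sequences (or a
#'   precomputed identity matrix from [pairwise_identity()]).
#' @param threshold identity threshold in `[0, 1]`.
#' @return a `fold_plan`: tibble `sequence_id`, `fold` plus attribute
#'   `threshold`; one warning when all sequences collapse into one fold.
#' @export
build_identity_folds <- function(seqs, threshold = 0.70) {
  m <- if (is.matrix(seqs)) seqs else pairwise_identity(seqs)
  ids <- rownames(m)
  n <- nrow(m)
  # union-find single linkage over edges with identity >= threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (m[i, j] >= threshold - 1e-12) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # canonical fold numbering: by smallest member sequence id
  first_id <- vapply(split(ids, roots), min, character(1))
  fold <- match(first_id[as.character(roots)],
                sort(unique(first_id)))
  if (length(unique(fold)) == 1L) {
    warning("all sequences fall in one identity group; ",
            "cross-validation is impossible", call. = FALSE)
  }
  out <- tibble::tibble(sequence_id = ids, fold = as.integer(fold))
  attr(out, "threshold") <- threshold
  class(out) <- c("fold_plan", class(out))
  out
}

#' ROC and precision-recall AUC of a ranking
#'
#' ROC AUC equals the Mann-Whitney concordance probability (rank formula,
#' ties averaged); PR AUC integrates precision over recall at every
#' distinct threshold by the trapezoidal rule.
#'
#' @param score numeric prediction scores (higher = more likely positive).
#' @param truth logical (or `"true"`/`"false"`) reference labels; both
#'   classes must be present.
#' @return list with `roc_auc`, `pr_auc`, `n_pos`, `n_neg`.
#' @export
roc_pr <- function(score, truth) {
  if (is.character(truth)) truth <- truth == "true"
  keep <- !is.na(score) & !is.na(truth)
  score <- score[keep]; truth <- truth[keep]
  n_pos <- sum(truth); n_neg <- sum(!truth)
  assert_that(n_pos > 0L && n_neg > 0L,
              "both classes must be present to compute AUCs")
  r <- rank(score, ties.method = "average")
  roc_auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(truth[ord])
  fp <- cumsum(!truth[ord])
  # collapse tied scores: evaluate at the last index of each score value
  last <- rev(!duplicated(rev(score[ord])))
  tp <- tp[last]; fp <- fp[last]
  recall <- c(0, tp / n_pos)
  precision <- c(1, tp / (tp + fp))
  pr_auc <- sum(diff(recall) * (head(precision, -1) + precision[-1]) / 2)
  list(roc_auc = roc_auc, pr_auc = pr_auc, n_pos = n_pos, n_neg = n_neg)
}

#' Enrichment factor of a ranking
#'
#' `EF = (actives in the top fraction / top-bucket size) /
#'  (total actives / total)`, with the top-bucket size
#' `ceiling(fraction * N)` so the bucket is never empty.  `ef_max` is the
#' value achieved by a perfect ranking (all bucket slots filled with
#' actives, capped by the number of actives available).
#'
#' @param score numeric confidence scores (ranked descending).
#' @param truth logical (or `"true"`/`"false"`) activity labels.
#' @param fraction top fraction to examine (default 0.05).
#' @return list with `ef`, `ef_max`, `n_top`, `n_actives`, `n_total`.
#' @export
enrichment_factor <- function(score, truth, fraction = 0.05) {
  if (is.character(truth)) truth <- truth == "true"
  keep <- !is.na(score) & !is.na(truth)
  score <- score[keep]; truth <- truth[keep]
  n <- length(score)
  n_act <- sum(truth)
  assert_that(n_act > 0L, "no actives: enrichment undefined")
  n_top <- max(1L, ceiling(fraction * n))
  ord <- order(score, decreasing = TRUE)
  hits <- sum(truth[ord][seq_len(n_top)])
  ef <- (hits / n_top) / (n_act / n)
  ef_max <- (min(n_top, n_act) / n_top) / (n_act / n)
  list(ef = ef, ef_max = ef_max, n_top = n_top,
       n_actives = n_act, n_total = n)
}

#' Identity-clustered cross-validation of the full pipeline
#'
#' For each fold, the fold's sequences have their labels masked to
#' `"unknown"` *before* HPC selection (so no test label influences any
#' purity), HPCs are selected and the vote-space SVM trained on the
#' remaining labeled sequences, and predictions are collected for the
#' fold's sequences.  Folds whose training votes contain a single class
#' are skipped with a warning.  Metrics are pooled over folds at the
#' sequence level.
#'
#' The subset clusterings are unsupervised and therefore computed once
#' and shared across folds; pass `clusterings` to reuse a pass.
#'
#' @param set an `aligned_set`.
#' @param labels label table tibble.
#' @param compound_id compound to evaluate.
#' @param plan a `fold_plan` from [build_identity_folds()].
#' @param clusterings optional precomputed [cluster_subsets()] result or
#'   a prebuilt [vote_engine()].
#' @param purity_threshold,min_mean_silhouette HPC selection settings.
#' @param C SVM regularisation constant.
#' @param seed master seed (clustering pass + SVM metadata).
#' @param ... further arguments passed to [cluster_subsets()] when no
#'   precomputed pass is given.
#' @return a `triad_eval`: list with `compound_id`, pooled `roc_auc`,
#'   `pr_auc`, `ef` (list from [enrichment_factor()]), `n_pos`, `n_neg`,
#'   `predictions` (pooled sequence-level tibble with `truth`), and
#'   `skipped_folds`.
#' @export
cross_validate <- function(set, labels, compound_id, plan,
                           clusterings = NULL, purity_threshold = 1.0,
                           min_mean_silhouette = 0.0, C = 1.0, seed = 1,
                           ...) {
  if (is.null(clusterings)) {
    clusterings <- cluster_subsets(set, seed = seed, ...)
  }
  engine <- if (is.list(clusterings) && !is.data.frame(clusterings) &&
                  !is.null(clusterings$struct_k)) {
    clusterings   # a prebuilt vote_engine
  } else {
    vote_engine(clusterings, set)
  }
  lab <- compound_labels(labels, compound_id)
  known_seqs <- names(lab)[lab %in% c("true", "false")]
  assert_that(length(unique(lab[known_seqs])) == 2L,
              "compound must have known labels of both classes")
  folds <- sort(unique(plan$fold))
  pooled <- list()
  skipped <- integer()
  for (f in folds) {
    test_seqs <- plan$sequence_id[plan$fold == f]
    if (!any(test_seqs %in% known_seqs)) next  # nothing to score
    masked <- lab
    masked[names(masked) %in% test_seqs] <- "unknown"
    if (length(unique(masked[masked != "unknown"])) < 2L) {
      warning("fold ", f, " leaves a single-class training set; skipped",
              call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    votes <- engine_votes(engine, masked, purity_threshold,
                          min_mean_silhouette)
    votes$label <- unname(masked[votes$sequence_id])
    votes$label[is.na(votes$label)] <- "unknown"
    model <- tryCatch(
      train_decision_boundary(votes, C = C, seed = derive_seed(seed, f)),
      error = function(e) NULL)
    if (is.null(model)) {
      warning("fold ", f, ": decision boundary not trainable; skipped",
              call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    test_votes <- dplyr::filter(votes, .data$sequence_id %in% test_seqs)
    preds <- predict(model, test_votes)
    seq_preds <- aggregate_to_sequence(preds)
    seq_preds$fold <- f
    pooled[[length(pooled) + 1L]] <- seq_preds
  }
  assert_that(length(pooled) > 0L, "no fold produced predictions")
  preds <- dplyr::bind_rows(pooled)
  preds$truth <- unname(lab[preds$sequence_id])
  scored <- dplyr::filter(preds, .data$truth %in% c("true", "false"),
                          .data$predicted_label != "no-evidence")
  metrics <- roc_pr(scored$decision_value, scored$truth)
  ef <- enrichment_factor(scored$confidence, scored$truth)
  structure(list(compound_id = compound_id,
                 roc_auc = metrics$roc_auc, pr_auc = metrics$pr_auc,
                 ef = ef, n_pos = metrics$n_pos, n_neg = metrics$n_neg,
                 predictions = preds, skipped_folds = skipped),
            class = "triad_eval")
}

#' @export
print.triad_eval <- function(x, ...) {
  cat("<triad_eval> ", x$compound_id, ": ROC AUC ",
      round(x$roc_auc, 3), ", PR AUC ", round(x$pr_auc, 3),
      ", EF ", round(x$ef$ef, 2), " (max ", round(x$ef$ef_max, 2),
      ") on ", x$n_pos, "+/", x$n_neg, "- sequences\n", sep = "")
  invisible(x)
}
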