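#' Plot a subset embedding
#'
#' Scatter of the first two embedding dimensions, coloured by cluster
#' assignment or by an arbitrary label vector (e.g. affinity labels).
#'
#' @param embedding a `triad_embedding`.
#' @param colour factor-like vector, one value per point (default: no
#'   colouring).
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_embedding <- function(embedding, colour = NULL, title = NULL) {
  co <- embedding$coordinates
  df <- tibble::tibble(
    pc1 = co[, 1],
    pc2 = if (ncol(co) >= 2) co[, 2] else 0)
  if (!is.null(colour)) {
    df$colour <- factor(colour)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                          colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "component 1", y = "component 2", title = title) +
    ggplot2::theme_minimal()
}

#' @rdname plot_embedding
#' @param object a `subset_clustering` (plotted in its stored embedding,
#'   coloured by cluster).
#' @param ... unused.
#' @export
autoplot.subset_clustering <- function(object, ...) {
  assert_that(!is.null(object$coordinates),
              "clustering carries no coordinates")
  plot_embedding(
    structure(list(coordinates = object$coordinates),
              class = "triad_embedding"),
    colour = object$assignments,
    title = paste0("K = ", object$K, " (", object$model, ")"))
}

#' Affinity-vs-phylogenetic purity scatter
#'
#' One point per true-majority cluster; the right-hand column (affinity
#' purity 1.0) holds the HPCs, and low phylogenetic purity there marks
#' cross-family structural features.
#'
#' @param points tibble from [purity_distribution()].
#' @return a ggplot object.
#' @export
plot_purity_distribution <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(.data$affinity_purity,
                                       .data$phylo_purity)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::coord_cartesian(xlim = c(0.5, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "affinity purity (true label)",
                  y = "phylogenetic purity") +
    ggplot2::theme_minimal()
}

#' Vote-space scatter with the decision boundary
#'
#' @param votes vote table with a `label` column.
#' @param model optional `triad_svm`; its hyperplane is drawn when given.
#' @return a ggplot object.
#' @export
plot_vote_space <- function(votes, model = NULL) {
  df <- dplyr::filter(votes, !.data$no_evidence)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$votes_true,
                                        .data$votes_false,
                                        colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c("true" = "#2166ac", "false" = "#b2182b",
                 "unknown" = "grey70"), na.value = "grey70") +
    ggplot2::labs(x = "votes for true", y = "votes for false",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    w <- crossprod(model$fit$coefs, model$fit$SV) * model$orient
    b <- -model$fit$rho * model$orient
    if (abs(w[2]) > 1e-12) {
      p <- p + ggplot2::geom_abline(slope = -w[1] / w[2],
                                    intercept = -b / w[2],
                                    linetype = "dashed")
    } else if (abs(w[1]) > 1e-12) {
      p <- p + ggplot2::geom_vline(xintercept = -b / w[1],
                                   linetype = "dashed")
    }
  }
  p
}

#' ROC curve of an evaluation
#'
#' @param object a `triad_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.triad_eval <- function(object, ...) {
  preds <- dplyr::filter(object$predictions,
                         .data$truth %in% c("true", "false"),
                         .data$predicted_label != "no-evidence")
  ord <- order(preds$decision_value, decreasing = TRUE)
  truth <- preds$truth[ord] == "true"
  df <- tibble::tibble(
    fpr = c(0, cumsum(!truth) / sum(!truth)),
    tpr = c(0, cumsum(truth) / sum(truth)))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = paste0(object$compound_id, " (ROC AUC ",
                     round(object$roc_auc, 2), ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
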