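# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an embedding PCA trajectory
#'
#' One path per token through the 2D PCA plane across training
#' snapshots, labelled at the final snapshot.
#'
#' @param trajectory Output of [embedding_pca_trajectory()].
#' @return A ggplot object.
#' @export
plot_embedding_trajectory <- function(trajectory) {
  final <- dplyr::filter(trajectory, .data$step == max(.data$step))
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               group = .data$label)) +
    ggplot2::geom_path(alpha = 0.4, colour = "grey40") +
    ggplot2::geom_point(data = final, size = 1) +
    ggplot2::geom_text(data = final, ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = "Token embedding trajectory during training") +
    ggplot2::theme_minimal()
}

#' Plot alphabet error rates
#'
#' @param rates Output of [error_rate_table()].
#' @return A ggplot object.
#' @export
plot_error_rates <- function(rates) {
  rates$alphabet <- stats::reorder(rates$alphabet, rates$error_rate_percent)
  ggplot2::ggplot(rates,
                  ggplot2::aes(x = .data$alphabet,
                               y = .data$error_rate_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Indistinguishable substitutions (%)",
                  title = "Mutation error rate by alphabet") +
    ggplot2::theme_minimal()
}

#' @method autoplot lddt_result
#' @export
autoplot.lddt_result <- function(object, ...) {
  ggplot2::ggplot(object$per_residue,
                  ggplot2::aes(x = .data$resno, y = .data$score)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_model), size = 1) +
    ggplot2::labs(x = "Residue number", y = "Per-residue LDDT-Cα",
                  colour = "In model",
                  title = sprintf("LDDT-Cα profile (global %.1f)",
                                  object$global)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @method autoplot masked_lm
#' @export
autoplot.masked_lm <- function(object, ...) {
  log <- object$log
  ckpt <- dplyr::filter(log, !is.na(.data$val_perplexity))
  ggplot2::ggplot(dplyr::filter(log, !is.na(.data$loss)),
                  ggplot2::aes(x = .data$step, y = exp(.data$loss))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_line(data = ckpt,
                       ggplot2::aes(y = .data$val_perplexity),
                       colour = "firebrick") +
    ggplot2::geom_point(data = ckpt,
                        ggplot2::aes(y = .data$val_perplexity),
                        colour = "firebrick") +
    ggplot2::labs(x = "Step", y = "Perplexity",
                  title = "Training (grey) and held-out (red) perplexity") +
    ggplot2::theme_minimal()
}

#' Plot per-target LDDT comparison across alphabets
#'
#' @param comparison Output of [compare_alphabet_predictions()].
#' @return A ggplot object.
#' @export
plot_alphabet_comparison <- function(comparison) {
  comparison$alphabet <- stats::reorder(comparison$alphabet,
                                        comparison$lddt_ca)
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$alphabet, y = .data$lddt_ca,
                               fill = .data$improved)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "LDDT-Cα",
                  fill = "Improved vs baseline") +
    ggplot2::theme_minimal()
}
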