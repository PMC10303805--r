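#' Heatmap of predicted association scores
#'
#' Tiles the final score matrix with known associations marked, a quick visual
#' check that scores concentrate around the observed structure.
#'
#' @param object A `msif_lnp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msif_lnp_fit <- function(object, ...) {
  tab <- tidy(object)
  tab$microbe <- factor(tab$microbe, levels = rownames(object$scores))
  tab$disease <- factor(tab$disease, levels = colnames(object$scores))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$disease, y = .data$microbe)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_point(data = tab[tab$known, , drop = FALSE],
                        shape = 4, size = 0.8, colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "disease", y = "microbe", fill = "score",
                  title = "Predicted association scores",
                  subtitle = "crosses mark known associations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Cross-validation AUC distribution
#'
#' Boxplot of fold-level AUCs per repeat with the overall mean drawn as a
#' dashed line.
#'
#' @param object A `msif_lnp_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msif_lnp_cv <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$repeat_), y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = object$auc_mean, linetype = "dashed") +
    ggplot2::labs(x = "repeat", y = "fold AUC",
                  title = sprintf("Cross-validated AUC: %.4f", object$auc_mean)) +
    ggplot2::theme_minimal()
}

#' Sweep profile
#'
#' Mean AUC (with +/- 1 sd ribbon when available) along the first swept
#' parameter, faceted over any remaining grid columns.
#'
#' @param object A `msif_lnp_sweep` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msif_lnp_sweep <- function(object, ...) {
  tab <- tidy(object)
  par_cols <- setdiff(names(tab), c("auc_mean", "auc_sd"))
  xcol <- par_cols[1L]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xcol]], y = .data$auc_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xcol, y = "mean AUC", title = "Parameter sweep") +
    ggplot2::theme_minimal()
  if (length(par_cols) > 1L) {
    p <- p + ggplot2::facet_wrap(par_cols[-1L])
  }
  p
}

#' Singular-value spectrum of a fused network
#'
#' Scree plot of the fused network's singular values with the retained rank
#' marked; useful for judging how aggressive the denoising truncation is.
#'
#' @param network A `fused_network` (e.g. `fit$network_microbe`).
#' @return A ggplot object.
#' @export
plot_singular_values <- function(network) {
  if (!inherits(network, "fused_network")) {
    abort("`network` must be a fused_network object.")
  }
  tab <- tibble::tibble(
    index = seq_along(network$singular_values),
    value = network$singular_values
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = network$rank_kept + 0.5, linetype = "dashed") +
    ggplot2::labs(x = "singular value index", y = "singular value",
                  title = "Fused network spectrum",
                  subtitle = sprintf("%d of %d values kept", network$rank_kept,
                                     length(network$singular_values))) +
    ggplot2::theme_minimal()
}
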