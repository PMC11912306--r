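# ggplot2 graphics for the main result types ----------------------------------

#' Plot a fitted dose-response curve
#'
#' Observed per-concentration response proportions with the fitted curve on
#' a log-concentration axis.
#'
#' @param object A `zfet_fit` with its data attached.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zfet_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  d <- dplyr::mutate(object$data,
                     proportion = .data$n_affected / .data$n_total)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$concentration_umol_L,
                                       .data$proportion)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "concentration [µmol/L]",
                  y = "proportion affected",
                  size = "n embryos",
                  title = paste0(object$family, " fit",
                                 if (!object$valid) " (invalid)" else "")) +
    ggplot2::theme_minimal()
  if (is.finite(object$b)) {
    grid <- tibble::tibble(
      concentration_umol_L = exp(seq(log(min(d$concentration_umol_L)),
                                     log(max(d$concentration_umol_L)),
                                     length.out = 200)))
    grid$proportion <- .drm_p(object$family, object$b, log(object$e),
                              grid$concentration_umol_L)
    p <- p + ggplot2::geom_line(data = grid, colour = "#2166ac")
  }
  p
}

#' Heatmap of a fingerprint matrix
#'
#' Substances by effects, tile fill = proportion of non-normal embryos
#' exhibiting the effect; rows ordered by the Ward/Euclidean clustering.
#'
#' @param mat A matrix from [assemble_fingerprint_matrix()].
#' @param clusters Optional result of [cluster_fingerprints()] providing the
#'   row order.
#' @return A ggplot object.
#' @export
plot_fingerprint_heatmap <- function(mat, clusters = NULL) {
  row_order <- rownames(mat)
  if (!is.null(clusters)) {
    hc <- attr(clusters, "hclust")
    if (!is.null(hc)) row_order <- rownames(mat)[hc$order]
  }
  long <- tibble::as_tibble(mat, rownames = "substance_id") |>
    tidyr::pivot_longer(-"substance_id", names_to = "effect",
                        values_to = "proportion") |>
    dplyr::mutate(substance_id = factor(.data$substance_id,
                                        levels = row_order),
                  effect = factor(.data$effect, levels = colnames(mat)))
  ggplot2::ggplot(long, ggplot2::aes(.data$effect, .data$substance_id,
                                     fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of an effect-propagation matrix
#'
#' Early-time effects in rows, late-time effects in columns; fill = Pearson
#' correlation; insignificant (p >= 0.01) or undefined cells are marked.
#' Rows and columns follow the display clustering of
#' [cluster_propagation()].
#'
#' @param object A `zfet_propagation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zfet_propagation <- function(object, ...) {
  ord <- cluster_propagation(object)
  long <- tidy(object) |>
    dplyr::mutate(
      effect_t1 = factor(.data$effect_t1,
                         levels = rownames(object$pcc)[ord$row_order]),
      effect_t2 = factor(.data$effect_t2,
                         levels = colnames(object$pcc)[ord$col_order])
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$effect_t2, .data$effect_t1,
                                     fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(long, !.data$significant |
                                               !.data$defined),
                        shape = 4, size = 1, colour = "grey40") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  na.value = "grey90") +
    ggplot2::labs(x = paste0("effect @ ", object$t2, " hpf"),
                  y = paste0("effect @ ", object$t1, " hpf"),
                  fill = "PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
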