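#' Stacked-bar plot of ancestry proportions
#'
#' One thin bar per individual partitioned into cluster memberships — the
#' standard visual for admixture output. Individuals are grouped along the
#' x axis by population label (references) and declared group (queries)
#' when metadata is supplied.
#'
#' @param object an `admixture_fit`.
#' @param meta optional metadata tibble for grouping.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, meta = NULL, ...) {
  long <- tidy(object)
  if (!is.null(meta)) {
    m <- meta
    m$panel <- dplyr::coalesce(m$population_label, m$declared_group, "query")
    long <- dplyr::left_join(long, m[, c("sample_id", "panel")],
                             by = "sample_id")
  } else {
    long$panel <- ""
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$proportion,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~panel, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Scatter plot of PCA coordinates
#'
#' @param object a `pca_result`.
#' @param meta optional metadata tibble; points are coloured by population
#'   label / declared group.
#' @param pcs which two PCs to plot.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, meta = NULL, pcs = c(1, 2), ...) {
  sc <- object$scores
  xs <- paste0("PC", pcs[1]); ys <- paste0("PC", pcs[2])
  if (!is.null(meta)) {
    m <- meta
    m$group <- dplyr::coalesce(m$population_label, m$declared_group, "query")
    sc <- dplyr::left_join(sc, m[, c("sample_id", "group")], by = "sample_id")
  } else {
    sc$group <- ""
  }
  pct <- function(i) sprintf("%s (%.1f%%)", paste0("PC", i),
                             100 * object$var_frac[i])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xs]], y = .data[[ys]],
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = pct(pcs[1]), y = pct(pcs[2])) +
    ggplot2::theme_minimal()
}

#' Delta-K curve across the swept K values
#'
#' @param object a `delta_k_table`.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot delta_k_table
#' @export
autoplot.delta_k_table <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab[!is.na(tab$delta_k), ],
                  ggplot2::aes(x = .data$k, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise F_st
#'
#' @param object an `fst_pairwise`.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot fst_pairwise
#' @export
autoplot.fst_pairwise <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pop_a, y = .data$pop_b,
                               fill = .data$theta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$theta)), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(F[st])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
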