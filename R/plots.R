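# ggplot2 views of the result objects. The Venn figure is drawn from plain
# circle paths with region count labels; layout is schematic (counts only,
# not area-proportional).

circle_points <- function(cx, cy, r, n = 240) {
  theta <- seq(0, 2 * pi, length.out = n)
  tibble(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

venn_layout <- function(k) {
  if (k == 2L) {
    list(centers = data.frame(x = c(0, 1.6), y = c(0, 0)), r = 1.3,
         region_xy = list(c(-0.7, 0), c(2.3, 0), c(0.8, 0)),
         region_order = c(1L, 2L, 3L),
         name_xy = data.frame(x = c(-0.9, 2.5), y = c(1.5, 1.5)))
  } else {
    list(centers = data.frame(x = c(0, 2, 1), y = c(0, 0, 1.73)), r = 1.4,
         region_xy = list(c(-0.65, -0.45), c(2.65, -0.45), c(1, 2.6),
                          c(1, -0.5), c(0.25, 1.05), c(1.75, 1.05),
                          c(1, 0.55)),
         region_order = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
         name_xy = data.frame(x = c(-1.2, 3.2, 1), y = c(-1.5, -1.5, 3.3)))
  }
}

#' Plot a 2- or 3-set Venn partition
#'
#' Schematic circles with the exclusive region counts as labels. Only 2- and
#' 3-set partitions can be drawn; larger partitions remain available as the
#' tabular [venn_partition()] result.
#'
#' @param object A [venn_partition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  nm <- attr(object, "set_names")
  k <- length(nm)
  if (!k %in% c(2L, 3L)) {
    txc_abort("3-set plots only: Venn figures are drawn for 2 or 3 sets.",
              "txc_domain_error")
  }
  lay <- venn_layout(k)
  circles <- purrr::map_dfr(seq_len(k), function(i) {
    dplyr::mutate(circle_points(lay$centers$x[i], lay$centers$y[i], lay$r),
                  set = nm[i])
  })
  labels <- tibble(
    x = vapply(lay$region_xy, `[[`, numeric(1), 1L),
    y = vapply(lay$region_xy, `[[`, numeric(1), 2L),
    n = object$n_genes[lay$region_order]
  )
  names_df <- dplyr::mutate(lay$name_xy, set = nm)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$set, colour = .data$set),
                       linewidth = 0.8) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$n), size = 4) +
    ggplot2::geom_text(data = names_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$set, colour = .data$set),
                       size = 3.5, fontface = "bold") +
    ggplot2::coord_fixed(clip = "off") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Plot detected-gene counts against the cutoff ladder
#'
#' Reproduces the characteristic cutoff-dependence view: per-platform
#' detected-gene counts and the all-platform intersection, per cutoff.
#'
#' @param object A `concordance_report` from [sweep_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  counts <- purrr::map_dfr(object$per_cutoff, function(e) {
    dplyr::mutate(e$set_counts, cutoff = e$cutoff)
  })
  common <- purrr::map_dfr(object$per_cutoff, function(e) {
    tibble(cutoff = e$cutoff, set_id = "all platforms",
           n_detected = e$common_all)
  })
  df <- dplyr::bind_rows(counts, common)
  df$cutoff_lab <- factor(fmt6(df$cutoff),
                          levels = fmt6(sort(unique(df$cutoff))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_lab,
                                   y = .data$n_detected,
                                   group = .data$set_id,
                                   colour = .data$set_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cutoff (native units)", y = "detected genes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate-batch Tanimoto against the cutoff ladder
#'
#' @param object A [replicate_concordance()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replicate_concordance
#' @export
autoplot.replicate_concordance <- function(object, ...) {
  df <- as_tibble(object)
  df$cutoff_lab <- factor(fmt6(df$cutoff),
                          levels = fmt6(sort(unique(df$cutoff))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_lab, y = .data$tanimoto,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 2.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "cutoff (native units)", y = "Tanimoto index",
                  colour = "band") +
    ggplot2::theme_minimal()
}
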