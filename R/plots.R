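# ggplot2 displays for the package's result types.

#' Volcano plot of a differential-expression result
#'
#' @param res A [nb_de_test()] result.
#' @param label_top Label this many features with the smallest q-values
#'   (default 0, no labels).
#' @return A ggplot object.
#' @export
plot_volcano <- function(res, label_top = 0) {
  dat <- as_tibble(res) %>%
    mutate(neg_log10_q = -log10(pmax(.data$q_value, 1e-300)))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, .data$neg_log10_q)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction), size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey70")
    ) +
    ggplot2::labs(
      x = "log2 fold change (case / control)",
      y = expression(-log[10] ~ "q"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    lab <- dat %>% arrange(.data$q_value) %>% head(label_top)
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = .data$feature_id),
      size = 2.5, vjust = -0.6
    )
  }
  p
}

#' @export
autoplot.herv_filter <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$threshold, .data$similarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$s_star, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "filtering threshold (normalized counts)",
      y = "mean replicate Jaccard similarity",
      title = sprintf("s* = %.3g", object$s_star)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.herv_overlap_test <- function(object, ...) {
  ggplot2::ggplot(object$null_histogram, ggplot2::aes(.data$overlap, .data$n)) +
    ggplot2::geom_col(width = 0.9, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed_overlap,
                        colour = "#c0392b", linetype = "dashed") +
    ggplot2::labs(
      x = "null intersection size",
      y = "permutations",
      title = sprintf(
        "observed = %d; p %s %.3g",
        object$observed_overlap,
        if (object$p_is_upper_bound) "<" else "=",
        object$p_empirical
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.herv_distance_test <- function(object, ...) {
  dat <- tidy.herv_distance_test(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$distance_bp + 1, colour = .data$group)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "distance to nearest gene + 1 (bp)",
      y = "ECDF",
      colour = NULL,
      title = sprintf("rank-sum p = %.3g", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.herv_em <- function(object, top = 20, ...) {
  dat <- object$proportions %>%
    arrange(dplyr::desc(.data$pi)) %>%
    head(top) %>%
    mutate(locus_id = factor(.data$locus_id, levels = rev(.data$locus_id)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$pi, .data$locus_id)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "mixture proportion", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' @param res A [score_enrichment()] or [overrepresentation_test()] result.
#' @param top Show this many sets (ordered by q-value).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(res, top = 20) {
  dat <- as_tibble(res)
  dat$set_size <- dat[["n_members_scored"]] %||% dat[["n_in_universe"]]
  dat <- dat %>%
    arrange(.data$q_value) %>%
    head(top) %>%
    mutate(
      set_name = factor(.data$set_name, levels = rev(.data$set_name)),
      neg_log10_q = -log10(pmax(.data$q_value, 1e-300))
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$neg_log10_q, .data$set_name,
                 size = .data$set_size, colour = .data$frac_de)
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = expression(-log[10] ~ "q"),
      y = NULL,
      size = "set size",
      colour = "DE fraction"
    ) +
    ggplot2::theme_minimal()
}
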