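#' Tidy the particle set of a fitted posterior
#'
#' @param x An `abc_posterior`.
#' @param ... Unused.
#' @return The particle tibble: `meiotic`, `mitotic`, `distance`,
#'   normalised `weight`.
#' @export
tidy.abc_posterior <- function(x, ...) {
  x$particles
}

#' One-row summary of a fitted posterior
#'
#' @param x An `abc_posterior`.
#' @param ... Unused.
#' @return A one-row tibble: posterior means of both rates and their 95%
#'   credible bounds, particle count, iteration count, final tolerance and
#'   final acceptance proportion.
#' @export
glance.abc_posterior <- function(x, ...) {
  s <- posterior_summary(x)
  tibble::tibble(
    mean_meiotic = s$mean[s$parameter == "meiotic"],
    mean_mitotic = s$mean[s$parameter == "mitotic"],
    ci_lower_meiotic = s$ci_lower[s$parameter == "meiotic"],
    ci_upper_meiotic = s$ci_upper[s$parameter == "meiotic"],
    ci_lower_mitotic = s$ci_lower[s$parameter == "mitotic"],
    ci_upper_mitotic = s$ci_upper[s$parameter == "mitotic"],
    n_particles = nrow(x$particles),
    n_iterations = x$n_iterations,
    final_tolerance = if (length(x$tolerance_history)) {
      utils::tail(x$tolerance_history, 1)
    } else NA_real_,
    final_p_acc = if (length(x$p_acc_history)) {
      utils::tail(x$p_acc_history, 1)
    } else NA_real_
  )
}

#' Plot the particle cloud of a fitted posterior
#'
#' Scatter of retained particles in the (meiotic, mitotic) plane, coloured
#' by distance to the target and sized by importance weight — the standard
#' view of the joint posterior and of the negative correlation between the
#' two error rates.
#'
#' @param object An `abc_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abc_posterior <- function(object, ...) {
  ggplot2::ggplot(
    object$particles,
    ggplot2::aes(x = .data$meiotic, y = .data$mitotic,
                 colour = .data$distance, size = .data$weight)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 2.5, guide = "none") +
    ggplot2::labs(
      x = "meiotic error probability (per meiosis)",
      y = "mitotic error probability (per mitosis)",
      colour = "distance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive summary
#'
#' `type = "fraction"` draws the aneuploid-cell-fraction histogram across
#' embryos; `type = "embryo_types"` the whole-embryo type proportions;
#' `type = "rebiopsy"` the first-by-second biopsy class table as a tile
#' plot of within-first-class shares.
#'
#' @param object A `predictive_tables` object.
#' @param type Which summary to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.predictive_tables <- function(object,
                                       type = c("fraction", "embryo_types",
                                                "rebiopsy"),
                                       ...) {
  type <- match.arg(type)
  if (type == "fraction") {
    binned <- object$aneuploid_fraction |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(fraction = (.data$bin - 0.5) / max(.data$bin))
    ggplot2::ggplot(binned,
                    ggplot2::aes(x = .data$fraction, y = .data$n)) +
      ggplot2::geom_col(width = 1 / max(binned$bin), fill = "steelblue") +
      ggplot2::labs(x = "proportion of aneuploid cells per embryo",
                    y = "embryos") +
      ggplot2::theme_minimal()
  } else if (type == "embryo_types") {
    ggplot2::ggplot(object$embryo_types,
                    ggplot2::aes(x = .data$embryo_type,
                                 y = .data$proportion)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "proportion of embryos") +
      ggplot2::theme_minimal()
  } else {
    shares <- object$rebiopsy |>
      dplyr::group_by(.data$first_class, .data$second_class) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
      dplyr::mutate(share = ifelse(sum(.data$n) > 0,
                                   .data$n / sum(.data$n), NA_real_)) |>
      dplyr::ungroup()
    ggplot2::ggplot(shares,
                    ggplot2::aes(x = .data$second_class,
                                 y = .data$first_class,
                                 fill = .data$share)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = ifelse(is.na(.data$share), "",
                       sprintf("%.1f%%", 100 * .data$share))
      )) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                   na.value = "grey90") +
      ggplot2::labs(x = "second biopsy", y = "first biopsy",
                    fill = "share") +
      ggplot2::theme_minimal()
  }
}

#' Plot a misclassification sweep
#'
#' Stacked inferred embryo-type proportions against the assumed
#' misclassification rate, one panel per dispersal level.
#'
#' @param sweep A [run_misclassification_sweep()] tibble.
#' @return A ggplot.
#' @export
plot_misclassification_sweep <- function(sweep) {
  long <- sweep |>
    tidyr::pivot_longer(
      c("prop_fully_euploid", "prop_mosaic_embryo", "prop_fully_aneuploid"),
      names_to = "embryo_type", values_to = "proportion"
    ) |>
    dplyr::mutate(embryo_type = sub("^prop_", "", .data$embryo_type))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$rate, y = .data$proportion,
                               fill = .data$embryo_type)) +
    ggplot2::geom_area() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dispersal),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "assumed mosaic misclassification rate",
                  y = "inferred proportion of embryos",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
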