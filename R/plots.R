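#' Relative-viscosity versus descriptor panels
#'
#' Scatter panels of average relative viscosity against SlogP, charge-group
#' count and molecular weight, with the VRA threshold drawn as a dashed line
#' and the screening filter windows shaded.
#'
#' @param table Analysis tibble from [build_analysis_table()].
#' @param threshold VRA threshold line (default 0.8).
#' @param windows Named list of filter windows to shade; defaults to the
#'   campaign windows `list(slogp = c(-2, 2), mw = c(100, 300),
#'   n_charge_groups = c(3, Inf))`. Set `NULL` to disable shading.
#' @return Named list of ggplot objects (`slogp`, `n_charge_groups`, `mw`;
#'   only panels whose column is present are built).
#' @export
plot_descriptor_panels <- function(table, threshold = 0.8,
                                   windows = list(slogp = c(-2, 2),
                                                  mw = c(100, 300),
                                                  n_charge_groups = c(3, Inf))) {
  table <- as_tibble(table)
  stopifnot("avg_rel_visc" %in% names(table))
  panels <- intersect(c("slogp", "n_charge_groups", "mw"), names(table))
  out <- lapply(panels, function(d) {
    p <- ggplot2::ggplot(table, ggplot2::aes(x = .data[[d]],
                                             y = .data$avg_rel_visc))
    win <- windows[[d]]
    if (!is.null(win)) {
      lo <- if (is.finite(win[1])) win[1] else min(table[[d]], na.rm = TRUE)
      hi <- if (is.finite(win[2])) win[2] else max(table[[d]], na.rm = TRUE)
      p <- p + ggplot2::annotate("rect", xmin = lo, xmax = hi,
                                 ymin = -Inf, ymax = Inf,
                                 alpha = 0.12, fill = "darkgreen")
    }
    p +
      ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = d, y = "average relative viscosity") +
      ggplot2::theme_minimal()
  })
  stats::setNames(out, panels)
}

#' Charge-group count versus descriptor panels
#'
#' Strip panels showing how SlogP, hydrogen-bond donors, polar surface area
#' and the PSA/SASA ratio vary with the number of charge groups. Horizontal
#' jitter is seeded so rendering is deterministic.
#'
#' @param table Analysis tibble.
#' @param descriptors Columns to panel (default `slogp`, `hbd`, `psa`,
#'   `psa_sasa`).
#' @param jitter_seed Seed for the jitter position (default 1).
#' @return Named list of ggplot objects.
#' @export
plot_charge_panels <- function(table,
                               descriptors = c("slogp", "hbd", "psa",
                                               "psa_sasa"),
                               jitter_seed = 1) {
  table <- as_tibble(table)
  stopifnot("n_charge_groups" %in% names(table))
  descriptors <- intersect(descriptors, names(table))
  out <- lapply(descriptors, function(d) {
    ggplot2::ggplot(table, ggplot2::aes(x = .data$n_charge_groups,
                                        y = .data[[d]])) +
      ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.15,
                                                              height = 0,
                                                              seed = jitter_seed),
                          alpha = 0.8) +
      ggplot2::labs(x = "charge groups", y = d) +
      ggplot2::theme_minimal()
  })
  stats::setNames(out, descriptors)
}

#' Plot an exponential viscosity baseline fit
#'
#' @param object A `vra_baseline_fit`.
#' @param measurements Optional measurement tibble; its baseline points are
#'   overlaid on the fitted curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vra_baseline_fit <- function(object, measurements = NULL, ...) {
  f <- as_tibble(unclass_tbl(object))
  curves <- f %>%
    group_by(.data$mab_id) %>%
    group_modify(function(d, key) {
      cc <- seq(d$c_min, d$c_max, length.out = 50)
      tibble(concentration_mg_ml = cc, viscosity_cp = d$a * exp(d$b * cc))
    }) %>%
    ungroup()
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$concentration_mg_ml,
                                            y = .data$viscosity_cp,
                                            colour = .data$mab_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "protein concentration (mg/mL)",
                  y = "viscosity (cP)", colour = "mAb") +
    ggplot2::theme_minimal()
  if (!is.null(measurements)) {
    base <- as_tibble(measurements) %>% filter(is.na(.data$compound_id))
    p <- p + ggplot2::geom_point(data = base)
  }
  p
}
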