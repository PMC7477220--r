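#' Tidy a fitted stock-discrimination forest
#'
#' @param x A `"tunamix_forest"`.
#' @param ... Passed to [forest_importance()].
#' @return The importance tibble, one row per feature.
#' @export
tidy.tunamix_forest <- function(x, ...) forest_importance(x, ...)

#' One-row summary of a fitted forest
#'
#' @param x A `"tunamix_forest"`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_trees`, `mtry`, `n_features`, `classes`,
#'   `oob_error_pct`.
#' @export
glance.tunamix_forest <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$training),
    n_trees = x$engine$ntree,
    mtry = x$engine$mtry,
    n_features = length(x$features),
    classes = paste(x$classes, collapse = "/"),
    oob_error_pct = oob_error(x)
  )
}

#' Tidy an assignment result into long format
#'
#' @param x A `"tunamix_assignment"`.
#' @param ... Unused.
#' @return Long tibble: `id`, `area`, `class`, `vote`, plus one label column
#'   per threshold.
#' @export
tidy.tunamix_assignment <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      dplyr::starts_with("vote_"),
                      names_to = "class", values_to = "vote",
                      names_prefix = "vote_")
}

#' Plot baseline isotope signatures by origin
#'
#' @param specimens Specimen tibble with `d13C`, `d18O` and `origin`.
#' @return A ggplot.
#' @export
plot_baseline_isotopes <- function(specimens) {
  df <- tibble::as_tibble(specimens)
  ggplot(df[!is.na(df$d18O) & !is.na(df$d13C), ],
         aes(x = .data$d13C, y = .data$d18O, colour = .data$origin)) +
    geom_point(alpha = 0.6) +
    stat_ellipse(level = 0.95) +
    labs(x = expression(delta^13 * C ~ "(‰ VPDB)"),
         y = expression(delta^18 * O ~ "(‰ VPDB)"),
         colour = "Origin") +
    theme_minimal()
}

#' Plot vote fractions with abstention bands
#'
#' @param object A `"tunamix_assignment"`.
#' @param threshold Abstention threshold drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tunamix_assignment <- function(object, threshold = 0.8, ...) {
  classes <- attr(object, "classes")
  v <- paste0("vote_", classes[1])
  df <- tibble::as_tibble(object)
  df$rank <- rank(df[[v]], ties.method = "first")
  ggplot(df, aes(x = .data$rank, y = .data[[v]])) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = c(threshold, 1 - threshold), linetype = 2) +
    labs(x = "Specimen (ranked)",
         y = sprintf("Vote fraction for %s", classes[1]),
         caption = sprintf(
           "Fish between the dashed lines are unassigned at t = %.2f", threshold)) +
    theme_minimal()
}

#' Plot observed vs simulated delta-18O densities
#'
#' @param object A `"tunamix_mixfit"` from [compare_mixture()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tunamix_mixfit <- function(object, ...) {
  ov <- tidyr::pivot_longer(object$overlay, -"x",
                            names_to = "which", values_to = "density")
  ggplot(ov, aes(x = .data$x, y = .data$density, colour = .data$which)) +
    geom_line() +
    annotate("rect", xmin = object$window[1], xmax = object$window[2],
             ymin = -Inf, ymax = Inf, alpha = 0.1) +
    scale_colour_manual(values = c(observed_density = "#1b9e77",
                                   mixture_density = "#7570b3"),
                        labels = c(observed_density = "Observed (KDE)",
                                   mixture_density = "Simulated mixture")) +
    labs(x = expression(delta^18 * O ~ "(‰ VPDB)"), y = "Density",
         colour = NULL) +
    theme_minimal()
}

#' Plot a predicted otolith delta-18O isoscape
#'
#' @param object A grid tibble with a `d18o_oto` column.
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.tunamix_grid <- function(object, ...) {
  g <- tibble::as_tibble(object)
  fill <- if ("d18o_oto" %in% names(g)) "d18o_oto" else "d18o_w"
  ggplot(g, aes(x = .data$lon, y = .data$lat, fill = .data[[fill]])) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey85") +
    coord_fixed() +
    labs(x = "Longitude", y = "Latitude",
         fill = expression(delta^18 * O ~ "(‰)")) +
    theme_minimal()
}
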