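#' Stock composition of the mixed sample, by capture area
#'
#' Per-area fractions of fish assigned to each class or unassigned, at one
#' threshold.  Optionally splits the Central Atlantic (`"CA"`) at a
#' longitude cut into `"CA (E)"`/`"CA (W)"` when the specimens carry a `lon`
#' column; the default cut is the 45 degrees W management boundary.
#'
#' @param result A `"tunamix_assignment"` result.
#' @param specimens Specimen tibble with `id` and `area` (and optionally
#'   `lon`).
#' @param threshold Which threshold's labels to tabulate (default 0.8, the
#'   abstention regime in which composition tables are usually reported).
#' @param split_ca Split Central Atlantic east/west of `ca_lon_cut`?
#' @param ca_lon_cut Longitude of the split, degrees (default -45).
#' @return Tibble of class `"tunamix_composition"`: `area`, `n`, one
#'   `prop_<label>` column per class and `prop_UA`; proportions sum to 1 per
#'   area.
#' @export
composition_by_area <- function(result, specimens, threshold = 0.8,
                                split_ca = TRUE, ca_lon_cut = -45) {
  lab_col <- sprintf("label_%d", round(100 * threshold))
  if (!lab_col %in% names(result)) {
    stop("result holds no labels at threshold ", threshold)
  }
  sp <- tibble::as_tibble(specimens)
  keep <- c("id", "area", intersect("lon", names(sp)))
  joined <- dplyr::inner_join(tibble::as_tibble(result)[c("id", lab_col)],
                              sp[keep], by = "id")
  if (split_ca && "lon" %in% names(joined)) {
    joined$area <- ifelse(
      joined$area == "CA" & !is.na(joined$lon),
      ifelse(joined$lon >= ca_lon_cut, "CA (E)", "CA (W)"),
      joined$area
    )
  }
  empty <- is.na(joined$area)
  if (any(empty)) {
    warning("omitting ", sum(empty), " specimen(s) with no area code")
    joined <- joined[!empty, ]
  }
  classes <- attr(result, "classes")
  labels <- c(classes, "UA")
  out <- joined |>
    dplyr::count(.data$area, label = factor(.data[[lab_col]], levels = labels)) |>
    tidyr::complete(.data$area, .data$label, fill = list(n = 0)) |>
    dplyr::group_by(.data$area) |>
    dplyr::mutate(prop = .data$n / sum(.data$n), n_area = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("area", "label", "prop", "n_area") |>
    tidyr::pivot_wider(names_from = "label", values_from = "prop",
                       names_prefix = "prop_") |>
    dplyr::rename(n = "n_area")
  structure(out, class = c("tunamix_composition", class(out)),
            classes = classes, threshold = threshold)
}

#' Mixing coefficients from a composition estimate
#'
#' Converts per-area (or pooled) assignment proportions into per-class
#' mixing weights for the forward mixture simulation.  Unassigned fish carry
#' no origin information, so by default their share is renormalised over the
#' assigned classes -- the only convention under which the weights form a
#' simplex.  Set `ua_policy = "error"` to refuse instead.
#'
#' @param est A [composition_by_area()] row set, or any tibble with
#'   `prop_<class>` columns and `prop_UA`.
#' @param ua_policy `"renormalise"` (default) or `"error"`.
#' @return Tibble: `area` (if present), one `weight_<class>` column per
#'   class; weights sum to 1 per row.
#' @export
mixing_coefficient <- function(est, ua_policy = c("renormalise", "error")) {
  ua_policy <- match.arg(ua_policy)
  est <- tibble::as_tibble(est)
  prop_cols <- grep("^prop_", names(est), value = TRUE)
  class_cols <- setdiff(prop_cols, "prop_UA")
  if (!length(class_cols)) stop("no class proportion columns found")
  assigned <- rowSums(est[class_cols])
  if (any(assigned <= 0)) stop("all specimens unassigned in some row(s)")
  if (ua_policy == "error" && "prop_UA" %in% names(est) &&
      any(est$prop_UA > 0)) {
    stop("unassigned fish present and ua_policy = 'error'")
  }
  out <- est[intersect(c("area", "n"), names(est))]
  for (cc in class_cols) {
    out[[sub("^prop_", "weight_", cc)]] <- est[[cc]] / assigned
  }
  out
}

#' Three-way comparison of assignment methods
#'
#' Cross-tabulates, fish by fish, the labels given by the genetics-only,
#' chemistry-only and integrated methods into a full label-cube (each axis
#' taking values in the classes plus `UA`), together with the summaries used
#' to discuss method agreement: how many fish neither single method could
#' assign, how many none of the three could, and how the integrated method
#' resolved the fish on which the single methods disagreed.
#'
#' @param genetics,chemistry,integrated `"tunamix_assignment"` results over
#'   an identical set of specimen ids.
#' @param threshold Which threshold's labels to compare (default 0.8).
#' @return Tibble of class `"tunamix_threeway"` with columns `genetics`,
#'   `chemistry`, `integrated`, `n` (all cells, zeros included) and a
#'   `summary` attribute.
#' @export
three_way <- function(genetics, chemistry, integrated, threshold = 0.8) {
  lab <- sprintf("label_%d", round(100 * threshold))
  pull_labels <- function(res, nm) {
    if (!lab %in% names(res)) stop(nm, " holds no labels at threshold ", threshold)
    stats::setNames(tibble::as_tibble(res)[c("id", lab)], c("id", nm))
  }
  g <- pull_labels(genetics, "genetics")
  c_ <- pull_labels(chemistry, "chemistry")
  i <- pull_labels(integrated, "integrated")
  if (!setequal(g$id, c_$id) || !setequal(g$id, i$id) ||
      nrow(g) != nrow(c_) || nrow(g) != nrow(i)) {
    offenders <- unique(c(
      setdiff(g$id, c_$id), setdiff(c_$id, g$id),
      setdiff(g$id, i$id), setdiff(i$id, g$id)
    ))
    stop("id mismatch between methods: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  merged <- dplyr::inner_join(dplyr::inner_join(g, c_, by = "id"), i, by = "id")
  labels <- c(attr(integrated, "classes"), "UA")
  cube <- merged |>
    dplyr::count(
      genetics = factor(.data$genetics, levels = labels),
      chemistry = factor(.data$chemistry, levels = labels),
      integrated = factor(.data$integrated, levels = labels),
      .drop = FALSE
    )
  discordant <- merged$genetics != "UA" & merged$chemistry != "UA" &
    merged$genetics != merged$chemistry
  summary <- list(
    n = nrow(merged),
    ua_both_single = sum(merged$genetics == "UA" & merged$chemistry == "UA"),
    ua_all_three = sum(merged$genetics == "UA" & merged$chemistry == "UA" &
                         merged$integrated == "UA"),
    discordant_single = sum(discordant),
    discordant_resolved = sum(discordant & merged$integrated != "UA")
  )
  structure(cube, class = c("tunamix_threeway", class(cube)),
            labels = labels, summary = summary, threshold = threshold)
}

#' @export
print.tunamix_threeway <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    paste0("<three-way comparison: n=%d; UA by both single methods=%d; ",
           "UA by all three=%d; discordant single-method pairs=%d ",
           "(%d resolved by the integrated method)>\n"),
    s$n, s$ua_both_single, s$ua_all_three,
    s$discordant_single, s$discordant_resolved))
  NextMethod()
}
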