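#' Aragonite fractionation parameters
#'
#' The otolith-seawater oxygen-isotope offset is modelled as linear in
#' temperature: `d18O_oto - d18O_w = gamma * T + beta`.  The slope and
#' intercept are species-specific, empirically derived constants and are
#' therefore mandatory configuration -- the package ships no default.  Record
#' where your values come from in `source_label`.
#'
#' For aragonite the temperature dependence of the fractionation is
#' negative; a positive `gamma` is almost certainly a sign error and draws a
#' warning.
#'
#' @param gamma Slope, permil per degree C.
#' @param beta Intercept, permil.
#' @param source_label Free-text provenance of the constants.
#' @return List of class `"tunamix_fractionation"`.
#' @export
#' @examples
#' fractionation_params(gamma = -0.2, beta = 2.5, source_label = "example values")
fractionation_params <- function(gamma, beta, source_label = "unspecified") {
  stopifnot(is.finite(gamma), is.finite(beta))
  if (gamma > 0) {
    warning("gamma > 0: aragonite-temperature fractionation slopes are negative")
  }
  structure(list(gamma = gamma, beta = beta, source_label = source_label),
            class = "tunamix_fractionation")
}

#' Predict otolith delta-18O at a point
#'
#' `d18O_oto = d18O_w + gamma * T + beta`; exactly linear in both inputs and
#' vectorised.  Missing input propagates to missing output.
#'
#' @param d18o_w Seawater delta-18O (permil).
#' @param sst Water temperature (degrees C).
#' @param params A [fractionation_params()].
#' @return Predicted otolith delta-18O (permil).
#' @export
predict_otolith <- function(d18o_w, sst, params) {
  stopifnot(inherits(params, "tunamix_fractionation"))
  d18o_w + params$gamma * sst + params$beta
}

#' Seasonal mean SST field
#'
#' Cell-wise arithmetic mean of the selected monthly SST fields; the default
#' months (July-October) are the period of fastest otolith growth, which
#' dominates the core signature.  A cell missing in any selected month is
#' missing in the mean.
#'
#' @param grid A grid tibble (see [tunamix_grid]).
#' @param months Integer months in 1..12.
#' @return Numeric vector of mean SST per cell, in grid row order.
#' @export
seasonal_sst <- function(grid, months = 7:10) {
  if (!length(months)) stop("empty month list")
  stopifnot(all(months %in% 1:12))
  m <- as.matrix(tibble::as_tibble(grid)[paste0("sst_", months)])
  rowMeans(m)
}

#' Predict the otolith delta-18O field over a grid
#'
#' Applies [predict_otolith()] cell-wise with the seasonal mean SST; land
#' (missing) cells stay missing.
#'
#' @param grid A grid tibble.
#' @param params A [fractionation_params()].
#' @param months Months for the seasonal SST mean.
#' @return The grid with a `d18o_oto` column added/replaced.
#' @export
grid_predict <- function(grid, params, months = 7:10) {
  g <- tibble::as_tibble(grid)
  g$d18o_oto <- predict_otolith(g$d18o_w, seasonal_sst(grid, months), params)
  new_grid(g)
}

#' Regional summaries of the predicted otolith delta-18O isoscape
#'
#' Mean, minimum and maximum of the non-missing predicted cells inside each
#' rectangular region (containment half-open on the max edges).  A region
#' with no ocean cells is kept in the output, flagged with `n_cells = 0` and
#' missing statistics, rather than silently dropped.
#'
#' @param grid A grid tibble with a `d18o_oto` column (see [grid_predict()]).
#' @param regions Tibble of region boxes: `name`, `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max` (e.g. [default_regions()]).
#' @return Tibble: `name`, `n_cells`, `mean`, `min`, `max` (permil).
#' @export
region_summary <- function(grid, regions) {
  g <- tibble::as_tibble(grid)
  if (!"d18o_oto" %in% names(g)) stop("grid has no predicted d18o_oto field")
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    inside <- g$lon >= r$lon_min & g$lon < r$lon_max &
      g$lat >= r$lat_min & g$lat < r$lat_max
    v <- g$d18o_oto[inside]
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(tibble::tibble(name = r$name, n_cells = 0L,
                            mean = NA_real_, min = NA_real_, max = NA_real_))
    }
    tibble::tibble(name = r$name, n_cells = length(v),
                   mean = mean(v), min = min(v), max = max(v))
  })
}
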