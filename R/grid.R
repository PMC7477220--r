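#' Gridded seawater delta-18O and SST fields
#'
#' Grids are stored in long form: one row per 1-degree (or other resolution)
#' cell centre, with columns `lon`, `lat`, `d18o_w` (seawater delta-18O,
#' permil), `sst_1` .. `sst_12` (long-term monthly mean sea-surface
#' temperature, degrees C) and, after prediction, `d18o_oto` (predicted
#' otolith delta-18O, permil).  Land cells carry `NA` in the value fields and
#' the missingness propagates through every downstream computation.
#'
#' Longitudes are cell-centred in [-180, 180) and latitudes ascending.
#'
#' @name tunamix_grid
NULL

# internal constructor + invariant checks
new_grid <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("lon", "lat", "d18o_w", paste0("sst_", 1:12))
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("grid is missing fields: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df[c("lon", "lat")])) stop("duplicate grid cells")
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude outside [-90, 90]")
  df$lon <- wrap_lon(df$lon)
  structure(dplyr::arrange(df, .data$lat, .data$lon),
            class = c("tunamix_grid", class(df)))
}

# normalise longitudes to [-180, 180)
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Read co-registered delta-18O-water and SST grids from delimited text
#'
#' Accepts either a single long-format file carrying all fields, or a pair of
#' files (one with seawater delta-18O, one with the twelve monthly SST
#' fields) sharing identical lon/lat axes.  No regridding is performed:
#' mismatched axes between the two files are an error, because silently
#' interpolating two climatologies onto each other is exactly the kind of
#' decision the analyst must make upstream.
#'
#' @param path Path to the combined grid file, or the delta-18O-water file
#'   when `sst_path` is given.
#' @param sst_path Optional path to a separate SST file.
#' @param variable_map Named character vector mapping internal names
#'   (`lon`, `lat`, `d18o_w`, `sst_1` .. `sst_12`) to the column names used
#'   in the file(s).  Defaults to the internal names.
#' @return A grid tibble (see [tunamix_grid]).
#' @export
read_grid <- function(path, sst_path = NULL, variable_map = NULL) {
  vm <- c(lon = "lon", lat = "lat", d18o_w = "d18o_w",
          stats::setNames(paste0("sst_", 1:12), paste0("sst_", 1:12)))
  if (!is.null(variable_map)) vm[names(variable_map)] <- variable_map

  read_one <- function(p) {
    header <- readLines(p, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
    # parse numerics through strtod (correctly rounded) so that a %.17g
    # write/read cycle is bit-exact
    raw <- readr::read_delim(p, delim = delim, show_col_types = FALSE,
                             progress = FALSE,
                             col_types = readr::cols(.default = "c"))
    dplyr::mutate(raw, dplyr::across(dplyr::everything(), as.numeric))
  }
  rename_known <- function(df) {
    for (internal in names(vm)) {
      if (vm[[internal]] %in% names(df) && internal != vm[[internal]]) {
        names(df)[names(df) == vm[[internal]]] <- internal
      }
    }
    df
  }
  a <- rename_known(read_one(path))
  if (is.null(sst_path)) return(new_grid(a))
  b <- rename_known(read_one(sst_path))
  key_a <- paste(wrap_lon(a$lon), a$lat)
  key_b <- paste(wrap_lon(b$lon), b$lat)
  if (!setequal(key_a, key_b) || length(key_a) != length(key_b)) {
    stop("dimension error: delta-18O-water and SST grids have different lon/lat axes")
  }
  merged <- dplyr::inner_join(
    dplyr::mutate(a, lon = wrap_lon(.data$lon)),
    dplyr::mutate(b, lon = wrap_lon(.data$lon)),
    by = c("lon", "lat")
  )
  new_grid(merged)
}

#' Write a grid to delimited text
#'
#' Full double precision is kept so that a write/read cycle is lossless.
#'
#' @param grid A grid tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  out <- dplyr::mutate(tibble::as_tibble(grid),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ ifelse(is.na(.x), NA, sprintf("%.17g", .x))))
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Rectangular named region on the grid
#'
#' @param name Region label.
#' @param lon_min,lon_max,lat_min,lat_max Bounds in degrees.  Containment is
#'   half-open on the max edges (`lon_min <= lon < lon_max`) so adjacent
#'   boxes never double-count a cell.
#' @return One-row tibble of class `"tunamix_region"`.
#' @export
region_box <- function(name, lon_min, lon_max, lat_min, lat_max) {
  stopifnot(lon_min < lon_max, lat_min < lat_max,
            lat_min >= -90, lat_max <= 90)
  structure(tibble::tibble(name = name, lon_min = lon_min, lon_max = lon_max,
                           lat_min = lat_min, lat_max = lat_max),
            class = c("tunamix_region", "tbl_df", "tbl", "data.frame"))
}

#' Approximate bounding boxes for the areas of interest
#'
#' Editable configuration shipped with the package: approximate rectangular
#' bounds for the named larval/yearling occurrence regions and the Central
#' Atlantic migration corridor.  The bounds are deliberately coarse
#' (rectangles on a 1-degree grid) and are meant to be replaced by the
#' analyst's own definitions where precision matters.
#'
#' @return Tibble with one row per region.
#' @export
default_regions <- function() {
  path <- system.file("extdata", "regions.csv", package = "tunamix")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
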