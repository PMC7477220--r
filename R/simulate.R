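#' Parameters describing one spawning population
#'
#' Each population is characterised by a bivariate Gaussian over the otolith
#' core isotope signature (delta-13C, delta-18O) and by an alt-allele
#' frequency per SNP marker; genotype calls are drawn under Hardy-Weinberg
#' equilibrium.  The default presets emulate the two Atlantic bluefin tuna
#' spawning populations: Mediterranean fish centre near -0.7 permil delta-18O
#' and Gulf of Mexico fish near -1.5 permil, the separation on which stock
#' discrimination rests.  Within-population spreads and delta-13C centres are
#' configuration, not literature claims; the defaults (sd_d18O = 0.30,
#' sd_d13C = 0.5 permil, rho = 0.2) give the moderate overlap regime in which
#' abstention thresholds are actually exercised.
#'
#' @param name Population label, e.g. `"GoM"` or `"Med"`.
#' @param mu_d18O,sd_d18O delta-18O mean and SD (permil VPDB).
#' @param mu_d13C,sd_d13C delta-13C mean and SD (permil VPDB).
#' @param rho Correlation between the two isotopes, in [-1, 1].
#' @param allele_freq Named numeric vector, marker id -> alt-allele frequency
#'   in [0, 1].
#' @return List of class `"tunamix_population"`.
#' @export
#' @examples
#' population_params("Med", mu_d18O = -0.7)
population_params <- function(name, mu_d18O, sd_d18O = 0.30,
                              mu_d13C = -8.75, sd_d13C = 0.5, rho = 0.2,
                              allele_freq = numeric()) {
  stopifnot(sd_d18O > 0, sd_d13C > 0, abs(rho) <= 1,
            all(allele_freq >= 0 & allele_freq <= 1))
  structure(list(name = name, mu_d18O = mu_d18O, sd_d18O = sd_d18O,
                 mu_d13C = mu_d13C, sd_d13C = sd_d13C, rho = rho,
                 allele_freq = allele_freq),
            class = "tunamix_population")
}

#' Default two-population presets
#'
#' Mediterranean and Gulf of Mexico presets with the four default markers
#' (RAD2, RAD26, RAD35, RAD213) at strongly divergent alt-allele frequencies
#' (0.15 vs 0.85), so the genetics-only model is informative but imperfect.
#' No attempt is made to calibrate the frequencies against any real panel.
#'
#' @return Named list of two [population_params()] objects.
#' @export
default_populations <- function() {
  markers <- c("RAD2", "RAD26", "RAD35", "RAD213")
  list(
    Med = population_params("Med", mu_d18O = -0.7, mu_d13C = -8.5,
                            allele_freq = stats::setNames(rep(0.15, 4), markers)),
    GoM = population_params("GoM", mu_d18O = -1.5, mu_d13C = -9.0,
                            allele_freq = stats::setNames(rep(0.85, 4), markers))
  )
}

# internal: n draws from a population's bivariate isotope Gaussian
draw_isotopes <- function(pop, n) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  d13C <- pop$mu_d13C + pop$sd_d13C * z1
  d18O <- pop$mu_d18O + pop$sd_d18O * (pop$rho * z1 + sqrt(1 - pop$rho^2) * z2)
  tibble::tibble(d13C = d13C, d18O = d18O)
}

# internal: Hardy-Weinberg genotype draws for every marker of a population
draw_genotypes <- function(pop, n) {
  cols <- lapply(pop$allele_freq, function(p) {
    g <- stats::rbinom(n, 2L, p)
    factor(c("ref", "het", "alt")[g + 1L], levels = genotype_levels())
  })
  tibble::new_tibble(cols, nrow = n)  # keeps n rows even with no markers
}

#' Simulate a two-(or more-)population baseline
#'
#' Draws `n_per_pop` fish from each population: isotope signatures from the
#' population's bivariate Gaussian, genotype calls per marker under
#' Hardy-Weinberg from the population's allele frequencies, origin labels set
#' to the population names.
#'
#' @param populations Named list of [population_params()]; default
#'   [default_populations()].
#' @param n_per_pop Integer vector (recycled) of fish per population; each
#'   must be at least 2 so the baseline can be bootstrapped later.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A baseline specimen tibble (see [read_specimens()] for layout).
#' @export
#' @examples
#' b <- make_baseline(n_per_pop = 25, seed = 1)
#' dplyr::count(b, origin)
make_baseline <- function(populations = default_populations(),
                          n_per_pop = 100, seed) {
  stopifnot(length(populations) >= 2, !missing(seed))
  n_per_pop <- rep_len(as.integer(n_per_pop), length(populations))
  if (any(n_per_pop < 2L)) stop("n_per_pop must be >= 2 for every population")
  markers <- unique(unlist(lapply(populations, function(p) names(p$allele_freq))))
  withr::with_seed(as.integer(seed), {
    parts <- purrr::map2(populations, n_per_pop, function(pop, n) {
      iso <- draw_isotopes(pop, n)
      gen <- draw_genotypes(pop, n)
      dplyr::bind_cols(
        tibble::tibble(origin = pop$name, area = pop$name,
                       year = NA_integer_, length_cm = NA_real_),
        iso, gen
      )
    })
    out <- dplyr::bind_rows(parts)
  })
  out <- dplyr::mutate(out, id = sprintf("S%04d", dplyr::row_number()),
                       .before = 1)
  new_specimens(out, role = "baseline", markers = markers)
}

#' Design of a simulated mixed sample
#'
#' @param components List of [population_params()] for each mixture
#'   component (an optional third, "intermediate" component with delta-18O
#'   between -1.2 and -1.4 permil can be added to emulate fish characteristic
#'   of neither baseline).
#' @param weights Nonnegative mixing weights summing to 1.
#' @param n Number of fish.
#' @param missing_rate Per-marker probability in [0, 1) that a genotype call
#'   is masked to missing (genotyping dropout).
#' @param area Area code stamped on the specimens.
#' @return List of class `"tunamix_mixture_design"`.
#' @export
mixture_design <- function(components, weights, n, missing_rate = 0,
                           area = "CA") {
  stopifnot(length(components) == length(weights), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8, n >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(components = components, weights = weights, n = n,
                 missing_rate = missing_rate, area = area),
            class = "tunamix_mixture_design")
}

#' Simulate a mixed sample of unknown-origin fish
#'
#' Each fish's component is drawn by the design weights; isotopes and
#' genotypes are then drawn from that component as in [make_baseline()].
#' The true component travels in a ground-truth sidecar (the `truth`
#' attribute, also returned by [mixture_truth()]), never in the specimen
#' table itself: the file handed to the assigner carries `origin = "unknown"`.
#'
#' @param design A [mixture_design()].
#' @param seed Integer seed.
#' @return A mixed specimen tibble; `mixture_truth()` recovers the hidden
#'   per-fish component labels.
#' @export
make_mixed <- function(design, seed) {
  stopifnot(inherits(design, "tunamix_mixture_design"), !missing(seed))
  markers <- unique(unlist(lapply(design$components,
                                  function(p) names(p$allele_freq))))
  withr::with_seed(as.integer(seed), {
    comp <- sample.int(length(design$components), design$n, replace = TRUE,
                       prob = design$weights)
    parts <- lapply(seq_along(design$components), function(k) {
      idx <- which(comp == k)
      if (!length(idx)) return(NULL)
      pop <- design$components[[k]]
      dplyr::bind_cols(
        tibble::tibble(.row = idx, .true = pop$name),
        draw_isotopes(pop, length(idx)),
        draw_genotypes(pop, length(idx))
      )
    })
    out <- dplyr::arrange(dplyr::bind_rows(parts), .data$.row)
    if (design$missing_rate > 0 && length(markers)) {
      for (m in markers) {
        mask <- stats::runif(design$n) < design$missing_rate
        out[[m]][mask] <- NA
      }
    }
  })
  truth <- tibble::tibble(id = sprintf("M%05d", out$.row), true = out$.true)
  out <- dplyr::transmute(
    out,
    id = sprintf("M%05d", .data$.row), origin = "unknown",
    area = design$area, year = NA_integer_, length_cm = NA_real_,
    d13C = .data$d13C, d18O = .data$d18O,
    dplyr::across(dplyr::all_of(markers), identity)
  )
  out <- new_specimens(out, role = "mixed", markers = markers)
  attr(out, "truth") <- truth
  out
}

#' @rdname make_mixed
#' @param specimens A mixed specimen set created by `make_mixed()`.
#' @export
mixture_truth <- function(specimens) {
  t <- attr(specimens, "truth")
  if (is.null(t)) stop("no ground-truth sidecar attached to this specimen set")
  t
}

#' Simulate a smooth gridded delta-18O-water / SST fixture
#'
#' Produces fields with known, simple spatial structure: seawater delta-18O
#' and SST both decline linearly with latitude, SST carries a sinusoidal
#' seasonal cycle, and a small seeded smooth perturbation is added so the
#' fields are not exactly collinear.  A land mask can be injected either as a
#' fraction of randomly-drawn cells or as an explicit predicate.
#'
#' @param lon_range,lat_range Numeric length-2 extents in degrees.
#' @param res Cell size in degrees (cells are centred at
#'   `min + res/2, ...`).
#' @param seed Integer seed.
#' @param sst_equator Mean SST at latitude 0 (degrees C).
#' @param sst_lat_slope SST change per degree latitude (degrees C / degree).
#' @param d18o_equator,d18o_lat_slope Same for seawater delta-18O (permil).
#' @param seasonal_amp Amplitude of the SST seasonal cycle (degrees C).
#' @param noise_sd SD of the seeded cell-level perturbation.
#' @param land_frac Fraction of cells masked to missing.
#' @return A grid tibble (see [tunamix_grid]).
#' @export
make_grid <- function(lon_range = c(-100, 40), lat_range = c(0, 60), res = 1,
                      seed, sst_equator = 28, sst_lat_slope = -0.35,
                      d18o_equator = 1, d18o_lat_slope = -0.02,
                      seasonal_amp = 3, noise_sd = 0.05, land_frac = 0) {
  stopifnot(!missing(seed), diff(lon_range) > 0, diff(lat_range) > 0, res > 0)
  if (lon_range[1] + res / 2 > lon_range[2] ||
      lat_range[1] + res / 2 > lat_range[2]) {
    stop("empty grid extent: no cell centre fits inside the ranges at this resolution")
  }
  lon <- seq(lon_range[1] + res / 2, lon_range[2], by = res)
  lat <- seq(lat_range[1] + res / 2, lat_range[2], by = res)
  cells <- tidyr::expand_grid(lat = lat, lon = lon)
  withr::with_seed(as.integer(seed), {
    cells$d18o_w <- d18o_equator + d18o_lat_slope * cells$lat +
      stats::rnorm(nrow(cells), 0, noise_sd)
    base_sst <- sst_equator + sst_lat_slope * cells$lat +
      stats::rnorm(nrow(cells), 0, noise_sd)
    for (m in 1:12) {
      cells[[paste0("sst_", m)]] <-
        base_sst + seasonal_amp * cos(2 * pi * (m - 8) / 12)
    }
    if (land_frac > 0) {
      land <- stats::runif(nrow(cells)) < land_frac
      value_cols <- c("d18o_w", paste0("sst_", 1:12))
      cells[land, value_cols] <- NA_real_
    }
  })
  new_grid(dplyr::relocate(cells, "lon", "lat"))
}
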