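#' Gaussian mixture specification for delta-18O
#'
#' A small container for the forward simulation: two (optionally three)
#' Gaussian delta-18O components with mixing weights on the simplex.
#'
#' @param labels Component labels.
#' @param mu,sigma Component means and SDs (permil); `sigma > 0`.
#' @param weights Nonnegative weights summing to 1.
#' @return Tibble of class `"tunamix_mixture_spec"` with one row per
#'   component.
#' @export
mixture_spec <- function(labels, mu, sigma, weights) {
  stopifnot(length(labels) == length(mu), length(mu) == length(sigma),
            length(sigma) == length(weights),
            all(sigma > 0), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  structure(tibble::tibble(label = labels, mu = mu, sigma = sigma,
                           weight = weights),
            class = c("tunamix_mixture_spec", "tbl_df", "tbl", "data.frame"))
}

#' Mixture components matched to the baseline populations
#'
#' Sets each component's mean and SD to the sample mean and SD of the
#' corresponding population's delta-18O values in the baseline, and attaches
#' the supplied mixing weights -- the distribution the mixed sample would
#' follow if it were drawn at random from the same populations as the
#' baseline, in those proportions.
#'
#' @param baseline Baseline specimen tibble (each population needs at least
#'   two non-missing delta-18O values).
#' @param weights Named numeric vector, population -> weight (weights for a
#'   subset of populations are allowed if they sum to 1; a zero-weight
#'   component is kept, degenerate specs are legal).
#' @return A [mixture_spec()].
#' @export
mixture_from_baseline <- function(baseline, weights) {
  df <- tibble::as_tibble(baseline)
  pops <- names(weights)
  if (is.null(pops)) stop("weights must be named by population")
  stats <- purrr::map_dfr(pops, function(p) {
    v <- df$d18O[df$origin == p & !is.na(df$d18O)]
    if (length(v) < 2L) {
      stop("population ", p, " has fewer than 2 delta-18O values")
    }
    tibble::tibble(label = p, mu = mean(v), sigma = stats::sd(v))
  })
  mixture_spec(stats$label, stats$mu, stats$sigma, unname(weights[pops]))
}

#' Draw from a delta-18O mixture
#'
#' Component indices are multinomial in the weights; values are Gaussian per
#' component.  Deterministic under the seed.
#'
#' @param spec A [mixture_spec()].
#' @param n Number of draws (the forward comparison conventionally uses 1e6).
#' @param seed Integer seed.
#' @return Numeric vector of delta-18O draws, with the component index
#'   attached as attribute `"component"`.
#' @export
draw_mixture <- function(spec, n, seed) {
  stopifnot(n >= 1, !missing(seed))
  withr::with_seed(as.integer(seed), {
    k <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$weight)
    x <- stats::rnorm(n, spec$mu[k], spec$sigma[k])
  })
  attr(x, "component") <- spec$label[k]
  x
}

#' Closed-form mixture density
#'
#' @param spec A [mixture_spec()].
#' @param x Evaluation points (permil).
#' @return Density values `sum_k w_k dnorm(x, mu_k, sigma_k)`.
#' @export
mixture_density <- function(spec, x) {
  rowSums(vapply(seq_len(nrow(spec)),
                 function(k) spec$weight[k] *
                   stats::dnorm(x, spec$mu[k], spec$sigma[k]),
                 numeric(length(x))) |> matrix(nrow = length(x)))
}

#' Mixture cumulative distribution function
#' @rdname mixture_density
#' @export
mixture_cdf <- function(spec, x) {
  rowSums(vapply(seq_len(nrow(spec)),
                 function(k) spec$weight[k] *
                   stats::pnorm(x, spec$mu[k], spec$sigma[k]),
                 numeric(length(x))) |> matrix(nrow = length(x)))
}

#' Compare observed delta-18O values with a simulated mixture
#'
#' Quantifies how well the observed delta-18O distribution matches the
#' two-component mixture expected if the sample were drawn at random from
#' the baseline populations in the estimated proportions:
#'
#' * the Kolmogorov-Smirnov distance between the observed empirical CDF and
#'   the mixture CDF (with its asymptotic 5 percent critical value
#'   `1.358/sqrt(n)` for reference);
#' * observed-minus-expected probability mass in a delta-18O window,
#'   by default [-1.4, -1.2] permil -- the "intermediate" band in which an
#'   excess of fish signals a contingent characteristic of neither baseline
#'   population -- with its binomial standard error;
#' * a kernel-density overlay (Gaussian kernel, Silverman bandwidth) of the
#'   observed values against the closed-form mixture density on a shared
#'   grid, for plotting only.
#'
#' @param observed Numeric vector of observed delta-18O values (>= 20).
#' @param spec A [mixture_spec()].
#' @param window Length-2 delta-18O window (permil).
#' @param grid_n Points in the overlay grid.
#' @return List of class `"tunamix_mixfit"`: `ks_distance`, `ks_critical_5pct`,
#'   `window`, `observed_mass`, `expected_mass`, `excess_mass`, `excess_se`,
#'   and an `overlay` tibble (`x`, `observed_density`, `mixture_density`).
#' @export
compare_mixture <- function(observed, spec, window = c(-1.4, -1.2),
                            grid_n = 512) {
  observed <- observed[!is.na(observed)]
  if (length(observed) < 20L) stop("need at least 20 observed values")
  stopifnot(length(window) == 2L, window[1] < window[2])
  n <- length(observed)
  xs <- sort(observed)
  cdf <- mixture_cdf(spec, xs)
  # exact two-sided KS distance of the empirical CDF from the mixture CDF
  d <- max(pmax(seq_len(n) / n - cdf, cdf - (seq_len(n) - 1) / n))
  obs_mass <- mean(observed >= window[1] & observed <= window[2])
  exp_mass <- mixture_cdf(spec, window[2]) - mixture_cdf(spec, window[1])
  lo <- min(observed, spec$mu - 4 * spec$sigma)
  hi <- max(observed, spec$mu + 4 * spec$sigma)
  grid <- seq(lo, hi, length.out = grid_n)
  kde <- stats::density(observed, kernel = "gaussian", bw = "nrd0",
                        from = lo, to = hi, n = grid_n)
  structure(
    list(ks_distance = d,
         ks_critical_5pct = 1.358 / sqrt(n),
         n = n,
         window = window,
         observed_mass = obs_mass,
         expected_mass = exp_mass,
         excess_mass = obs_mass - exp_mass,
         excess_se = sqrt(exp_mass * (1 - exp_mass) / n),
         overlay = tibble::tibble(x = grid,
                                  observed_density = kde$y,
                                  mixture_density = mixture_density(spec, grid))),
    class = "tunamix_mixfit"
  )
}

#' @export
print.tunamix_mixfit <- function(x, ...) {
  cat(sprintf(
    paste0("<mixture fit: n=%d, KS distance=%.4f (5%% critical %.4f); ",
           "mass in [%.2f, %.2f]: observed %.4f, expected %.4f, ",
           "excess %+.4f (SE %.4f)>\n"),
    x$n, x$ks_distance, x$ks_critical_5pct, x$window[1], x$window[2],
    x$observed_mass, x$expected_mass, x$excess_mass, x$excess_se))
  invisible(x)
}
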