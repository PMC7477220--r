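test_that("baseline-matched specs carry each population's sample moments", {
  base <- tibble::tibble(
    id = as.character(1:4),
    origin = c("A", "A", "B", "B"),
    d18O = c(-1, -2, 0, -0.4)
  )
  spec <- mixture_from_baseline(base, c(A = 0.3, B = 0.7))
  expect_equal(spec$mu, c(-1.5, -0.2))
  expect_equal(spec$sigma, c(sd(c(-1, -2)), sd(c(0, -0.4))))
  expect_equal(spec$weight, c(0.3, 0.7))
  # degenerate weights are accepted
  spec10 <- mixture_from_baseline(base, c(A = 1, B = 0))
  expect_equal(spec10$weight, c(1, 0))
  expect_error(mixture_from_baseline(base[1:3, ], c(A = 0.5, B = 0.5)),
               "fewer than 2")
})

test_that("synthetic baselines at scale recover the preset component means", {
  b <- make_baseline(n_per_pop = 3000, seed = 21)
  spec <- mixture_from_baseline(b, c(GoM = 0.1, Med = 0.9))
  expect_equal(spec$mu[spec$label == "GoM"], -1.5, tolerance = 0.03)
  expect_equal(spec$mu[spec$label == "Med"], -0.7, tolerance = 0.03)
})

test_that("mixture draws follow the weights and component moments", {
  spec <- mixture_spec(c("a", "b"), c(-1.5, -0.7), c(1e-12, 1e-12), c(1, 0))
  x <- draw_mixture(spec, 100, seed = 1)
  expect_true(all(abs(x - (-1.5)) < 1e-9))

  spec2 <- mixture_spec(c("a", "b"), c(-1.5, -0.7), c(0.3, 0.3), c(0.1, 0.9))
  y <- draw_mixture(spec2, 1e6, seed = 2)
  frac_a <- mean(attr(y, "component") == "a")
  expect_lt(abs(frac_a - 0.1), 0.001)
  true_mean <- sum(spec2$weight * spec2$mu)
  true_var <- sum(spec2$weight * (spec2$sigma^2 + spec2$mu^2)) - true_mean^2
  expect_lt(abs(mean(y) - true_mean), 4 * sqrt(true_var / 1e6))
  expect_identical(draw_mixture(spec2, 100, seed = 3),
                   draw_mixture(spec2, 100, seed = 3))
})

test_that("the closed-form density is symmetric, normalised, and matches draws", {
  spec <- mixture_spec(c("a", "b"), c(-1, 1), c(0.4, 0.4), c(0.5, 0.5))
  grid <- seq(-6, 6, length.out = 4001)
  dens <- mixture_density(spec, grid)
  expect_equal(dens, rev(dens), tolerance = 1e-12)   # symmetric about 0
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  expect_lt(abs(integral - 1), 1e-4)

  spec2 <- mixture_spec(c("GoM", "Med"), c(-1.5, -0.7), c(0.25, 0.3), c(0.2, 0.8))
  x <- draw_mixture(spec2, 1e6, seed = 5)
  breaks <- seq(-3, 0.5, by = 0.1)
  h <- hist(x[x >= -3 & x <= 0.5], breaks = breaks, plot = FALSE)
  expected_p <- diff(mixture_cdf(spec2, breaks))
  observed_p <- h$counts / length(x)
  se <- sqrt(expected_p * (1 - expected_p) / length(x))
  expect_true(all(abs(observed_p - expected_p) < 5 * se + 1e-5))
})

test_that("KS stays below its critical value for samples drawn from the spec itself", {
  spec <- mixture_spec(c("GoM", "Med"), c(-1.5, -0.7), c(0.3, 0.3), c(0.2, 0.8))
  below <- withr::with_seed(31, {
    purrr::map_lgl(1:50, function(r) {
      o <- draw_mixture(spec, 1e4, seed = sample.int(1e8, 1))
      f <- compare_mixture(o, spec)
      f$ks_distance < f$ks_critical_5pct
    })
  })
  expect_gte(mean(below), 0.9)
})

test_that("an injected intermediate component produces significant window excess", {
  spec <- mixture_spec(c("GoM", "Med"), c(-1.5, -0.7), c(0.25, 0.25), c(0.2, 0.8))
  with_third <- mixture_spec(c("GoM", "Med", "Int"),
                             c(-1.5, -0.7, -1.3), c(0.25, 0.25, 0.05),
                             c(0.16, 0.64, 0.2))
  obs <- draw_mixture(with_third, 5000, seed = 8)
  fit <- compare_mixture(obs, spec)
  expect_gt(fit$excess_mass, 3 * fit$excess_se)
  expect_gt(fit$ks_distance, fit$ks_critical_5pct)
})

test_that("an empty intermediate band on both sides gives zero excess", {
  spec <- mixture_spec(c("a", "b"), c(5, 8), c(0.1, 0.1), c(0.5, 0.5))
  obs <- draw_mixture(spec, 1000, seed = 9)
  fit <- compare_mixture(obs, spec, window = c(-1.4, -1.2))
  expect_equal(fit$observed_mass, 0)
  expect_lt(fit$expected_mass, 1e-12)
  expect_equal(fit$excess_mass, 0, tolerance = 1e-12)
})

test_that("the comparison is invariant to observation order", {
  spec <- mixture_spec(c("a", "b"), c(-1.5, -0.7), c(0.3, 0.3), c(0.3, 0.7))
  obs <- draw_mixture(spec, 500, seed = 10)
  f1 <- compare_mixture(obs, spec)
  f2 <- compare_mixture(rev(obs), spec)
  expect_equal(f1$ks_distance, f2$ks_distance)
  expect_equal(f1$excess_mass, f2$excess_mass)
  expect_error(compare_mixture(obs[1:10], spec), "at least 20")
})
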