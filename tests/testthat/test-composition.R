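fake_result <- function(ids, labels, areas = "CA", classes = c("GoM", "Med"),
                        threshold = 80) {
  votes <- ifelse(labels == "GoM", 0.9, ifelse(labels == "Med", 0.1, 0.6))
  res <- tibble::tibble(id = ids, area = rep_len(areas, length(ids)),
                        vote_GoM = votes, vote_Med = 1 - votes)
  res[[paste0("label_", threshold)]] <- labels
  attr(res, "classes") <- classes
  class(res) <- c("tunamix_assignment", class(res))
  res
}

test_that("area composition reproduces hand counts and handles degenerate areas", {
  ids <- sprintf("m%02d", 1:10)
  res <- fake_result(ids, c("GoM", "GoM", rep("Med", 6), "UA", "UA"))
  sp <- tibble::tibble(id = ids, area = "CA")
  est <- composition_by_area(res, sp, split_ca = FALSE)
  expect_equal(est$prop_GoM, 0.2)
  expect_equal(est$prop_Med, 0.6)
  expect_equal(est$prop_UA, 0.2)
  expect_equal(est$n, 10)

  one_label <- fake_result(ids, rep("Med", 10))
  est1 <- composition_by_area(one_label, sp, split_ca = FALSE)
  expect_equal(est1$prop_Med, 1)
  expect_equal(est1$prop_GoM + est1$prop_UA, 0)

  sp_na <- dplyr::mutate(sp, area = ifelse(id == "m01", NA, area))
  expect_warning(composition_by_area(res, sp_na, split_ca = FALSE), "omitting")
})

test_that("proportions recomputed from raw label counts agree exactly", {
  withr::with_seed(99, {
    for (r in 1:10) {
      n <- sample(20:60, 1)
      ids <- sprintf("r%03d", 1:n)
      labels <- sample(c("GoM", "Med", "UA"), n, replace = TRUE)
      areas <- sample(c("CA", "MO", "PO"), n, replace = TRUE)
      res <- fake_result(ids, labels)
      sp <- tibble::tibble(id = ids, area = areas)
      est <- composition_by_area(res, sp, split_ca = FALSE)
      for (a in unique(areas)) {
        expect_equal(est$prop_GoM[est$area == a],
                     mean(labels[areas == a] == "GoM"))
      }
      expect_equal(est$prop_GoM + est$prop_Med + est$prop_UA,
                   rep(1, nrow(est)))
    }
  })
})

test_that("the Central Atlantic splits east/west at the longitude cut", {
  ids <- sprintf("c%d", 1:4)
  res <- fake_result(ids, c("Med", "Med", "GoM", "UA"))
  sp <- tibble::tibble(id = ids, area = "CA", lon = c(-50, -60, -30, -10))
  est <- composition_by_area(res, sp)
  expect_setequal(est$area, c("CA (E)", "CA (W)"))
  expect_equal(est$n[est$area == "CA (W)"], 2)
})

test_that("mixing coefficients renormalise over assigned fish", {
  est <- tibble::tibble(area = "CA", n = 10, prop_GoM = 0.2, prop_Med = 0.6,
                        prop_UA = 0.2)
  w <- mixing_coefficient(est)
  expect_equal(w$weight_GoM, 0.25)
  expect_equal(w$weight_Med, 0.75)
  no_ua <- tibble::tibble(prop_GoM = 0.3, prop_Med = 0.7, prop_UA = 0)
  expect_equal(mixing_coefficient(no_ua)$weight_GoM, 0.3)
  expect_error(mixing_coefficient(est, "error"), "unassigned")
  all_ua <- tibble::tibble(prop_GoM = 0, prop_Med = 0, prop_UA = 1)
  expect_error(mixing_coefficient(all_ua), "all specimens unassigned")
})

test_that("random composition rows always give weights on the simplex", {
  withr::with_seed(5, {
    for (r in 1:100) {
      p <- as.numeric(stats::rmultinom(1, 50, runif(3))) / 50
      est <- tibble::tibble(prop_GoM = p[1], prop_Med = p[2], prop_UA = p[3])
      if (p[1] + p[2] == 0) {
        expect_error(mixing_coefficient(est))
      } else {
        w <- mixing_coefficient(est)
        expect_equal(w$weight_GoM + w$weight_Med, 1, tolerance = 1e-12)
        expect_true(all(c(w$weight_GoM, w$weight_Med) >= 0))
      }
    }
  })
})

test_that("the three-way cube counts cells and keeps marginals consistent", {
  ids <- sprintf("f%d", 1:5)
  g <- fake_result(ids, c("Med", "Med", "GoM", "UA", "Med"))
  c_ <- fake_result(ids, c("Med", "GoM", "GoM", "UA", "Med"))
  i <- fake_result(ids, c("Med", "UA", "GoM", "Med", "Med"))
  cube <- three_way(g, c_, i)
  expect_equal(sum(cube$n), 5)
  cell <- cube$n[cube$genetics == "Med" & cube$chemistry == "GoM" &
                   cube$integrated == "UA"]
  expect_equal(cell, 1)
  # marginals equal each method's label counts
  marg <- function(cube, axis) {
    tapply(cube$n, cube[[axis]], sum)
  }
  expect_equal(as.numeric(marg(cube, "genetics")[c("GoM", "Med", "UA")]),
               as.numeric(table(factor(g$label_80, c("GoM", "Med", "UA")))))
  expect_equal(as.numeric(marg(cube, "chemistry")[c("GoM", "Med", "UA")]),
               as.numeric(table(factor(c_$label_80, c("GoM", "Med", "UA")))))
  s <- attr(cube, "summary")
  expect_equal(s$ua_both_single, 1)
  expect_equal(s$ua_all_three, 0)
  expect_equal(s$discordant_single, 1)
  expect_equal(s$discordant_resolved, 0)
})

test_that("agreement everywhere populates only diagonal cells", {
  ids <- sprintf("d%d", 1:6)
  labs <- c("Med", "Med", "GoM", "GoM", "UA", "Med")
  cube <- three_way(fake_result(ids, labs), fake_result(ids, labs),
                    fake_result(ids, labs))
  off <- cube$n[!(cube$genetics == cube$chemistry &
                    cube$chemistry == cube$integrated)]
  expect_true(all(off == 0))
})

test_that("mismatched id sets are refused with the offenders listed", {
  g <- fake_result(c("a", "b"), c("Med", "Med"))
  h <- fake_result(c("a", "zzz"), c("Med", "Med"))
  expect_error(three_way(g, h, g), "zzz")
})
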