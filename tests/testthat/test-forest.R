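test_that("perfect 1-D separation gives zero OOB error", {
  b <- toy_separable()
  fit <- fit_forest(b, c("f1", "f2"), forest_config(n_trees = 100, seed = 1))
  expect_equal(oob_error(fit), 0)
})

test_that("shuffled labels push OOB error to chance (permutation null)", {
  errs <- purrr::map_dbl(1:8, function(r) {
    d <- withr::with_seed(100 + r, {
      n <- 300
      tibble::tibble(id = as.character(1:n),
                     origin = sample(rep(c("A", "B"), each = n / 2)),
                     f1 = rnorm(n), f2 = rnorm(n))
    })
    oob_error(fit_forest(d, c("f1", "f2"),
                         forest_config(n_trees = 150, seed = r)))
  })
  # balanced classes: chance = 50%
  expect_lt(abs(mean(errs) - 50), 5)
})

test_that("OOB error equals its recomputation from the stored OOB votes", {
  b <- make_baseline(n_per_pop = 60, seed = 2)
  fit <- fit_forest(b, c("d13C", "d18O"), forest_config(n_trees = 200, seed = 2))
  v <- as.matrix(fit$oob_votes[paste0("vote_", fit$classes)])
  pred <- fit$classes[max.col(v, ties.method = "first")]
  manual <- 100 * mean(pred != fit$training$origin |
                         abs(v[, 1] - v[, 2]) < 1e-12)
  expect_equal(oob_error(fit), manual)
})

test_that("seeded refits are identical; different seeds differ", {
  b <- make_baseline(n_per_pop = 40, seed = 3)
  f1 <- fit_forest(b, c("d13C", "d18O"), forest_config(n_trees = 80, seed = 7))
  f2 <- fit_forest(b, c("d13C", "d18O"), forest_config(n_trees = 80, seed = 7))
  expect_identical(f1$oob_votes, f2$oob_votes)
  expect_identical(forest_importance(f1), forest_importance(f2))
  f3 <- fit_forest(b, c("d13C", "d18O"), forest_config(n_trees = 80, seed = 8))
  expect_false(identical(f1$oob_votes, f3$oob_votes))
})

test_that("every tree's root split is the Gini-optimal split of its bootstrap sample", {
  # exhaustive enumeration oracle on a small 2-feature baseline
  b <- tibble::tibble(
    id = sprintf("t%d", 1:8),
    origin = rep(c("A", "B"), each = 4),
    f1 = c(1, 2, 3, 4, 6, 7, 8, 9),
    f2 = c(5, 1, 4, 2, 3, 8, 2, 9)
  )
  fit <- fit_forest(b, c("f1", "f2"),
                    forest_config(n_trees = 3, mtry = 2, seed = 5))
  inbag <- fit$engine$inbag

  best_gini_split <- function(df) {
    n <- nrow(df)
    gini <- function(y) 1 - sum((table(y) / length(y))^2)
    best <- list(score = Inf)
    for (f in c("f1", "f2")) {
      cuts <- sort(unique(df[[f]]))
      cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
      for (cut in cuts) {
        left <- df[[f]] <= cut
        score <- sum(left) / n * gini(df$origin[left]) +
          sum(!left) / n * gini(df$origin[!left])
        if (score < best$score - 1e-12) best <- list(score = score, f = f, cut = cut)
      }
    }
    best
  }

  for (k in 1:3) {
    boot <- b[rep(seq_len(nrow(b)), inbag[, k]), ]
    oracle <- best_gini_split(boot)
    tree <- randomForest::getTree(fit$engine, k, labelVar = TRUE)
    expect_equal(as.character(tree$`split var`[1]), oracle$f)
    expect_equal(tree$`split point`[1], oracle$cut)
  }
})

test_that("constant features warn and single-class baselines error", {
  b <- toy_separable()
  b$flat <- 1
  expect_warning(fit_forest(b, c("f1", "flat"),
                            forest_config(n_trees = 30, seed = 1)),
                 "constant")
  solo <- dplyr::mutate(b, origin = "A")
  expect_error(fit_forest(solo, "f1", forest_config(n_trees = 30, seed = 1)),
               "two classes")
})

test_that("pure-noise features have negligible permutation importance", {
  deltas <- purrr::map_dbl(1:10, function(r) {
    b <- withr::with_seed(200 + r, {
      d <- toy_separable(n_per_class = 50, seed = 200 + r)
      d$noise <- rnorm(nrow(d))
      d
    })
    fit <- fit_forest(b, c("f1", "noise"),
                      forest_config(n_trees = 200, seed = r))
    imp <- forest_importance(fit, scale = FALSE)
    imp$mean_decrease_accuracy[imp$feature == "noise"]
  })
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(length(deltas)) + 1e-3)
})

test_that("duplicating a feature splits its Gini importance roughly in half", {
  b <- make_baseline(n_per_pop = 150, seed = 3)
  f1 <- fit_forest(b, c("d13C", "d18O"), forest_config(seed = 4))
  b2 <- dplyr::mutate(b, d18O_copy = d18O)
  f2 <- fit_forest(b2, c("d13C", "d18O", "d18O_copy"), forest_config(seed = 4))
  g_orig <- forest_importance(f1, scale = FALSE)
  g_dup <- forest_importance(f2, scale = FALSE)
  full <- g_orig$mean_decrease_gini[g_orig$feature == "d18O"]
  halves <- g_dup$mean_decrease_gini[g_dup$feature %in% c("d18O", "d18O_copy")]
  expect_true(all(abs(halves / full - 0.5) < 0.25))
})

test_that("vote fractions are normalised and thresholds act monotonically", {
  pops <- default_populations()
  b <- make_baseline(pops, n_per_pop = 80, seed = 6)
  mx <- make_mixed(mixture_design(list(pops$GoM, pops$Med), c(0.4, 0.6),
                                  n = 120), seed = 7)
  fit <- fit_forest(b, c("d13C", "d18O"), forest_config(n_trees = 200, seed = 6))
  res <- assign_stock(fit, mx, thresholds = c(0.5, 0.6, 0.8, 0.9))
  votes <- as.matrix(res[paste0("vote_", attr(res, "classes"))])
  expect_true(all(abs(rowSums(votes) - 1) < 1e-9))
  labs <- res[paste0("label_", c(50, 60, 80, 90))]
  n_ua <- vapply(labs, function(l) sum(l == "UA"), integer(1))
  expect_true(all(diff(n_ua) >= 0))
  for (j in 2:4) {
    assigned <- labs[[j]] != "UA"
    expect_true(all(labs[[j]][assigned] == labs[[1]][assigned] |
                      labs[[1]][assigned] == "UA"))
  }
})

test_that("threshold comparison is inclusive and exact 50/50 ties abstain", {
  votes <- rbind(c(0.79, 0.21), c(0.80, 0.20), c(0.5, 0.5))
  classes <- c("GoM", "Med")
  expect_equal(tunamix:::label_votes(votes, classes, 0.8),
               c("UA", "GoM", "UA"))
  expect_equal(tunamix:::label_votes(votes, classes, 0.5),
               c("GoM", "GoM", "UA"))
})

test_that("baseline fish get OOB votes, new fish full-ensemble votes", {
  b <- toy_separable(n_per_class = 25)
  fit <- fit_forest(b, c("f1", "f2"), forest_config(n_trees = 100, seed = 9))
  res_self <- assign_stock(fit, b)
  expect_equal(res_self$vote_A, fit$oob_votes$vote_A)
  new <- dplyr::mutate(b, id = paste0("new_", id))
  res_new <- assign_stock(fit, new)
  expect_false(isTRUE(all.equal(res_new$vote_A, fit$oob_votes$vote_A)))
})

test_that("specimens missing model features are skipped with a warning", {
  b <- toy_separable()
  fit <- fit_forest(b, c("f1", "f2"), forest_config(n_trees = 50, seed = 1))
  holey <- b
  holey$f1[2] <- NA
  expect_warning(res <- assign_stock(fit, holey), "t002")
  expect_equal(nrow(res), nrow(b) - 1)
})

test_that("confusion arithmetic matches hand counts with UA in denominators", {
  res <- tibble::tibble(
    id = sprintf("s%02d", 1:10),
    area = "CA",
    vote_GoM = c(rep(0.9, 3), rep(0.1, 5), 0.6, 0.55),
    vote_Med = 1 - c(rep(0.9, 3), rep(0.1, 5), 0.6, 0.55),
    label_80 = c(rep("GoM", 3), rep("Med", 5), "UA", "UA")
  )
  attr(res, "classes") <- c("GoM", "Med")
  truth <- tibble::tibble(id = res$id,
                          true = c(rep("GoM", 4), rep("Med", 6)))
  cs <- confusion_summary(res, truth, 0.8)
  gom <- cs[cs$true == "GoM", ]
  expect_equal(gom$GoM, 3)          # 3 of the 4 true GoM assigned home
  expect_equal(gom$Med, 1)          # 1 misassigned
  expect_equal(unname(gom$pct_correct), 75)  # 3/4, denominators include UA
  med <- cs[cs$true == "Med", ]
  expect_equal(med$UA, 2)
  expect_equal(unname(med$pct_correct), 100 * 4 / 6)
  expect_equal(unname(cs$pct_correct[cs$true == "Total"]), 70)  # 7/10
  # e.g. a 85/9/0-of-94 row gives 90.4%
  expect_equal(round(100 * 85 / 94, 1), 90.4)
  expect_error(confusion_summary(res, truth[1:5, ], 0.8), "missing")
})

test_that("tidy and glance expose the model surface", {
  b <- toy_separable()
  fit <- fit_forest(b, c("f1", "f2"), forest_config(n_trees = 50, seed = 1))
  td <- tidy(fit)
  expect_true(all(c("feature", "mean_decrease_gini") %in% names(td)))
  expect_true(all(td$mean_decrease_gini >= 0))
  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_equal(gl$oob_error_pct, 0)
})
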