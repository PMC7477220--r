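#' Automated two-stage variable selection
#'
#' Reproduces, in a self-contained form, the usual automated forest-based
#' selection: variables with a negligible influence on the out-of-bag error
#' and a low mean decrease in Gini impurity are dropped.
#'
#' Stage 1 (threshold): candidates are ranked by mean decrease in Gini
#' importance averaged over `r_rank` refits with different seeds.  In every
#' refit, `n_shadow` "shadow" features -- copies of randomly chosen real
#' candidates with their values permuted, hence informative about nothing --
#' are appended, with fresh permutations every refit; the largest importance
#' any shadow ever achieves across the refits is the data-driven noise
#' floor, and candidates whose mean importance sits at or below it are
#' discarded.
#'
#' Stage 2 (confirmation): starting from the empty set (whose error is the
#' majority-class error rate), features are considered in rank order and kept
#' only if adding them lowers the OOB error by more than `tol`.  The
#' with/without errors are paired over `r_confirm` refits sharing the same
#' seeds, and by default `tol` is one standard error of the paired error
#' difference, so a feature must beat the refit-to-refit noise to stay.
#'
#' @param baseline Baseline specimen tibble.
#' @param candidates Candidate feature names.
#' @param config A [forest_config()]; its seed anchors all refit seeds.
#' @param r_rank Refits used for the ranking stage (default 25).
#' @param r_confirm Refits per candidate in the confirmation stage
#'   (default 5).
#' @param n_shadow Number of shadow features (default 3).
#' @param tol Error-improvement tolerance; `NULL` (default) uses 1 SE of the
#'   paired with/without error difference across the confirmation refits.
#' @return Character vector of kept features in rank order, with the ranking
#'   diagnostics attached as attribute `"ranking"`.
#' @export
select_features <- function(baseline, candidates, config,
                            r_rank = 25, r_confirm = 5, n_shadow = 3,
                            tol = NULL) {
  stopifnot(length(candidates) >= 1, inherits(config, "tunamix_forest_config"))
  df <- tibble::as_tibble(baseline)
  df <- df[usable_specimens(df, candidates), ]
  refit_cfg <- function(s) {
    forest_config(n_trees = config$n_trees, mtry = config$mtry,
                  min_leaf = config$min_leaf, seed = s)
  }

  # --- stage 1: rank against a shadow-feature noise floor ------------------
  shadow_names <- paste0(".shadow", seq_len(n_shadow))
  imp_runs <- purrr::map(seq_len(r_rank), function(r) {
    s <- config$seed + 1000L * r
    aug <- df
    withr::with_seed(s, {
      src <- sample(candidates, n_shadow, replace = TRUE)
      for (k in seq_len(n_shadow)) {
        aug[[shadow_names[k]]] <- sample(df[[src[k]]])
      }
    })
    fit <- fit_forest(aug, c(candidates, shadow_names), refit_cfg(s))
    imp <- forest_importance(fit, scale = FALSE)
    stats::setNames(imp$mean_decrease_gini, imp$feature)
  })
  mean_imp <- Reduce(`+`, purrr::map(imp_runs, ~ .x[c(candidates, shadow_names)])) /
    r_rank
  # the floor is the largest importance any shadow achieved in any refit:
  # shadows are re-permuted every refit, so over R refits the floor samples
  # the upper tail of the noise-importance distribution, and a candidate's
  # mean importance must clear what known-uninformative features ever reach
  noise_floor <- max(purrr::map_dbl(imp_runs, ~ max(.x[shadow_names])))
  ranking <- tibble::tibble(
    feature = c(candidates, shadow_names),
    mean_gini = unname(mean_imp[c(candidates, shadow_names)]),
    shadow = c(rep(FALSE, length(candidates)), rep(TRUE, n_shadow))
  )
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$mean_gini))
  survivors <- ranking$feature[!ranking$shadow &
                                 ranking$mean_gini > noise_floor]
  if (!length(survivors)) {
    stop("all candidates fell below the shadow-feature noise floor\n",
         paste(utils::capture.output(print(ranking)), collapse = "\n"))
  }

  # --- stage 2: greedy confirmation against OOB error ----------------------
  # with/without errors are paired on a common set of refit seeds, so a
  # candidate is judged on the mean paired error difference against its own
  # standard error rather than on two independently noisy estimates
  # mtry is held at the full-candidate-pool value for every nested model, so
  # the comparison isolates the feature set: with a varying mtry, small pools
  # force single-feature splits and even pure-noise features can "help" by
  # decorrelating trees
  mtry_confirm <- config$mtry %||% max(1L, floor(sqrt(length(candidates))))
  refit_seeds <- config$seed + 7919L * seq_len(r_confirm)
  errs_for <- function(feats) {
    purrr::map_dbl(refit_seeds, function(s) {
      cfg <- refit_cfg(s)
      cfg$mtry <- min(mtry_confirm, length(feats))
      oob_error(fit_forest(df, feats, cfg))
    })
  }
  majority_err <- 100 * (1 - max(table(df$origin)) / nrow(df))
  current_errs <- rep(majority_err, r_confirm)
  kept <- character()
  for (f in survivors) {
    trial_errs <- errs_for(c(kept, f))
    d <- trial_errs - current_errs
    this_tol <- tol %||% (stats::sd(d) / sqrt(r_confirm))
    if (mean(d) < -this_tol) {
      kept <- c(kept, f)
      current_errs <- trial_errs
    }
  }
  if (!length(kept)) {
    stop("no candidate improved on the majority-class error rate\n",
         paste(utils::capture.output(print(ranking)), collapse = "\n"))
  }
  structure(kept, ranking = ranking)
}
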