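#' Configuration for the bootstrap tree-ensemble classifier
#'
#' @param n_trees Number of trees (default 500, the conventional ensemble
#'   size; accuracy is insensitive well before this).
#' @param mtry Features drawn (uniformly, without replacement) at each split;
#'   default `floor(sqrt(p))` where `p` is the number of features.
#' @param min_leaf Minimum terminal-node size (default 1).
#' @param seed Integer seed; mandatory so every fit is reproducible.
#' @return List of class `"tunamix_forest_config"`.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, min_leaf = 1, seed) {
  stopifnot(n_trees >= 1, !missing(seed))
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "tunamix_forest_config")
}

#' Fit the stock-discrimination forest on a baseline
#'
#' Fits a bootstrap ensemble of Gini-split decision trees (via the
#' \pkg{randomForest} engine) on the baseline specimens, treating isotope
#' features as continuous and genotype features as unordered 3-level factors,
#' and keeps the out-of-bag (OOB) vote bookkeeping needed for unbiased
#' self-assignment: each training fish is voted on only by the trees whose
#' bootstrap sample excluded it.
#'
#' Specimens missing any requested feature are excluded before fitting, with
#' a warning naming them (a fish is usable by a model only if it carries every
#' feature the model requires).
#'
#' @param baseline Baseline specimen tibble with an `origin` column carrying
#'   at least two classes.
#' @param features Character vector of feature column names, e.g.
#'   `c("d18O", "RAD213", "RAD26", "RAD35", "RAD2")`.
#' @param config A [forest_config()].
#' @return Object of class `"tunamix_forest"`: the fitted engine, the config,
#'   feature list, class labels, per-training-fish OOB vote fractions and a
#'   training-set fingerprint (ids).
#' @export
#' @examples
#' b <- make_baseline(n_per_pop = 30, seed = 1)
#' fit <- fit_forest(b, c("d13C", "d18O"), forest_config(n_trees = 100, seed = 1))
#' glance(fit)
fit_forest <- function(baseline, features, config) {
  stopifnot(inherits(config, "tunamix_forest_config"))
  df <- tibble::as_tibble(baseline)
  missing_cols <- setdiff(c("id", "origin", features), names(df))
  if (length(missing_cols)) {
    stop("baseline lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  classes <- sort(setdiff(unique(df$origin), "unknown"))
  if (length(classes) < 2L) stop("baseline must contain at least two classes")
  usable <- usable_specimens(df, features)
  if (!all(usable)) {
    warning(sum(!usable), " specimen(s) excluded from fitting (missing features): ",
            paste(utils::head(df$id[!usable], 10), collapse = ", "),
            if (sum(!usable) > 10) ", ..." else "")
    df <- df[usable, ]
  }
  if (any(table(df$origin) < 2L)) stop("each class needs at least 2 specimens")
  x <- as.data.frame(df[, features, drop = FALSE])
  constant <- vapply(x, function(col) length(unique(col[!is.na(col)])) < 2L,
                     logical(1))
  if (all(constant)) {
    stop("every requested feature is constant across the baseline; nothing to split on")
  }
  if (any(constant)) {
    warning("constant feature(s) across the baseline (zero importance): ",
            paste(features[constant], collapse = ", "))
  }
  # drop unused factor levels per column but keep the 3-level coding intact
  y <- factor(df$origin, levels = classes)
  mtry <- config$mtry %||% max(1L, floor(sqrt(length(features))))
  rf <- withr::with_seed(config$seed,
    randomForest::randomForest(
      x = x, y = y, ntree = config$n_trees, mtry = mtry,
      nodesize = config$min_leaf, importance = TRUE,
      keep.inbag = TRUE, keep.forest = TRUE, norm.votes = TRUE
    )
  )
  oob <- tibble::as_tibble(as.data.frame(unclass(rf$votes)))
  names(oob) <- paste0("vote_", colnames(rf$votes))
  oob <- dplyr::bind_cols(tibble::tibble(id = df$id), oob)
  structure(
    list(engine = rf, config = config, features = features,
         classes = classes, oob_votes = oob,
         training = tibble::tibble(id = df$id, origin = df$origin),
         training_x = x),
    class = "tunamix_forest"
  )
}

#' @export
print.tunamix_forest <- function(x, ...) {
  cat(sprintf(
    "<tunamix forest: %d trees, mtry=%d, features=%s, classes=%s, OOB error=%.2f%%>\n",
    x$engine$ntree, x$engine$mtry, paste(x$features, collapse = ","),
    paste(x$classes, collapse = "/"), oob_error(x)))
  invisible(x)
}

#' Out-of-bag misclassification rate, in percent
#'
#' Fraction of training fish whose OOB majority vote differs from their true
#' origin, times 100.  A fish with an exact vote tie holds no majority and
#' counts as misclassified.  Fish never out-of-bag (possible only for tiny
#' ensembles) are excluded with a warning.
#'
#' @param model A fitted [fit_forest()] model.
#' @return Percentage in [0, 100].
#' @export
oob_error <- function(model) {
  stopifnot(inherits(model, "tunamix_forest"))
  votes <- as.matrix(model$oob_votes[paste0("vote_", model$classes)])
  voted <- rowSums(is.na(votes)) == 0 & rowSums(votes) > 0
  if (!all(voted)) {
    warning(sum(!voted), " specimen(s) never out-of-bag; excluded from OOB error")
  }
  v <- votes[voted, , drop = FALSE]
  truth <- model$training$origin[voted]
  top <- max.col(v, ties.method = "first")
  best <- v[cbind(seq_len(nrow(v)), top)]
  tie <- rowSums(abs(v - best) < 1e-12) > 1   # no majority -> counts as wrong
  wrong <- model$classes[top] != truth | tie
  100 * mean(wrong)
}

#' Variable importance of a fitted forest
#'
#' Two complementary measures, both from the OOB bookkeeping:
#' mean decrease in Gini impurity (total impurity decrease at splits using
#' the feature, averaged over trees) and mean decrease in accuracy (drop in
#' OOB accuracy after permuting the feature's values), overall and per class.
#'
#' @param model A fitted [fit_forest()] model.
#' @param scale Divide permutation importances by their standard errors
#'   (the engine's conventional display scaling); default `TRUE`.
#' @return Tibble with one row per feature: `feature`,
#'   `mean_decrease_gini`, `mean_decrease_accuracy`, and one
#'   `accuracy_<class>` column per class.
#' @export
forest_importance <- function(model, scale = TRUE) {
  stopifnot(inherits(model, "tunamix_forest"))
  imp <- randomForest::importance(model$engine, scale = scale)
  out <- tibble::tibble(feature = rownames(imp))
  for (cl in model$classes) out[[paste0("accuracy_", cl)]] <- imp[, cl]
  out$mean_decrease_accuracy <- imp[, "MeanDecreaseAccuracy"]
  out$mean_decrease_gini <- imp[, "MeanDecreaseGini"]
  dplyr::arrange(out, dplyr::desc(.data$mean_decrease_gini))
}

# internal: shared vote -> label logic.
# t <= 0.5: strict majority (exact tie -> UA).
# t  > 0.5: inclusive comparison, votes >= t assigns, otherwise UA.
label_votes <- function(votes, classes, threshold) {
  top <- max.col(votes, ties.method = "first")
  best <- votes[cbind(seq_len(nrow(votes)), top)]
  if (threshold <= 0.5) {
    lab <- ifelse(rowSums(abs(votes - best) < 1e-12) > 1, "UA", classes[top])
  } else {
    lab <- ifelse(best >= threshold, classes[top], "UA")
  }
  lab
}

#' Assign specimens to a stock with abstention thresholds
#'
#' For every specimen the per-class vote fraction over the ensemble is
#' computed; a fish in the model's own training set receives its out-of-bag
#' votes (so self-assignment of the baseline is not optimistically biased),
#' any other fish the votes of the full ensemble.  At threshold 0.5 a fish is
#' assigned to the strict-majority class (an exact tie abstains); at a
#' threshold t > 0.5 it is assigned to a class only if that class's vote
#' fraction is at least t (inclusive), otherwise it is unassigned (`"UA"`).
#'
#' Specimens missing any model feature are skipped with a warning naming
#' them.
#'
#' @param model A fitted [fit_forest()] model.
#' @param specimens Specimen tibble carrying the model's features.
#' @param thresholds Numeric vector of assignment thresholds.
#' @return Tibble of class `"tunamix_assignment"`: `id`, `area`, one
#'   `vote_<class>` column per class, and one `label_<percent>` column per
#'   threshold.
#' @export
assign_stock <- function(model, specimens, thresholds = c(0.5, 0.8)) {
  stopifnot(inherits(model, "tunamix_forest"), all(thresholds > 0),
            all(thresholds <= 1))
  df <- tibble::as_tibble(specimens)
  usable <- usable_specimens(df, model$features)
  if (!all(usable)) {
    warning("skipping ", sum(!usable), " specimen(s) with missing features: ",
            paste(utils::head(df$id[!usable], 10), collapse = ", "),
            if (sum(!usable) > 10) ", ..." else "")
    df <- df[usable, ]
  }
  if (!nrow(df)) stop("no assignable specimens")
  vote_cols <- paste0("vote_", model$classes)
  in_train <- df$id %in% model$training$id
  votes <- matrix(NA_real_, nrow(df), length(model$classes),
                  dimnames = list(NULL, vote_cols))
  if (any(in_train)) {
    m <- match(df$id[in_train], model$oob_votes$id)
    votes[in_train, ] <- as.matrix(model$oob_votes[m, vote_cols])
  }
  if (any(!in_train)) {
    newx <- as.data.frame(df[!in_train, model$features, drop = FALSE])
    p <- stats::predict(model$engine, newdata = newx, type = "prob")
    votes[!in_train, ] <- p[, model$classes, drop = FALSE]
  }
  out <- dplyr::bind_cols(
    tibble::tibble(id = df$id,
                   area = if ("area" %in% names(df)) df$area else NA_character_),
    tibble::as_tibble(votes)
  )
  for (t in thresholds) {
    out[[sprintf("label_%d", round(100 * t))]] <-
      label_votes(votes, model$classes, t)
  }
  structure(out, class = c("tunamix_assignment", class(out)),
            classes = model$classes, thresholds = thresholds)
}

#' Confusion summary of an assignment against known origins
#'
#' Cross-tabulates true origin against assigned label (including `UA`) and
#' computes percent-correct per class and overall.  Percentages use the full
#' class size, unassigned fish included, in the denominator, so an abstention
#' lowers the correct-assignment rate rather than being dropped.
#'
#' @param result A [assign_stock()] result.
#' @param truth Tibble with columns `id` and `true` (or a specimen tibble,
#'   whose `origin` is used).
#' @param threshold Which threshold's labels to summarise (must be one of the
#'   thresholds the result was built with).
#' @return Tibble of class `"tunamix_confusion"`: one row per true class plus
#'   a `Total` row; count columns per predicted label and `pct_correct`.
#' @export
confusion_summary <- function(result, truth, threshold = 0.5) {
  lab_col <- sprintf("label_%d", round(100 * threshold))
  if (!lab_col %in% names(result)) {
    stop("result holds no labels at threshold ", threshold)
  }
  if ("origin" %in% names(truth) && !"true" %in% names(truth)) {
    truth <- tibble::tibble(id = truth$id, true = truth$origin)
  }
  joined <- dplyr::inner_join(tibble::as_tibble(result)[c("id", lab_col)],
                              truth, by = "id")
  if (nrow(joined) < nrow(result)) {
    stop("truth labels missing for ",
         nrow(result) - nrow(joined), " specimen(s)")
  }
  classes <- attr(result, "classes")
  labels <- c(classes, "UA")
  tab <- table(factor(joined$true, levels = classes),
               factor(joined[[lab_col]], levels = labels))
  body <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "true")
  body$n <- rowSums(tab)
  body$pct_correct <- 100 * diag(tab[, classes, drop = FALSE])[
    match(body$true, classes)] / body$n
  total <- tibble::tibble(true = "Total")
  for (l in labels) total[[l]] <- sum(body[[l]])
  total$n <- sum(body$n)
  total$pct_correct <- 100 * sum(diag(tab[, classes, drop = FALSE])) / total$n
  out <- dplyr::bind_rows(body, total)
  structure(out, class = c("tunamix_confusion", class(out)),
            threshold = threshold)
}
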