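#' Friedman H-statistic: interaction strength of each feature
#'
#' For a feature j, the (one-vs-rest) H-statistic measures how much of the
#' variability in the model's prediction attributable to j is explained by
#' interactions with the remaining features: 0 means the prediction function
#' is additive in j, 1 means j acts only through interactions.
#'
#' It is computed on the probability-of-first-class scale.  With F the
#' ensemble probability function, PD_j the partial dependence on feature j
#' and PD_-j the partial dependence on all other features, all three centred
#' over the evaluation points x_1..x_n,
#'
#' \deqn{H_j^2 = \sum_i [F(x_i) - PD_j(x_{ij}) - PD_{-j}(x_{i,-j})]^2 /
#'              \sum_i F(x_i)^2}
#'
#' and H_j is its square root, clipped into [0, 1].  Partial dependences are
#' evaluated over the training points themselves (not a synthetic grid),
#' subsampled to at most `max_points` rows to bound the n-squared prediction
#' cost.  A model whose prediction is (numerically) constant has no variance
#' to decompose; the statistic is undefined and returned as `NA`.
#'
#' @param model A fitted [fit_forest()] model.
#' @param features Features to score; default all model features.
#' @param max_points Maximum evaluation points (default 300).
#' @param seed Seed for the evaluation-point subsample (default: the model's
#'   seed), so repeated calls are identical.
#' @return Tibble with columns `feature` and `H`.
#' @export
h_statistic <- function(model, features = NULL, max_points = 300, seed = NULL) {
  stopifnot(inherits(model, "tunamix_forest"))
  features <- features %||% model$features
  stopifnot(all(features %in% model$features))
  seed <- seed %||% model$config$seed
  x <- model$training_x
  if (nrow(x) > max_points) {
    idx <- withr::with_seed(as.integer(seed),
                            sample.int(nrow(x), max_points))
    x <- x[idx, , drop = FALSE]
  }
  n <- nrow(x)
  f_of <- function(df) {
    stats::predict(model$engine, newdata = df, type = "prob")[, model$classes[1]]
  }
  f_hat <- f_of(x)
  denom <- sum((f_hat - mean(f_hat))^2)
  purrr::map_dfr(features, function(j) {
    if (denom < 1e-12) return(tibble::tibble(feature = j, H = NA_real_))
    # M[i, k] = F(feature j from row i, all other features from row k);
    # row blocks indexed by i, the k index cycling within each block
    big <- x[rep(seq_len(n), times = n), , drop = FALSE]
    big[[j]] <- x[[j]][rep(seq_len(n), each = n)]
    m <- matrix(f_of(big), nrow = n, byrow = TRUE)  # rows: j-index i, cols: k
    pd_j <- rowMeans(m)
    pd_rest <- colMeans(m)
    f_c <- f_hat - mean(f_hat)
    pd_j_c <- pd_j - mean(pd_j)
    pd_rest_c <- pd_rest - mean(pd_rest)
    h2 <- sum((f_c - pd_j_c - pd_rest_c)^2) / sum(f_c^2)
    tibble::tibble(feature = j, H = min(1, sqrt(max(0, h2))))
  })
}
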