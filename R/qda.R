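#' Quadratic-discriminant stock assignment from isotope signatures
#'
#' The comparator used with the yearling-style baseline: each class gets its
#' own bivariate Gaussian over (delta-13C, delta-18O), fitted by the sample
#' mean vector and covariance matrix; posterior class probabilities are
#' computed under equal priors and thresholded exactly as in
#' [assign_stock()] (inclusive at t > 0.5, strict majority at t = 0.5).
#'
#' A numerically singular class covariance (collinear or constant isotopes
#' within a class) is ridge-regularised -- a small multiple of the average
#' variance is added to the diagonal -- with a warning.
#'
#' @param baseline Baseline specimen tibble with `origin` and both isotope
#'   columns.
#' @param specimens Specimens to assign.
#' @param thresholds Assignment thresholds, as in [assign_stock()].
#' @param features Feature columns (default `c("d13C", "d18O")`).
#' @param ridge Relative ridge added on singularity (default 1e-6).
#' @return A `"tunamix_assignment"` tibble with posterior columns
#'   `vote_<class>` and labels per threshold.
#' @export
qda_assign <- function(baseline, specimens, thresholds = c(0.5, 0.8),
                       features = c("d13C", "d18O"), ridge = 1e-6) {
  df <- tibble::as_tibble(baseline)
  df <- df[usable_specimens(df, features), ]
  classes <- sort(setdiff(unique(df$origin), "unknown"))
  if (length(classes) < 2L) stop("baseline must contain at least two classes")
  fits <- lapply(classes, function(cl) {
    xm <- as.matrix(df[df$origin == cl, features, drop = FALSE])
    if (nrow(xm) < 2L) stop("class ", cl, " has fewer than 2 usable specimens")
    mu <- colMeans(xm)
    sigma <- stats::cov(xm)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10)) {
      warning("singular covariance for class ", cl, "; ridge-regularised")
      sigma <- sigma + diag(ridge * mean(diag(sigma)) + 1e-12, ncol(sigma))
      ch <- chol(sigma)
    }
    list(mu = mu, chol = ch)
  })
  names(fits) <- classes

  log_density <- function(fit, x) {
    # multivariate normal log density via the Cholesky factor
    z <- backsolve(fit$chol, t(x) - fit$mu, transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(fit$chol))) -
      0.5 * length(fit$mu) * log(2 * pi)
  }

  sp <- tibble::as_tibble(specimens)
  usable <- usable_specimens(sp, features)
  if (!all(usable)) {
    warning("skipping ", sum(!usable), " specimen(s) with missing isotopes: ",
            paste(utils::head(sp$id[!usable], 10), collapse = ", "))
    sp <- sp[usable, ]
  }
  if (!nrow(sp)) stop("no assignable specimens")
  x <- as.matrix(sp[, features, drop = FALSE])
  ll <- vapply(fits, log_density, numeric(nrow(x)), x = x)
  ll <- matrix(ll, nrow = nrow(x))
  # equal priors: posterior = softmax of the log densities
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll) / rowSums(exp(ll))
  colnames(post) <- paste0("vote_", classes)
  out <- dplyr::bind_cols(
    tibble::tibble(id = sp$id,
                   area = if ("area" %in% names(sp)) sp$area else NA_character_),
    tibble::as_tibble(post)
  )
  for (t in thresholds) {
    out[[sprintf("label_%d", round(100 * t))]] <- label_votes(post, classes, t)
  }
  structure(out, class = c("tunamix_assignment", class(out)),
            classes = classes, thresholds = thresholds)
}
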