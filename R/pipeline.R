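#' Run the full stock-assignment analysis from a configuration
#'
#' Orchestrates the end-to-end flow on one pair of input tables: load the
#' baseline and mixed specimen tables, (optionally) run variable selection,
#' fit the three models -- chemistry-only, genetics-only and integrated --
#' self-assign the baseline with OOB votes, assign the mixed sample, compare
#' the three methods fish-by-fish, estimate per-area composition and mixing
#' coefficients, and forward-simulate the expected delta-18O mixture.  Every
#' stage writes a delimited table into the output directory and the run ends
#' with a JSON manifest recording the configuration hash, seed and package
#' version, so a rerun with the same configuration is byte-identical.
#'
#' One global seed fans out deterministically to per-stage seeds
#' (`stage_seed = (seed * 97 + stage_index) mod 2^31 - 1`), so any stage can
#' be rerun in isolation with the seed its in-pipeline run used.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list with entries: `baseline` and `mixed` (file paths or specimen
#'   tibbles), `features` (list with `chemistry`, `genetics`, `integrated`
#'   character vectors), `thresholds`, `n_trees`, `seed`, `out_dir`,
#'   optional `select_candidates` (runs variable selection and uses the kept
#'   set as the integrated feature list), `mixture_n` (default 1e6) and
#'   `composition_threshold` (default 0.8).
#' @return The run manifest (named list), invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed), !is.null(config$out_dir))
  seed <- as.integer(config$seed)
  stage_seed <- function(i) as.integer((seed * 97 + i) %% (2^31 - 1))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[tunamix] ", msg)
  }

  load_specimens <- function(x, role) {
    if (is.character(x)) {
      read_specimens(x, specimen_schema(role = role))
    } else x
  }
  baseline <- load_specimens(config$baseline, "baseline")
  mixed <- if (!is.null(config$mixed)) load_specimens(config$mixed, "mixed")
  note("loaded baseline (n=%d) and mixed (n=%d)", nrow(baseline),
       if (is.null(mixed)) 0L else nrow(mixed))

  feats <- config$features
  thresholds <- unlist(config$thresholds %||% c(0.5, 0.8))
  n_trees <- config$n_trees %||% 500
  comp_t <- config$composition_threshold %||% 0.8

  if (!is.null(config$select_candidates)) {
    kept <- select_features(baseline, unlist(config$select_candidates),
                            forest_config(n_trees = n_trees,
                                          seed = stage_seed(1)))
    note("variable selection kept: %s", paste(kept, collapse = ", "))
    feats$integrated <- as.character(kept)
    readr::write_lines(kept, file.path(out_dir, "selected_features.txt"))
  }

  models <- list()
  results_baseline <- list()
  results_mixed <- list()
  for (m in names(feats)) {
    cfg <- forest_config(n_trees = n_trees, seed = stage_seed(10 + match(m, names(feats))))
    models[[m]] <- fit_forest(baseline, unlist(feats[[m]]), cfg)
    note("model %s: OOB error %.2f%%", m, oob_error(models[[m]]))
    results_baseline[[m]] <- assign_stock(models[[m]], baseline, thresholds)
    write_assignments(results_baseline[[m]],
                      file.path(out_dir, sprintf("baseline_assignments_%s.csv", m)))
    for (t in thresholds) {
      conf <- confusion_summary(results_baseline[[m]], baseline, t)
      write_table(conf, file.path(out_dir,
                                  sprintf("confusion_%s_t%d.csv", m, round(100 * t))))
    }
    imp <- forest_importance(models[[m]])
    write_table(imp, file.path(out_dir, sprintf("importance_%s.csv", m)))
    if (!is.null(mixed) && nrow(mixed)) {
      results_mixed[[m]] <- assign_stock(models[[m]], mixed, thresholds)
      write_assignments(results_mixed[[m]],
                        file.path(out_dir, sprintf("mixed_assignments_%s.csv", m)))
    }
  }

  compositions <- NULL
  weights_tbl <- NULL
  mixfit <- NULL
  if (length(results_mixed) >= 1L) {
    ref <- results_mixed[[length(results_mixed)]]  # last model = integrated
    compositions <- composition_by_area(ref, mixed, comp_t)
    write_table(compositions, file.path(out_dir, "composition_by_area.csv"))
    weights_tbl <- mixing_coefficient(compositions)
    write_table(weights_tbl, file.path(out_dir, "mixing_coefficients.csv"))
    note("composition estimated for %d area(s)", nrow(compositions))
    # pooled weights drive the forward mixture simulation
    lab_col <- sprintf("label_%d", round(100 * comp_t))
    labels <- ref[[lab_col]]
    classes <- attr(ref, "classes")
    pooled <- table(factor(labels[labels != "UA"], levels = classes))
    if (sum(pooled) > 0 && all(classes %in% baseline$origin)) {
      w <- stats::setNames(as.numeric(pooled) / sum(pooled), classes)
      spec <- mixture_from_baseline(baseline, w)
      obs <- mixed$d18O[!is.na(mixed$d18O)]
      if (length(obs) >= 20) {
        mixfit <- compare_mixture(obs, spec)
        write_table(mixfit$overlay, file.path(out_dir, "mixture_overlay.csv"))
        write_table(
          tibble::tibble(ks_distance = mixfit$ks_distance,
                         ks_critical_5pct = mixfit$ks_critical_5pct,
                         excess_mass = mixfit$excess_mass,
                         excess_se = mixfit$excess_se),
          file.path(out_dir, "mixture_fit.csv"))
        note("mixture comparison: KS=%.4f, window excess=%+.4f",
             mixfit$ks_distance, mixfit$excess_mass)
      }
    }
  }

  threeway <- NULL
  if (length(results_mixed) >= 3L) {
    nm <- names(results_mixed)
    # methods can only be compared on fish usable by all three models
    common <- Reduce(intersect, lapply(results_mixed, function(r) r$id))
    dropped <- length(unique(unlist(lapply(results_mixed, function(r) r$id)))) -
      length(common)
    if (dropped > 0) {
      note("three-way comparison restricted to %d fish usable by all methods (%d dropped)",
           length(common), dropped)
    }
    restrict <- function(r) {
      out <- r[r$id %in% common, ]
      attributes(out)[c("classes", "thresholds")] <-
        attributes(r)[c("classes", "thresholds")]
      class(out) <- class(r)
      out
    }
    threeway <- three_way(restrict(results_mixed[[nm[2]]]),
                          restrict(results_mixed[[nm[1]]]),
                          restrict(results_mixed[[nm[3]]]), comp_t)
    write_table(threeway, file.path(out_dir, "three_way_cube.csv"))
    note("three-way comparison written (n=%d)", attr(threeway, "summary")$n)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tunamix")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    thresholds = thresholds,
    models = lapply(models, function(m) {
      list(features = m$features, oob_error_pct = oob_error(m))
    }),
    outputs = sort(list.files(out_dir)),
    log = log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' @param manifest A manifest list from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @return Character vector of markdown lines, invisibly; also printed.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  lines <- c(
    "# tunamix run report",
    sprintf("- package version: %s", manifest$package_version),
    sprintf("- seed: %s", manifest$seed),
    sprintf("- config hash: %s", manifest$config_hash),
    "",
    "## Models"
  )
  for (m in names(manifest$models)) {
    mm <- manifest$models[[m]]
    lines <- c(lines, sprintf("- %s: features = %s; OOB error = %.2f%%",
                              m, paste(unlist(mm$features), collapse = ", "),
                              as.numeric(mm$oob_error_pct)))
  }
  lines <- c(lines, "", "## Outputs",
             paste0("- ", unlist(manifest$outputs)))
  if (length(manifest$log)) {
    lines <- c(lines, "", "## Log", paste0("- ", unlist(manifest$log)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
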