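# Shared in-code fixtures; everything is generated, nothing read from disk.

# tiny two-class baseline with clean 1-D separation on f1
toy_separable <- function(n_per_class = 20, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("A", "B"), each = n_per_class)
    tibble::tibble(
      id = sprintf("t%03d", seq_along(lab)),
      origin = lab,
      f1 = ifelse(lab == "A", rnorm(length(lab), gap, 1),
                  rnorm(length(lab), -gap, 1)),
      f2 = rnorm(length(lab))
    )
  })
}

# write a small specimen csv and return its path
write_specimen_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "specimens.csv")
  readr::write_csv(df, path, na = "")
  path
}

# the study-condition presets used across the end-to-end checks
study_populations <- function() default_populations()

# combined-style baseline: GoM 45 / Med 105 with 1 + 4 fish missing genetics
combined_baseline <- function(seed) {
  b <- make_baseline(study_populations(), n_per_pop = c(Med = 105, GoM = 45),
                     seed = seed)
  mask <- c(b$id[b$origin == "GoM"][1], b$id[b$origin == "Med"][1:4])
  for (m in specimen_markers(b)) b[[m]][b$id %in% mask] <- NA
  attr(b, "masked_ids") <- mask
  b
}
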