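#' Declare the column layout and genotype coding of a specimen table
#'
#' Specimen tables arrive as delimited text with site-specific column names,
#' so the reader is schema-driven rather than hard-coded.  A schema maps the
#' columns of the file onto the fields the pipeline understands and declares
#' how genotype calls are encoded.
#'
#' Two genotype encodings are accepted:
#' \describe{
#'   \item{`"letters"`}{biallelic letter pairs such as `"AA"`, `"AG"`, `"GG"`.
#'     The reference allele per marker may be declared through `ref_alleles`;
#'     when it is not, the alphabetically first allele observed at the marker
#'     is taken as reference (documented, deterministic).}
#'   \item{`"dosage"`}{alt-allele counts `0`/`1`/`2`.}
#' }
#' Blank cells and the literal `NA` are read as missing calls in either
#' encoding.  Internally a call is always stored as a categorical value with
#' levels `ref`, `het`, `alt`; it is never collapsed to a numeric dosage,
#' because the classifier treats genotypes as unordered factors.
#'
#' @param id,origin,area,year,length,d13C,d18O Column names in the file.
#'   Set an entry to `NULL` if the file lacks that column.
#' @param markers Character vector of genotype column names, or `NULL` to
#'   auto-detect columns whose names start with `"RAD"`.
#' @param genotype_coding `"letters"` or `"dosage"`.
#' @param ref_alleles Named character vector, marker id -> reference allele
#'   letter (only used with `genotype_coding = "letters"`).
#' @param role `"auto"`, `"baseline"` or `"mixed"`.  With `"auto"` the set is
#'   a baseline when at least two known origin labels are present.
#' @return A list of class `"tunamix_schema"`.
#' @export
#' @examples
#' specimen_schema(markers = c("RAD2", "RAD26"), genotype_coding = "dosage")
specimen_schema <- function(id = "id", origin = "origin", area = "area",
                            year = "year", length = "length_cm",
                            d13C = "d13C", d18O = "d18O",
                            markers = NULL,
                            genotype_coding = c("letters", "dosage"),
                            ref_alleles = NULL,
                            role = c("auto", "baseline", "mixed")) {
  genotype_coding <- match.arg(genotype_coding)
  role <- match.arg(role)
  structure(
    list(id = id, origin = origin, area = area, year = year, length = length,
         d13C = d13C, d18O = d18O, markers = markers,
         genotype_coding = genotype_coding, ref_alleles = ref_alleles,
         role = role),
    class = "tunamix_schema"
  )
}

# internal: the three genotype levels used everywhere downstream
genotype_levels <- function() c("ref", "het", "alt")

#' Decode genotype calls to the internal categorical representation
#'
#' @param x Character (letter pairs) or numeric/character (dosage) vector.
#' @param coding `"letters"` or `"dosage"`.
#' @param ref_allele Reference allele letter; if `NA` with letter coding, the
#'   alphabetically first allele observed in `x` is used.
#' @return Factor with levels `ref`, `het`, `alt`; missing input maps to `NA`.
#' @export
decode_genotypes <- function(x, coding = c("letters", "dosage"),
                             ref_allele = NA_character_) {
  coding <- match.arg(coding)
  x <- as.character(x)
  x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA_character_
  if (coding == "dosage") {
    bad <- !is.na(x) & !x %in% c("0", "1", "2")
    if (any(bad)) {
      stop("invalid dosage codes: ", paste(unique(x[bad]), collapse = ", "))
    }
    out <- c("0" = "ref", "1" = "het", "2" = "alt")[x]
    return(factor(unname(out), levels = genotype_levels()))
  }
  ok <- !is.na(x)
  if (any(nchar(x[ok]) != 2L)) {
    stop("letter genotype calls must be two characters, e.g. 'AG'")
  }
  a1 <- substr(x, 1, 1)
  a2 <- substr(x, 2, 2)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  if (length(alleles) > 2L) {
    stop("more than two alleles observed at one marker: ",
         paste(alleles, collapse = ", "))
  }
  if (is.na(ref_allele)) ref_allele <- alleles[1]
  dose <- (a1 != ref_allele) + (a2 != ref_allele)
  out <- c("ref", "het", "alt")[dose + 1L]
  out[!ok] <- NA_character_
  factor(out, levels = genotype_levels())
}

#' Encode internal genotype calls back to a file representation
#'
#' Inverse of [decode_genotypes()]: `encode_genotypes(decode_genotypes(x))`
#' reproduces `x` for every legal code.
#'
#' @param g Factor with levels `ref`, `het`, `alt`.
#' @param coding Target encoding.
#' @param ref_allele,alt_allele Allele letters (letter coding only).
#' @return Character vector; missing calls become `NA`.
#' @export
encode_genotypes <- function(g, coding = c("letters", "dosage"),
                             ref_allele = "A", alt_allele = "B") {
  coding <- match.arg(coding)
  g <- as.character(g)
  if (coding == "dosage") {
    out <- c(ref = "0", het = "1", alt = "2")[g]
  } else {
    out <- c(ref = paste0(ref_allele, ref_allele),
             het = paste0(ref_allele, alt_allele),
             alt = paste0(alt_allele, alt_allele))[g]
  }
  unname(out)
}

# internal: stamp a tibble as a specimen set and validate invariants
new_specimens <- function(df, role, markers) {
  df <- tibble::as_tibble(df)
  structure(df,
            class = c("tunamix_specimens", class(df)),
            role = role, markers = markers)
}

#' @export
print.tunamix_specimens <- function(x, ...) {
  cat(sprintf("<tunamix specimen set: role=%s, n=%d, markers=%s>\n",
              attr(x, "role"), nrow(x),
              if (length(attr(x, "markers"))) {
                paste(attr(x, "markers"), collapse = ",")
              } else "none"))
  NextMethod()
}

#' Accessors for specimen-set metadata
#' @param x A specimen set from [read_specimens()] or the simulators.
#' @return `specimen_role()` returns `"baseline"` or `"mixed"`;
#'   `specimen_markers()` the marker column names.
#' @export
specimen_role <- function(x) attr(x, "role")

#' @rdname specimen_role
#' @export
specimen_markers <- function(x) attr(x, "markers") %||% character()

#' Read a specimen table from delimited text
#'
#' Reads comma- or tab-separated specimen records (one fish per row), decodes
#' genotype calls to the internal categorical representation, and validates
#' the result.  Records that fail type validation are rejected with
#' row-numbered messages; duplicated ids and missing mandatory columns are
#' errors for the whole file.
#'
#' delta-18O values outside the plausibility window [-4, +3] permil trigger a
#' warning (not an error): such values are almost certainly unit or transcription
#' problems but the decision is left to the analyst.
#'
#' @param path File path (`.csv` or `.tsv`/`.txt`; the delimiter is sniffed
#'   from the header line).
#' @param schema A [specimen_schema()].
#' @return A specimen tibble with columns `id`, `origin`, `area`, `year`,
#'   `length_cm`, `d13C`, `d18O` and one factor column per marker, carrying
#'   `role` and `markers` attributes.
#' @export
read_specimens <- function(path, schema = specimen_schema()) {
  stopifnot(inherits(schema, "tunamix_schema"))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  if (is.null(schema$id) || !schema$id %in% names(raw)) {
    stop("schema error: mandatory id column '", schema$id, "' not found in ", path)
  }
  markers <- schema$markers
  if (is.null(markers)) markers <- grep("^RAD", names(raw), value = TRUE)
  missing_markers <- setdiff(markers, names(raw))
  if (length(missing_markers)) {
    stop("schema error: declared marker columns absent: ",
         paste(missing_markers, collapse = ", "))
  }

  get_col <- function(nm) if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NULL

  n <- nrow(raw)
  out <- tibble::tibble(id = as.character(raw[[schema$id]]))
  if (anyNA(out$id)) stop("validation error: missing id in rows ",
                          paste(which(is.na(out$id)), collapse = ", "))
  if (anyDuplicated(out$id)) {
    stop("validation error: duplicate ids: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }

  parse_num <- function(x, nm) {
    if (is.null(x)) return(rep(NA_real_, n))
    suppressWarnings(v <- as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop(sprintf("validation error: non-numeric %s in rows %s",
                   nm, paste(bad, collapse = ", ")))
    }
    v
  }
  out$origin <- {
    o <- get_col(schema$origin)
    if (is.null(o)) rep("unknown", n) else dplyr::coalesce(as.character(o), "unknown")
  }
  out$area <- {
    a <- get_col(schema$area)
    if (is.null(a)) rep(NA_character_, n) else as.character(a)
  }
  out$year <- {
    y <- parse_num(get_col(schema$year), "year")
    as.integer(y)
  }
  out$length_cm <- parse_num(get_col(schema$length), "length")
  if (any(!is.na(out$length_cm) & out$length_cm <= 0)) {
    stop("validation error: non-positive length in rows ",
         paste(which(!is.na(out$length_cm) & out$length_cm <= 0), collapse = ", "))
  }
  out$d13C <- parse_num(get_col(schema$d13C), "d13C")
  out$d18O <- parse_num(get_col(schema$d18O), "d18O")
  if (all(is.na(out$d18O)) && !is.null(schema$d18O)) {
    warning("d18O column is entirely missing; isotope signatures absent")
  }
  out_of_window <- !is.na(out$d18O) & (out$d18O < -4 | out$d18O > 3)
  if (any(out_of_window)) {
    warning("d18O outside [-4, 3] permil in rows ",
            paste(which(out_of_window), collapse = ", "),
            " -- check units/transcription")
  }

  for (m in markers) {
    ref <- if (!is.null(schema$ref_alleles) && m %in% names(schema$ref_alleles)) {
      schema$ref_alleles[[m]]
    } else NA_character_
    out[[m]] <- decode_genotypes(raw[[m]], schema$genotype_coding, ref)
  }

  role <- schema$role
  if (role == "auto") {
    known <- setdiff(unique(out$origin), "unknown")
    role <- if (length(known) >= 2L) "baseline" else "mixed"
  }
  if (role == "baseline" && length(setdiff(unique(out$origin), "unknown")) < 2L) {
    stop("validation error: baseline must contain at least two origin labels")
  }
  new_specimens(out, role, markers)
}

#' Write an assignment result (or any tibble) to delimited text
#'
#' One row per specimen: id, area, the vote fraction for each class and the
#' label at each configured threshold.  All numeric columns are fixed at six
#' decimal places so output files diff reproducibly.
#'
#' @param result An assignment result from [assign_stock()] (or any data
#'   frame for `write_table()`).
#' @param path Output file path; the extension chooses comma (`.csv`) or tab
#'   delimiting.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(result, path) {
  if (!nrow(result)) stop("empty assignment result")
  write_table(result, path)
}

#' @rdname write_assignments
#' @param rows Data frame to write.
#' @export
write_table <- function(rows, path) {
  out <- dplyr::mutate(tibble::as_tibble(rows),
                       dplyr::across(dplyr::where(is.double),
                                     ~ sprintf("%.6f", .x)))
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

# internal: specimens usable by a model = all required features present
usable_specimens <- function(specimens, features) {
  stats::complete.cases(as.data.frame(specimens)[, features, drop = FALSE])
}
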