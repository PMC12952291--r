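#' Read GEO-style series metadata
#'
#' Parses series metadata into a tibble with one row per series. Two dialects
#' are supported: `"jsonl"` (one JSON object per line with keys `accession`,
#' `title`, `summary`, `overall_design`, `species`, `experiment_types`,
#' `platform_vendor`, `retired`, `is_subseries`, `condition_labels`) and
#' `"soft"` (a minimal subset of the SOFT format: `^SERIES = <accession>`
#' blocks with `!Series_title`, `!Series_summary` (repeatable, joined with
#' spaces), `!Series_overall_design`, `!Series_sample_organism`, and
#' `!Series_type` (repeatable) attribute lines).
#'
#' Missing optional text fields become empty strings; order of appearance is
#' preserved; a duplicated accession is an error.
#'
#' @param path Path to a metadata file, or a character vector of lines via
#'   `text`.
#' @param dialect `"jsonl"` or `"soft"`.
#' @param text Optional character vector of lines (used instead of `path`).
#' @return A series tibble: columns `accession`, `title`, `summary`,
#'   `overall_design`, `species` (character), `experiment_types`,
#'   `condition_labels` (list columns of character vectors),
#'   `platform_vendor` (character), `retired`, `is_subseries` (logical).
#' @export
read_series <- function(path = NULL, dialect = c("jsonl", "soft"), text = NULL) {
  dialect <- match.arg(dialect)
  lines <- text %||% readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- switch(dialect,
    jsonl = parse_series_jsonl(lines),
    soft = parse_series_soft(lines)
  )
  dup <- recs$accession[duplicated(recs$accession)]
  if (length(dup)) {
    abort(sprintf("duplicate accession(s): %s", paste(unique(dup), collapse = ", ")))
  }
  recs
}

series_tibble <- function(rows) {
  tibble(
    accession = vapply(rows, `[[`, character(1), "accession"),
    title = vapply(rows, `[[`, character(1), "title"),
    summary = vapply(rows, `[[`, character(1), "summary"),
    overall_design = vapply(rows, `[[`, character(1), "overall_design"),
    species = vapply(rows, `[[`, character(1), "species"),
    experiment_types = lapply(rows, `[[`, "experiment_types"),
    platform_vendor = vapply(rows, `[[`, character(1), "platform_vendor"),
    retired = vapply(rows, `[[`, logical(1), "retired"),
    is_subseries = vapply(rows, `[[`, logical(1), "is_subseries"),
    condition_labels = lapply(rows, `[[`, "condition_labels")
  )
}

chr1 <- function(x, default = "") {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) return(default)
  paste(as.character(x), collapse = " ")
}

parse_series_jsonl <- function(lines) {
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) abort(sprintf("malformed JSON on line %d: %s", i, conditionMessage(e)))
    )
    acc <- chr1(obj$accession)
    if (!nzchar(acc)) abort(sprintf("record on line %d has no accession", i))
    list(
      accession = acc,
      title = chr1(obj$title),
      summary = chr1(obj$summary),
      overall_design = chr1(obj$overall_design),
      species = chr1(obj$species),
      experiment_types = as.character(obj$experiment_types %||% character(0)),
      platform_vendor = chr1(obj$platform_vendor),
      retired = isTRUE(obj$retired),
      is_subseries = isTRUE(obj$is_subseries),
      condition_labels = as.character(obj$condition_labels %||% character(0))
    )
  })
  series_tibble(rows)
}

parse_series_soft <- function(lines) {
  starts <- grep("^\\^SERIES", lines)
  if (!length(starts)) abort("no ^SERIES blocks found in SOFT input")
  ends <- c(starts[-1] - 1L, length(lines))
  rows <- Map(function(s, e) {
    head_line <- lines[s]
    acc <- trimws(sub("^\\^SERIES\\s*=\\s*", "", head_line))
    if (!nzchar(acc) || identical(acc, head_line)) {
      abort(sprintf("malformed ^SERIES line %d: '%s'", s, head_line))
    }
    block <- lines[seq(s, e)]
    attr_of <- function(key) {
      hits <- grep(sprintf("^!%s\\s*=", key), block, value = TRUE)
      vals <- trimws(sub("^![^=]*=\\s*", "", hits))
      vals[nzchar(vals)]
    }
    list(
      accession = acc,
      title = paste(attr_of("Series_title"), collapse = " "),
      summary = paste(attr_of("Series_summary"), collapse = " "),
      overall_design = paste(attr_of("Series_overall_design"), collapse = " "),
      species = paste(attr_of("Series_sample_organism"), collapse = " "),
      experiment_types = attr_of("Series_type"),
      platform_vendor = "",
      retired = FALSE,
      is_subseries = FALSE,
      condition_labels = character(0)
    )
  }, starts, ends)
  series_tibble(rows)
}

check_series <- function(series) {
  need <- c("accession", "title", "summary", "overall_design", "species",
            "experiment_types", "platform_vendor", "retired", "is_subseries",
            "condition_labels")
  missing <- setdiff(need, names(series))
  if (length(missing)) {
    abort(sprintf("series table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  invisible(series)
}

#' Filter series to the analysis-eligible subset
#'
#' Retains human series that are not retired, are not a SubSeries, and come
#' from a supported assay/platform combination: expression profiling by array
#' on an Affymetrix, Illumina, or Agilent platform, or expression profiling by
#' high throughput sequencing on an Illumina platform. Relative order is
#' preserved and filtering is idempotent.
#'
#' @param series A series tibble (see [read_series()]).
#' @return The retained rows, same columns.
#' @export
filter_series <- function(series) {
  check_series(series)
  array_ok <- vapply(series$experiment_types, function(tt) {
    "expression profiling by array" %in% tolower(tt)
  }, logical(1)) & tolower(series$platform_vendor) %in% c("affymetrix", "illumina", "agilent")
  hts_ok <- vapply(series$experiment_types, function(tt) {
    "expression profiling by high throughput sequencing" %in% tolower(tt)
  }, logical(1)) & tolower(series$platform_vendor) == "illumina"
  keep <- !series$retired &
    tolower(series$species) == "homo sapiens" &
    (array_ok | hts_ok) &
    !series$is_subseries
  series[keep, , drop = FALSE]
}

#' Write series metadata as JSON lines
#'
#' Emits the same JSON-lines dialect [read_series()] reads, so generated or
#' filtered corpora round-trip through the ingest path.
#'
#' @param series A series tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_jsonl <- function(series, path) {
  check_series(series)
  lines <- vapply(seq_len(nrow(series)), function(i) {
    jsonlite::toJSON(list(
      accession = series$accession[i],
      title = series$title[i],
      summary = series$summary[i],
      overall_design = series$overall_design[i],
      species = series$species[i],
      experiment_types = as.character(series$experiment_types[[i]]),
      platform_vendor = series$platform_vendor[i],
      retired = series$retired[i],
      is_subseries = series$is_subseries[i],
      condition_labels = as.character(series$condition_labels[[i]])
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
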