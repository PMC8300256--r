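#' Read a TNR program time series from CSV
#'
#' Reads yearly program data: a `year` column and a `surgeries` column
#' (annual sterilization surgeries, used as the population index when no
#' census exists), plus optional `census` (directly counted free-roaming
#' population) and `removals` (cats/kittens removed for adoption or
#' euthanasia) columns. Column names are matched case-insensitively and the
#' typographic minus (U+2212) found in published tables is normalized to the
#' ASCII hyphen-minus before parsing.
#'
#' Empty cells in optional columns are kept as `NA` — a printed `0` always
#' means a true zero count, never a missing value. Rows are sorted by year.
#' Gaps in the year sequence are flagged with a warning and recorded in the
#' `gap_after` attribute; they are never silently filled.
#'
#' @param path Path to a CSV file with a header row.
#' @param program_id Optional label stored in the `program_id` attribute;
#'   defaults to the file name without extension.
#' @return A tibble with columns `year`, `surgeries` and, when present in the
#'   file, `census`, `removals` and any additional numeric columns.
#' @export
#' @examples
#' path <- system.file("extdata", "alachua.csv", package = "rickertnr")
#' read_program_series(path)
read_program_series <- function(path, program_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!"year" %in% names(raw)) abort("No `year` column in the file header.")
  if (!"surgeries" %in% names(raw)) {
    abort("No `surgeries` column in the file header.")
  }
  parsed <- dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    ~ as.numeric(normalize_minus(.x))
  ))
  validate_program_series(parsed,
                          program_id = program_id %||%
                            tools::file_path_sans_ext(basename(path)))
}

#' Write a TNR program time series to CSV
#'
#' Inverse of [read_program_series()]: a write-then-read round trip
#' reproduces the series field for field.
#'
#' @param data A program series tibble (columns `year`, `surgeries`, optional
#'   `census`, `removals`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_program_series <- function(data, path) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

# U+2212 (minus sign) -> ASCII hyphen-minus; published tables use the former.
normalize_minus <- function(x) {
  gsub("−", "-", x)
}

validate_program_series <- function(data, program_id = NULL) {
  data <- as_tibble(data)
  check_number(nrow(data), "number of rows", min = 1)
  if (anyNA(data$year)) abort("`year` contains missing values.")
  dup <- unique(data$year[duplicated(data$year)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate year(s) in series: %s",
                  paste(dup, collapse = ", ")))
  }
  data <- dplyr::arrange(data, .data$year)
  if (anyNA(data$surgeries)) {
    abort("`surgeries` must be present for every year.")
  }
  for (col in intersect(c("surgeries", "census", "removals"), names(data))) {
    check_count_vector(data[[col]], col)
  }
  gaps <- diff(data$year) != 1L
  if (any(gaps)) {
    gap_after <- data$year[-nrow(data)][gaps]
    warn(sprintf("Non-consecutive years: gap(s) after %s.",
                 paste(gap_after, collapse = ", ")))
    attr(data, "gap_after") <- gap_after
  }
  attr(data, "program_id") <- program_id
  data
}

#' Read per-cat surgery records from CSV
#'
#' Per-cat records have columns `year`, `month`, `sex` (`female`/`male`),
#' `pregnant` (logical, meaningful only for females at surgery),
#' `age_months` and `outcome` (`returned`, `adopted`, `euthanized`, `died`).
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated cat records.
#' @export
read_cat_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      year = "i", month = "i", sex = "c", pregnant = "l",
      age_months = "d", outcome = "c"
    ),
    progress = FALSE
  )
  validate_cat_records(raw)
}

#' @rdname read_cat_records
#' @param data A cat-record tibble to write.
#' @export
write_cat_records <- function(data, path) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

validate_cat_records <- function(data) {
  data <- as_tibble(data)
  bad_sex <- setdiff(unique(data$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    abort(sprintf("Unknown sex value(s): %s", paste(bad_sex, collapse = ", ")))
  }
  if (any(!is.na(data$pregnant) & data$pregnant & data$sex != "female")) {
    abort("`pregnant = TRUE` requires `sex = \"female\"`.")
  }
  if (any(!is.na(data$age_months) & data$age_months < 0)) {
    abort("`age_months` must be non-negative.")
  }
  if (any(!is.na(data$month) & (data$month < 1 | data$month > 12))) {
    abort("`month` must be in 1..12.")
  }
  data
}

#' Bundled program fixtures
#'
#' The package ships the two published county datasets (estimated annual
#' sterilization surgeries with the growth-rate column exactly as printed,
#' typographic minus and all) and the four-program Ricker simulation
#' parameter table.
#'
#' The printed San Diego growth-rate column is internally inconsistent with
#' its own surgeries column for several years; both columns are stored
#' verbatim so that the discrepancies can be reproduced (see
#' [run_replication()]).
#'
#' @param name One of `"san_diego"`, `"alachua"` (program series with a
#'   `printed_growth_rate` column) or `"table2_params"` (simulation
#'   parameters: `program`, `R_m`, `K`, `N_1`).
#' @return A tibble; program series carry the usual series attributes.
#' @export
#' @examples
#' load_fixture("table2_params")
#' load_fixture("alachua")
load_fixture <- function(name) {
  available <- c("san_diego", "alachua", "table2_params")
  if (length(name) != 1L || !name %in% available) {
    abort(sprintf("Unknown fixture %s. Available fixtures: %s",
                  deparse(name), paste(available, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "rickertnr", mustWork = TRUE)
  if (name == "table2_params") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      program = "c", .default = "d"
    ), progress = FALSE)
    return(as_tibble(raw))
  }
  read_program_series(path, program_id = name)
}
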