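split_codes <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";",
                  fixed = TRUE)
  lapply(out, function(v) if (length(v) == 1L && is.na(v)) character() else v)
}

join_codes <- function(x) vapply(x, paste, "", collapse = ";")

#' Write the synthetic (or cleaned) cohort tables to CSV
#'
#' UTF-8 CSVs with header rows, ISO-8601 dates and dotless ICD-10 codes;
#' multi-code fields are semicolon-separated. The same dialect is accepted
#' back by the readers.
#'
#' @param deaths,episodes,population Tables as produced by
#'   [simulate_cohort()] (or reals in the same shape).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort_csvs <- function(deaths, episodes, population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- deaths
  d$mention_codes <- join_codes(d$mention_codes)
  d$chronic_codes <- NULL
  ep <- episodes
  ep$diagnosis_codes <- join_codes(ep$diagnosis_codes)
  paths <- file.path(dir, c("deaths.csv", "episodes.csv", "population.csv"))
  readr::write_csv(d, paths[1])
  readr::write_csv(ep, paths[2])
  readr::write_csv(population, paths[3])
  invisible(paths)
}

#' Read cohort tables from CSV
#'
#' @param path CSV path in the dialect written by [write_cohort_csvs()].
#' @return Parsed tibble with date columns as `Date` and code fields as list
#'   columns; extra columns are carried through untouched.
#' @export
read_deaths <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         child_key = "c", dob = "D", dod = "D", sex = "c",
                         underlying_cause = "c", mention_codes = "c",
                         died_in_hospital = "l", resident = "l",
                         .default = readr::col_guess()))
  d$mention_codes <- split_codes(d$mention_codes)
  d
}

#' @rdname read_deaths
#' @export
read_episodes <- function(path) {
  ep <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          child_key = "c", start_date = "D", end_date = "D",
                          diagnosis_codes = "c"))
  ep$diagnosis_codes <- split_codes(ep$diagnosis_codes)
  ep
}

#' @rdname read_deaths
#' @export
read_population <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(age_band = "c", year = "i",
                                          population = "d"))
}
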