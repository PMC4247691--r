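nth_birthday <- function(dob, n) {
  y <- as.integer(format(dob, "%Y")) + n
  out <- as.Date(paste0(y, format(dob, "-%m-%d")), format = "%Y-%m-%d")
  feb29 <- is.na(out)           # Feb 29 birthday in a non-leap year
  if (any(feb29)) out[feb29] <- as.Date(paste0(y[feb29], "-03-01"))
  out
}

# band label, NA when outside [28 days, 19th birthday)
age_band_of <- function(dob, dod) {
  d <- as.integer(dod - dob)
  band <- rep(NA_character_, length(d))
  band[d >= 28L & d <= 364L] <- "28-364d"
  b5 <- nth_birthday(dob, 5L)
  b19 <- nth_birthday(dob, 19L)
  band[d >= 365L & dod < b5] <- "1-4y"
  band[dod >= b5 & dod < b19] <- "5-18y"
  band
}

#' Age band at death
#'
#' Bands by completed age at death: 28-364 days; at least 365 days and
#' before the 5th birthday (1-4 years); from the 5th birthday to the day
#' before the 19th birthday (5-18 years, i.e. 18 completed years).
#'
#' @param dob,dod Dates of birth and death (`dod >= dob + 28` days).
#' @return Character vector of band labels (see [age_band_levels()]).
#' @export
assign_age_band <- function(dob, dod) {
  dob <- as.Date(dob)
  dod <- as.Date(dod)
  band <- age_band_of(dob, dod)
  if (anyNA(band)) {
    bad <- which(is.na(band))[1]
    stop("age at death outside [28 days, 19th birthday): dob ", dob[bad],
         ", dod ", dod[bad], call. = FALSE)
  }
  band
}

#' Link hospital episodes to deaths
#'
#' Deterministic linkage emulated as exact child-key equality. Every death
#' becomes one linked case; episodes whose key matches no death are dropped
#' (count recorded); exact duplicate episode rows (same key, start date and
#' code list) are deduplicated (count recorded).
#'
#' @param deaths Death table (one row per death; duplicate keys are an
#'   error naming the key).
#' @param episodes Episode table.
#' @param quiet Suppress the informational messages.
#' @return Tibble of linked cases: the death columns plus `episodes` (list
#'   column of per-case episode tibbles, any date), `n_episodes`,
#'   `age_at_death_days` and `age_band` (`NA` when out of range, removed by
#'   [filter_eligible()]). Attributes `dropped_episodes` and
#'   `deduplicated_episodes` carry the logged counts.
#' @export
link_records <- function(deaths, episodes, quiet = FALSE) {
  dup <- deaths$child_key[duplicated(deaths$child_key)]
  if (length(dup) > 0L) {
    stop("duplicate death record(s) for key(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  key <- paste(episodes$child_key, episodes$start_date,
               join_codes(episodes$diagnosis_codes))
  dupe_n <- sum(duplicated(key))
  if (dupe_n > 0L) episodes <- episodes[!duplicated(key), , drop = FALSE]
  matched <- episodes$child_key %in% deaths$child_key
  dropped_n <- sum(!matched)
  episodes <- episodes[matched, , drop = FALSE]
  if (!quiet) {
    message("link_records: ", dropped_n, " unmatched episode(s) dropped, ",
            dupe_n, " duplicate episode row(s) removed")
  }
  idx <- split(seq_len(nrow(episodes)), episodes$child_key)
  empty <- episodes[0, , drop = FALSE]
  cases <- tibble::as_tibble(deaths)
  cases$episodes <- lapply(cases$child_key, function(k) {
    i <- idx[[k]]
    if (is.null(i)) empty else episodes[i, , drop = FALSE]
  })
  cases$n_episodes <- vapply(cases$episodes, nrow, 0L)
  cases$age_at_death_days <- as.integer(cases$dod - cases$dob)
  cases$age_band <- age_band_of(cases$dob, cases$dod)
  attr(cases, "dropped_episodes") <- dropped_n
  attr(cases, "deduplicated_episodes") <- dupe_n
  cases
}

#' Restrict linked cases to the eligible cohort
#'
#' Retains resident children who died of non-injury causes (underlying cause
#' not in the configured injury/external-cause chapters), aged at least 28
#' days and before their 19th birthday, with date of death inside the study
#' window. Per-criterion exclusion counts (each counted over all input
#' cases) are recorded in the `exclusions` attribute.
#'
#' @param cases Output of [link_records()].
#' @param study_start,study_end Inclusive study window.
#' @param injury_prefixes Code prefixes treated as injury/external causes
#'   (default: ICD-10 chapters XIX-XX, letters S, T, V, W, X, Y).
#' @param quiet Suppress the informational message.
#' @return The eligible subset, with attribute `exclusions` (tibble of
#'   criterion, n_excluded).
#' @export
filter_eligible <- function(cases, study_start, study_end,
                            injury_prefixes = c("S", "T", "V", "W", "X", "Y"),
                            quiet = FALSE) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  b19 <- nth_birthday(cases$dob, 19L)
  ok_age_min <- cases$age_at_death_days >= 28L
  ok_age_max <- cases$dod < b19
  ok_window <- cases$dod >= study_start & cases$dod <= study_end
  ok_resident <- cases$resident
  ok_cause <- !(substr(cases$underlying_cause, 1L, 1L) %in% injury_prefixes)
  excl <- tibble::tibble(
    criterion = c("age_under_28_days", "age_19_or_over", "outside_window",
                  "non_resident", "injury_underlying_cause"),
    n_excluded = c(sum(!ok_age_min), sum(!ok_age_max), sum(!ok_window),
                   sum(!ok_resident), sum(!ok_cause))
  )
  keep <- ok_age_min & ok_age_max & ok_window & ok_resident & ok_cause
  if (!quiet) {
    message("filter_eligible: ", sum(!keep), " of ", length(keep),
            " case(s) excluded")
  }
  out <- cases[keep, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}
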