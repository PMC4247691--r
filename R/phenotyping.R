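#' Is an episode inside the pre-death window?
#'
#' The window is closed at both ends: an episode counts iff its start date
#' lies in `[dod - window_days, dod]`. Episodes starting after death never
#' count.
#'
#' @param start_date Episode start date(s).
#' @param dod Date(s) of death.
#' @param window_days Window length in days (default 30).
#' @return Logical vector.
#' @export
episode_in_window <- function(start_date, dod, window_days = 30) {
  start_date <- as.Date(start_date)
  dod <- as.Date(dod)
  start_date >= (dod - window_days) & start_date <= dod
}

# long code-level views of a linked cohort, built once and reused per cluster
case_code_longs <- function(cases) {
  n <- nrow(cases)
  cert_idx <- rep(seq_len(n), lengths(cases$mention_codes))
  cert_codes <- unlist(cases$mention_codes, use.names = FALSE)
  ep_tbl <- dplyr::bind_rows(cases$episodes)
  ep_case <- rep(seq_len(n), cases$n_episodes)
  code_idx <- rep(seq_along(ep_case), lengths(ep_tbl$diagnosis_codes))
  list(
    n = n,
    cert_idx = cert_idx,
    cert_codes = if (length(cert_codes)) cert_codes else character(),
    ep_case = ep_case[code_idx],
    ep_start = ep_tbl$start_date[code_idx],
    ep_dod = cases$dod[ep_case][code_idx],
    ep_codes = unlist(ep_tbl$diagnosis_codes, use.names = FALSE)
  )
}

any_by_case <- function(flag, idx, n) {
  out <- logical(n)
  if (length(flag) && any(flag)) out[unique(idx[flag])] <- TRUE
  out
}

# certificate / windowed-episode hits against one cluster
cluster_flags <- function(longs, cluster, window_days) {
  cert_hit <- code_in_cluster(longs$cert_codes, cluster)
  cert <- any_by_case(cert_hit, longs$cert_idx, longs$n)
  hosp <- logical(longs$n)
  if (length(longs$ep_codes)) {
    in_win <- episode_in_window(longs$ep_start, longs$ep_dod, window_days)
    ep_hit <- in_win & code_in_cluster(longs$ep_codes, cluster)
    hosp <- any_by_case(ep_hit, longs$ep_case, longs$n)
  }
  list(cert = cert, hosp = hosp, either = cert | hosp)
}

#' Phenotype a linked cohort
#'
#' Classifies every case: `rti_related` is true iff any certificate mention
#' code, or any diagnosis code of an episode starting within `window_days`
#' before death, hits the RTI cluster; `any_respiratory_related` likewise
#' with the sensitive cluster (the RTI cluster is contained in it, so
#' `rti_related` implies `any_respiratory_related`). A chronic group is
#' present iff any certificate code, or any code of an episode starting
#' within `chronic_lookback_days` before death, hits that group's cluster.
#'
#' @param cases Output of [link_records()] (typically after
#'   [filter_eligible()]).
#' @param rti_cluster,sensitive_cluster [code_cluster()] objects (defaults:
#'   [cluster_rti()], [cluster_respiratory()]).
#' @param chronic_groups A [chronic_groups()] list (default
#'   [chronic_groups_default()]).
#' @param window_days RTI episode window (default 30).
#' @param chronic_lookback_days Chronic-evidence episode lookback, anchored
#'   on the episode start date (default 365).
#' @return `cases` with added columns: `cert_rti`, `hosp_rti`, `rti_related`,
#'   `cert_respiratory`, `hosp_respiratory`, `any_respiratory_related`, one
#'   `chronic_<group>` logical per group, `any_chronic`, `n_chronic_groups`
#'   and `season` (of the death date).
#' @export
phenotype_cases <- function(cases,
                            rti_cluster = cluster_rti(),
                            sensitive_cluster = cluster_respiratory(),
                            chronic_groups = chronic_groups_default(),
                            window_days = 30,
                            chronic_lookback_days = 365) {
  stopifnot(inherits(chronic_groups, "chronic_groups"))
  longs <- case_code_longs(cases)
  rti <- cluster_flags(longs, rti_cluster, window_days)
  resp <- cluster_flags(longs, sensitive_cluster, window_days)
  cases$cert_rti <- rti$cert
  cases$hosp_rti <- rti$hosp
  cases$rti_related <- rti$either
  cases$cert_respiratory <- resp$cert
  cases$hosp_respiratory <- resp$hosp
  cases$any_respiratory_related <- resp$either
  n_groups <- integer(nrow(cases))
  for (g in names(chronic_groups)) {
    fl <- cluster_flags(longs, chronic_groups[[g]], chronic_lookback_days)
    cases[[paste0("chronic_", g)]] <- fl$either
    n_groups <- n_groups + fl$either
  }
  cases$any_chronic <- n_groups > 0L
  cases$n_chronic_groups <- n_groups
  cases$season <- season_of(cases$dod)
  cases
}

#' Phenotype one case with a full evidence trail
#'
#' Single-case counterpart of [phenotype_cases()] that also records, for
#' every true flag, which source(s) support it (certificate codes and/or
#' episode codes with their start dates).
#'
#' @param case A one-row linked-case tibble.
#' @inheritParams phenotype_cases
#' @return List: `rti_related`, `any_respiratory_related`,
#'   `chronic_groups_present` (character), `evidence` (named list per true
#'   flag with `certificate` codes and an `episodes` tibble).
#' @export
phenotype_case <- function(case,
                           rti_cluster = cluster_rti(),
                           sensitive_cluster = cluster_respiratory(),
                           chronic_groups = chronic_groups_default(),
                           window_days = 30,
                           chronic_lookback_days = 365) {
  stopifnot(nrow(case) == 1L)
  ep <- case$episodes[[1]]
  gather <- function(cluster, win) {
    cert <- case$mention_codes[[1]][
      code_in_cluster(case$mention_codes[[1]], cluster)]
    ep_rows <- NULL
    if (nrow(ep) > 0L) {
      in_win <- episode_in_window(ep$start_date, case$dod, win)
      hits <- lapply(ep$diagnosis_codes,
                     function(cc) cc[code_in_cluster(cc, cluster)])
      keep <- in_win & lengths(hits) > 0L
      if (any(keep)) {
        ep_rows <- tibble::tibble(start_date = ep$start_date[keep],
                                  codes = join_codes(hits[keep]))
      }
    }
    list(flag = length(cert) > 0L || !is.null(ep_rows),
         evidence = list(certificate = cert,
                         episodes = ep_rows %||%
                           tibble::tibble(start_date = as.Date(character()),
                                          codes = character())))
  }
  rti <- gather(rti_cluster, window_days)
  resp <- gather(sensitive_cluster, window_days)
  ch <- lapply(chronic_groups, gather, win = chronic_lookback_days)
  present <- names(ch)[vapply(ch, `[[`, TRUE, "flag")]
  evidence <- c(
    if (rti$flag) list(rti_related = rti$evidence),
    if (resp$flag) list(any_respiratory_related = resp$evidence),
    stats::setNames(lapply(present, function(g) ch[[g]]$evidence), present)
  )
  list(rti_related = rti$flag,
       any_respiratory_related = resp$flag,
       chronic_groups_present = present,
       evidence = evidence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-source recording agreement
#'
#' Percentage of cases where the certificate-derived and episode-derived
#' flags for an indicator agree (both true or both false), optionally
#' restricted to children who died in hospital.
#'
#' @param cases Phenotyped cohort.
#' @param indicator `"rti"` or `"respiratory"`.
#' @param restrict_to_hospital_deaths Compute over hospital deaths only?
#' @return One-row tibble: `n`, the 2x2 source counts (`both`, `cert_only`,
#'   `hosp_only`, `neither`) and `percent_agreement`.
#' @export
agreement_table <- function(cases, indicator = c("rti", "respiratory"),
                            restrict_to_hospital_deaths = TRUE) {
  indicator <- match.arg(indicator)
  if (restrict_to_hospital_deaths) {
    cases <- cases[cases$died_in_hospital, , drop = FALSE]
  }
  if (nrow(cases) == 0L) stop("no cases in the requested subset",
                              call. = FALSE)
  cert <- cases[[paste0("cert_", if (indicator == "rti") "rti" else
    "respiratory")]]
  hosp <- cases[[paste0("hosp_", if (indicator == "rti") "rti" else
    "respiratory")]]
  tibble::tibble(
    indicator = indicator,
    n = nrow(cases),
    both = sum(cert & hosp),
    cert_only = sum(cert & !hosp),
    hosp_only = sum(!cert & hosp),
    neither = sum(!cert & !hosp),
    percent_agreement = mean(cert == hosp) * 100
  )
}

#' Any-mention versus underlying-cause rate ratio
#'
#' Compares, per age band, the mortality rate using codes anywhere on the
#' certificate or on linked in-window episodes against the rate using the
#' underlying cause alone. Person-time cancels, so the ratio equals the
#' count ratio; rates are still reported per 100,000 person-years.
#'
#' @param cases Linked (not necessarily phenotyped) cohort.
#' @param cluster A [code_cluster()].
#' @param population Denominator tibble (`age_band`, `year`, `population`).
#' @param window_days Episode window for the any-mention route (default 30).
#' @return Tibble per band (plus `"all"`): `n_any`, `n_underlying`,
#'   `person_years`, `rate_any`, `rate_underlying`, `ratio` (`NA` with
#'   `undefined = TRUE` when the underlying-cause count is zero).
#' @export
mention_vs_underlying_ratio <- function(cases, cluster, population,
                                        window_days = 30) {
  longs <- case_code_longs(cases)
  fl <- cluster_flags(longs, cluster, window_days)
  under <- code_in_cluster(cases$underlying_cause, cluster)
  tab <- tibble::tibble(age_band = cases$age_band,
                        any = fl$either, under = under) |>
    dplyr::group_by(.data$age_band) |>
    dplyr::summarise(n_any = sum(.data$any),
                     n_underlying = sum(.data$under), .groups = "drop")
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(age_band = "all", n_any = sum(tab$n_any),
                   n_underlying = sum(tab$n_underlying))
  )
  py <- population |>
    dplyr::group_by(.data$age_band) |>
    dplyr::summarise(person_years = sum(.data$population), .groups = "drop")
  py <- dplyr::bind_rows(
    py, tibble::tibble(age_band = "all",
                       person_years = sum(py$person_years)))
  tab |>
    dplyr::inner_join(py, by = "age_band") |>
    dplyr::mutate(
      rate_any = .data$n_any / .data$person_years * 1e5,
      rate_underlying = .data$n_underlying / .data$person_years * 1e5,
      undefined = .data$n_underlying == 0L,
      ratio = dplyr::if_else(.data$undefined, NA_real_,
                             .data$n_any / .data$n_underlying)
    )
}
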