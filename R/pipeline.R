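#' Deaths linked to an episode within a pre-death window
#'
#' @param cases Output of [link_records()].
#' @param window_days Window length (default 30).
#' @return Logical vector: the case has at least one episode starting within
#'   `window_days` before death.
#' @export
linked_within_window <- function(cases, window_days = 30) {
  ep <- dplyr::bind_rows(cases$episodes)
  idx <- rep(seq_len(nrow(cases)), cases$n_episodes)
  if (nrow(ep) == 0L) return(rep(FALSE, nrow(cases)))
  hit <- episode_in_window(ep$start_date, cases$dod[idx], window_days)
  any_by_case(hit, idx, nrow(cases))
}

#' Build a pipeline configuration
#'
#' Exactly one of `simulation` (a list of [sim_params()] arguments) or
#' `inputs` (named paths `deaths`, `episodes`, `population`) must be given.
#'
#' @param output_dir Directory for all stage outputs.
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @param simulation List of [sim_params()] arguments (its `seed` is set
#'   from `seed`), or `NULL`.
#' @param inputs Named list of CSV paths, or `NULL`.
#' @param study_start,study_end Study window; defaults cover the simulation
#'   years when simulating.
#' @param rti_cluster,respiratory_cluster Member vectors overriding the
#'   default clusters.
#' @param chronic_groups Named list of member vectors overriding groups of
#'   [chronic_groups_default()].
#' @param rti_window_days,chronic_lookback_days Phenotyping windows.
#' @param injury_prefixes Underlying-cause prefixes excluded as injuries.
#' @param ci_method `"wald"` or `"exact"` rate CIs.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1L,
                            simulation = list(),
                            inputs = NULL,
                            study_start = NULL,
                            study_end = NULL,
                            rti_cluster = NULL,
                            respiratory_cluster = NULL,
                            chronic_groups = NULL,
                            rti_window_days = 30,
                            chronic_lookback_days = 365,
                            injury_prefixes = c("S", "T", "V", "W", "X", "Y"),
                            ci_method = "wald") {
  if (!is.null(inputs) && !is.null(simulation) && length(simulation) > 0L) {
    stop("supply exactly one of 'inputs' or 'simulation'", call. = FALSE)
  }
  if (is.null(inputs)) {
    simulation$seed <- as.integer(seed)
    params <- do.call(sim_params, simulation)
    if (is.null(study_start)) {
      study_start <- as.Date(sprintf("%d-01-01", min(params$study_years)))
    }
    if (is.null(study_end)) {
      study_end <- as.Date(sprintf("%d-12-31", max(params$study_years)))
    }
  } else {
    need <- c("deaths", "episodes", "population")
    if (!all(need %in% names(inputs))) {
      stop("inputs must name deaths, episodes and population files",
           call. = FALSE)
    }
    missing_files <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(missing_files) > 0L) {
      stop("input file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
    if (is.null(study_start) || is.null(study_end)) {
      stop("study_start and study_end are required with file inputs",
           call. = FALSE)
    }
    params <- NULL
  }
  structure(list(
    output_dir = output_dir,
    seed = as.integer(seed),
    params = params,
    inputs = inputs,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    rti_cluster = if (is.null(rti_cluster)) cluster_rti() else
      code_cluster("rti", rti_cluster),
    respiratory_cluster = if (is.null(respiratory_cluster))
      cluster_respiratory() else
      code_cluster("respiratory", respiratory_cluster),
    chronic_groups = chronic_groups_default(chronic_groups),
    rti_window_days = rti_window_days,
    chronic_lookback_days = chronic_lookback_days,
    injury_prefixes = injury_prefixes,
    ci_method = ci_method
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @param output_dir,seed Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, output_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(output_dir)) y$output_dir <- output_dir
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$simulation$age_band_populations)) {
    y$simulation$age_band_populations <-
      unlist(y$simulation$age_band_populations)
  }
  if (!is.null(y$simulation$annual_noninjury_deaths)) {
    y$simulation$annual_noninjury_deaths <-
      unlist(y$simulation$annual_noninjury_deaths)
  }
  do.call(pipeline_config, y)
}

#' Validate input CSV files
#'
#' Schema and content checks: required columns, parseable ISO dates and
#' ICD-10 codes, date ordering, underlying cause among the mentions, and
#' population coverage of every observed band x year.
#'
#' @param paths Named list/vector with `deaths`, `episodes`, `population`
#'   paths.
#' @return Tibble (`file`, `error`); zero rows means all checks passed.
#' @export
validate_inputs <- function(paths) {
  errs <- list()
  add <- function(file, msg) {
    errs[[length(errs) + 1L]] <<- tibble::tibble(file = file, error = msg)
  }
  read_chr <- function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = "c"),
                    show_col_types = FALSE)
  }
  check_dates <- function(file, raw, col) {
    parsed <- as.Date(raw, format = "%Y-%m-%d", optional = TRUE)
    bad <- !is.na(raw) & raw != "" & is.na(parsed)
    for (v in unique(raw[bad])) {
      add(file, paste0("unparseable date in ", col, ": '", v, "'"))
    }
    parsed
  }
  check_codes <- function(file, codes, col) {
    flat <- unlist(split_codes(codes))
    bad <- unique(flat[!grepl("^[A-Za-z][0-9]{2}[A-Za-z0-9.]*$",
                              trimws(flat))])
    for (v in bad) {
      add(file, paste0("unparseable ICD-10 code in ", col, ": '", v, "'"))
    }
  }

  d <- tryCatch(read_chr(paths[["deaths"]]), error = function(e) {
    add("deaths", conditionMessage(e)); NULL
  })
  dob <- dod <- NULL
  if (!is.null(d)) {
    need <- c("child_key", "dob", "dod", "sex", "underlying_cause",
              "mention_codes", "died_in_hospital", "resident")
    for (col in setdiff(need, names(d))) {
      add("deaths", paste0("missing column: ", col))
    }
    if (all(c("dob", "dod") %in% names(d))) {
      dob <- check_dates("deaths", d$dob, "dob")
      dod <- check_dates("deaths", d$dod, "dod")
      if (any(!is.na(dob) & !is.na(dod) & dod < dob)) {
        add("deaths", "dod precedes dob for at least one record")
      }
    }
    if ("mention_codes" %in% names(d)) {
      check_codes("deaths", d$mention_codes, "mention_codes")
      if ("underlying_cause" %in% names(d)) {
        men <- split_codes(d$mention_codes)
        orphan <- mapply(function(u, m) !is.na(u) && !(u %in% m),
                         d$underlying_cause, men)
        if (any(orphan)) {
          add("deaths", "underlying_cause not among mention_codes for at least one record")
        }
      }
    }
  }

  ep <- tryCatch(read_chr(paths[["episodes"]]), error = function(e) {
    add("episodes", conditionMessage(e)); NULL
  })
  if (!is.null(ep)) {
    for (col in setdiff(c("child_key", "start_date", "diagnosis_codes"),
                        names(ep))) {
      add("episodes", paste0("missing column: ", col))
    }
    if ("start_date" %in% names(ep)) {
      st <- check_dates("episodes", ep$start_date, "start_date")
      if ("end_date" %in% names(ep)) {
        en <- check_dates("episodes", ep$end_date, "end_date")
        if (any(!is.na(st) & !is.na(en) & en < st)) {
          add("episodes", "end_date precedes start_date for at least one episode")
        }
      }
    }
    if ("diagnosis_codes" %in% names(ep)) {
      if (any(lengths(split_codes(ep$diagnosis_codes)) == 0L)) {
        add("episodes", "episode with no diagnosis codes")
      }
      check_codes("episodes", ep$diagnosis_codes, "diagnosis_codes")
    }
  }

  pop <- tryCatch(read_chr(paths[["population"]]), error = function(e) {
    add("population", conditionMessage(e)); NULL
  })
  if (!is.null(pop)) {
    for (col in setdiff(c("age_band", "year", "population"), names(pop))) {
      add("population", paste0("missing column: ", col))
    }
    if (all(c("age_band", "year", "population") %in% names(pop))) {
      if (any(as.numeric(pop$population) <= 0, na.rm = TRUE)) {
        add("population", "non-positive population count")
      }
      if (!is.null(d) && !is.null(dob) && !is.null(dod)) {
        ok <- !is.na(dob) & !is.na(dod)
        band <- age_band_of(dob[ok], dod[ok])
        yrs <- format(dod[ok], "%Y")
        obs <- unique(stats::na.omit(paste(band, yrs)))
        have <- paste(pop$age_band, pop$year)
        for (cell in setdiff(obs, have)) {
          add("population", paste0("no denominator for observed band x year: ",
                                   cell))
        }
      }
    }
  }
  if (length(errs) == 0L) {
    tibble::tibble(file = character(), error = character())
  } else {
    dplyr::bind_rows(errs)
  }
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) -> link -> filter -> phenotype -> trends ->
#' season/excess -> comorbidity, writing every stage output to the
#' configured directory: the three input CSVs, `cohort.csv`,
#' `exclusions.csv`, `trends.csv`, `figure1_data.csv`, `table1.csv`,
#' `weekly_rates.csv`, `monthly_circular.csv`, `table2.csv`, `tests.json`,
#' an `audit.jsonl` evidence file, `run_summary.json` and `pipeline.log`.
#' Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()] (or YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, the run summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "pipeline.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)

  if (is.null(config$inputs)) {
    sim <- simulate_cohort(config$params)
    deaths <- sim$deaths
    episodes <- sim$episodes
    population <- sim$population
    write_cohort_csvs(deaths, episodes, population, config$output_dir)
    logline("simulate: ", nrow(deaths), " deaths, ", nrow(episodes),
            " episodes")
  } else {
    report <- validate_inputs(config$inputs)
    if (nrow(report) > 0L) {
      stop("input validation failed:\n",
           paste(report$file, report$error, sep = ": ", collapse = "\n"),
           call. = FALSE)
    }
    deaths <- read_deaths(config$inputs$deaths)
    episodes <- read_episodes(config$inputs$episodes)
    population <- read_population(config$inputs$population)
    logline("load: ", nrow(deaths), " deaths, ", nrow(episodes), " episodes")
  }

  cases <- link_records(deaths, episodes, quiet = TRUE)
  logline("link: ", attr(cases, "dropped_episodes"),
          " unmatched episodes dropped, ",
          attr(cases, "deduplicated_episodes"), " duplicates removed")
  cohort <- filter_eligible(cases, config$study_start, config$study_end,
                            injury_prefixes = config$injury_prefixes,
                            quiet = TRUE)
  excl <- attr(cohort, "exclusions")
  readr::write_csv(excl, file.path(config$output_dir, "exclusions.csv"))
  logline("filter: ", nrow(cohort), " of ", nrow(cases), " cases eligible")

  cohort <- phenotype_cases(
    cohort,
    rti_cluster = config$rti_cluster,
    sensitive_cluster = config$respiratory_cluster,
    chronic_groups = config$chronic_groups,
    window_days = config$rti_window_days,
    chronic_lookback_days = config$chronic_lookback_days
  )
  cohort$linked_30d <- linked_within_window(cohort, config$rti_window_days)
  logline("phenotype: ", sum(cohort$rti_related), " RTI-related, ",
          sum(cohort$any_respiratory_related), " any-respiratory, ",
          sum(cohort$any_chronic), " with chronic conditions")

  flat <- cohort
  flat$mention_codes <- join_codes(flat$mention_codes)
  flat$episodes <- NULL
  flat$chronic_codes <- NULL
  readr::write_csv(flat, file.path(config$output_dir, "cohort.csv"))

  audit <- file.path(config$output_dir, "audit.jsonl")
  audit_tbl <- cohort[, c("child_key", "cert_rti", "hosp_rti", "rti_related",
                          "cert_respiratory", "hosp_respiratory",
                          "any_respiratory_related", "any_chronic",
                          "n_chronic_groups", "season")]
  writeLines(vapply(seq_len(nrow(audit_tbl)), function(i) {
    jsonlite::toJSON(as.list(audit_tbl[i, ]), auto_unbox = TRUE)
  }, ""), audit)

  indicators <- c(rti = "rti_related", respiratory = "any_respiratory_related")
  fig1 <- dplyr::bind_rows(lapply(c(indicators, all_noninjury = list(NULL)),
    function(fl) annual_series(cohort, population, flag = fl)),
    .id = "indicator")
  readr::write_csv(fig1, file.path(config$output_dir, "figure1_data.csv"))
  trends <- dplyr::bind_rows(lapply(names(indicators), function(ind) {
    s <- fig1[fig1$indicator == ind, , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(indicator = ind), trend_table(s))
  }))
  trends <- dplyr::bind_rows(trends, dplyr::bind_cols(
    tibble::tibble(indicator = "all_noninjury"),
    trend_table(fig1[fig1$indicator == "all_noninjury", , drop = FALSE])))
  readr::write_csv(trends, file.path(config$output_dir, "trends.csv"))
  logline("trends: fitted ", nrow(trends), " band x indicator series")

  tab1 <- excess_table(cohort, population, config$study_start,
                       config$study_end, flags = indicators,
                       ci_method = config$ci_method)
  readr::write_csv(tab1, file.path(config$output_dir, "table1.csv"))
  wk <- dplyr::bind_rows(lapply(indicators, function(fl) {
    weekly_rates(cohort, population, config$study_start, config$study_end,
                 flag = fl)
  }), .id = "indicator")
  readr::write_csv(wk, file.path(config$output_dir, "weekly_rates.csv"))
  mo <- dplyr::bind_rows(lapply(indicators, function(fl) {
    monthly_circular(cohort, population, config$study_start, config$study_end,
                     flag = fl)
  }), .id = "indicator")
  readr::write_csv(mo, file.path(config$output_dir, "monthly_circular.csv"))
  logline("season: table1, weekly and monthly series written")

  tab2 <- prevalence_table(cohort)
  readr::write_csv(tab2, file.path(config$output_dir, "table2.csv"))

  band_prev <- tab2[tab2$group == "any_chronic" & tab2$age_band != "all", ]
  band_prev <- band_prev[match(intersect(age_band_levels(),
                                         band_prev$age_band),
                               band_prev$age_band), ]
  tests <- list(
    chronic_prevalence_rti_vs_nonrti = {
      rti <- cohort$rti_related
      chi2_2x2(sum(rti & cohort$any_chronic), sum(rti & !cohort$any_chronic),
               sum(!rti & cohort$any_chronic),
               sum(!rti & !cohort$any_chronic))
    },
    chronic_prevalence_age_trend =
      chi2_trend(band_prev$count, band_prev$denominator),
    winter_proportion = winter_proportion_comparison(cohort)
  )
  jsonlite::write_json(tests, file.path(config$output_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA)

  wpc <- tests$winter_proportion
  inf <- trends[trends$indicator == "rti" & trends$age_band == "28-364d", ]
  t1 <- function(ind) tab1[tab1$indicator == ind & tab1$age_band == "all", ]
  t1r <- t1("rti")
  t1s <- t1("respiratory")
  agr <- agreement_table(cohort, "respiratory",
                         restrict_to_hospital_deaths = TRUE)
  summary <- list(
    seed = config$seed,
    n_deaths_input = nrow(deaths),
    n_cohort = nrow(cohort),
    n_by_band = as.list(table(factor(cohort$age_band, age_band_levels()))),
    pct_rti_related = mean(cohort$rti_related) * 100,
    pct_rti_on_certificate = mean(cohort$cert_rti) * 100,
    pct_any_respiratory = mean(cohort$any_respiratory_related) * 100,
    pct_linked_30d = mean(cohort$linked_30d) * 100,
    pct_any_chronic = mean(cohort$any_chronic) * 100,
    pct_chronic_among_rti =
      mean(cohort$any_chronic[cohort$rti_related]) * 100,
    pct_chronic_among_nonrti =
      mean(cohort$any_chronic[!cohort$rti_related]) * 100,
    pct_multimorbid_of_chronic_rti = {
      cr <- cohort$rti_related & cohort$any_chronic
      mean(cohort$n_chronic_groups[cr] >= 2L) * 100
    },
    pct_rti_deaths_in_winter =
      mean(cohort$season[cohort$rti_related] == "winter") * 100,
    pct_winter_chronic = wpc$chronic$percent_winter,
    pct_winter_nonchronic = wpc$non_chronic$percent_winter,
    percent_agreement_respiratory_hospital = agr$percent_agreement,
    rti_all_ages = as.list(t1r[, c(
      "rate_winter", "rate_summer", "rate_ratio", "rate_difference",
      "excess_total", "excess_total_lo", "excess_total_hi", "excess_annual",
      "pct_of_winter_noninjury", "pct_of_all_indicator_deaths")]),
    respiratory_all_ages = as.list(t1s[, c(
      "rate_winter", "rate_summer", "rate_ratio", "rate_difference",
      "excess_total", "excess_annual", "pct_of_winter_noninjury",
      "pct_of_all_indicator_deaths")]),
    infant_rti_trend = list(
      annual_pct_change = inf$annual_pct_change,
      annual_pct_decline = -inf$annual_pct_change,
      ci = c(inf$annual_pct_change_lo, inf$annual_pct_change_hi),
      lr_p = inf$lr_p,
      changepoint_year = inf$changepoint_year
    )
  )
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done: run_summary.json written")
  invisible(summary)
}
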