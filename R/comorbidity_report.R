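#' Chronic-condition prevalence among RTI-related deaths
#'
#' Per age band (and all ages): the count and percentage of RTI-related
#' deaths carrying each chronic-condition group, plus `any_chronic` (one or
#' more groups) and `multimorbid` (two or more groups) rows. Groups are not
#' mutually exclusive, so group percentages can sum past 100.
#'
#' @param cases Phenotyped cohort; only `rti_related` rows are used.
#' @param flag Indicator column restricting the denominator (default
#'   `"rti_related"`).
#' @return Tibble (`age_band`, `group`, `count`, `denominator`, `percent`).
#' @export
prevalence_table <- function(cases, flag = "rti_related") {
  dd <- cases[cases[[flag]], , drop = FALSE]
  if (nrow(dd) == 0L) stop("no indicator deaths in the cohort", call. = FALSE)
  groups <- paste0("chronic_", chronic_group_names())
  one_band <- function(sub, band) {
    n <- nrow(sub)
    counts <- c(vapply(groups, function(g) sum(sub[[g]]), 0L),
                any_chronic = sum(sub$any_chronic),
                multimorbid = sum(sub$n_chronic_groups >= 2L))
    tibble::tibble(
      age_band = band,
      group = c(chronic_group_names(), "any_chronic", "multimorbid"),
      count = unname(counts),
      denominator = n,
      percent = unname(counts) / n * 100
    )
  }
  bands <- intersect(age_band_levels(), unique(dd$age_band))
  out <- lapply(bands, function(b) one_band(dd[dd$age_band == b, ], b))
  dplyr::bind_rows(c(out, list(one_band(dd, "all"))))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param correct Apply Yates continuity correction? Default `FALSE`.
#' @return List (`statistic`, `df`, `p`).
#' @export
chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- rbind(c(a, b), c(c, d))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Chi-squared test for trend in proportions
#'
#' Cochran-Armitage trend test across ordered groups with integer scores
#' 1..k (df = 1).
#'
#' @param successes,totals Integer vectors, one entry per ordered level.
#' @param scores Optional numeric scores (default `1:k`).
#' @return List (`statistic`, `df`, `p`).
#' @export
chi2_trend <- function(successes, totals, scores = seq_along(successes)) {
  if (length(successes) != length(totals) ||
      length(scores) != length(successes)) {
    stop("successes, totals and scores must have equal length", call. = FALSE)
  }
  if (length(successes) < 2L) stop("need at least 2 ordered groups",
                                   call. = FALSE)
  ht <- suppressWarnings(
    stats::prop.trend.test(successes, totals, score = scores))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Winter-death proportions for chronic versus non-chronic RTI deaths
#'
#' Among RTI-related deaths, compares the proportion dying in winter between
#' children with and without chronic conditions, with a Pearson 2x2
#' chi-squared test.
#'
#' @param cases Phenotyped cohort (needs `rti_related`, `any_chronic`,
#'   `season`).
#' @param correct Passed to [chi2_2x2()].
#' @return List: `chronic` and `non_chronic` (each `n`, `winter`,
#'   `percent_winter`) and `test` (see [chi2_2x2()]).
#' @export
winter_proportion_comparison <- function(cases, correct = FALSE) {
  dd <- cases[cases$rti_related, , drop = FALSE]
  ch <- dd[dd$any_chronic, , drop = FALSE]
  nc <- dd[!dd$any_chronic, , drop = FALSE]
  if (nrow(ch) == 0L || nrow(nc) == 0L) {
    stop("both chronic and non-chronic RTI-death groups must be non-empty",
         call. = FALSE)
  }
  summ <- function(x) list(n = nrow(x), winter = sum(x$season == "winter"),
                           percent_winter = mean(x$season == "winter") * 100)
  s_ch <- summ(ch)
  s_nc <- summ(nc)
  # a zero season margin means both proportions are 0 or 100: null test
  if (s_ch$percent_winter == s_nc$percent_winter &&
      s_ch$percent_winter %in% c(0, 100)) {
    test <- list(statistic = 0, df = 1L, p = 1)
  } else {
    test <- chi2_2x2(s_ch$winter, s_ch$n - s_ch$winter,
                     s_nc$winter, s_nc$n - s_nc$winter, correct = correct)
  }
  list(chronic = s_ch, non_chronic = s_nc, test = test)
}
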