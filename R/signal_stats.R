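#' Drug-by-endpoint contingency tables
#'
#' For every drug x endpoint pair, tabulates the four disproportionality
#' cells over the analysis cohort: `a` = cases exposed to the drug reporting
#' the endpoint, `b` = unexposed cases reporting the endpoint, `c` = exposed
#' cases without the endpoint, `d` = the remainder.  One case contributes
#' once per (drug-exposure, endpoint-status) combination, so every row sums
#' to the cohort grand total and, for a fixed endpoint, the event margin
#' `a + b` is identical across drugs.
#'
#' @param cohort An `analysis_cohort` from [build_cohort()].
#' @param drugs,endpoints Character vectors selecting and ordering the rows;
#'   default to the cohort's dictionaries.
#' @return Tibble with columns drug, endpoint, a, b, c, d, n.
#' @export
contingency_tables <- function(cohort, drugs = cohort$drugs,
                               endpoints = cohort$endpoints) {
  stopifnot(inherits(cohort, "analysis_cohort"))
  if (cohort$n == 0) stop("cohort is empty", call. = FALSE)
  grid <- tidyr::expand_grid(drug = drugs, endpoint = endpoints)
  exp_sets <- split(cohort$exposure$caseid, cohort$exposure$drug)
  evt_sets <- split(cohort$events$caseid, cohort$events$endpoint)
  n <- cohort$n
  cells <- purrr::pmap(grid, function(drug, endpoint) {
    ex <- exp_sets[[drug]] %||% character()
    ev <- evt_sets[[endpoint]] %||% character()
    a <- sum(ex %in% ev)
    tibble::tibble(a = a, b = length(ev) - a, c = length(ex) - a,
                   d = n - length(ev) - length(ex) + a)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(cells)) |>
    dplyr::mutate(n = .env$n)
}

#' Proportional reporting ratio with 95% CI
#'
#' PRR = \[a/(a+c)\] / \[b/(b+d)\] with a Woolf-type interval
#' exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d))).  Not estimable
#' (all `NA`) when `a = 0` or `b = 0`.
#'
#' @param a,b,c,d Contingency cells (vectorized).
#' @return Tibble with columns `prr`, `prr_low`, `prr_high`.
#' @export
prr <- function(a, b, c, d) {
  est <- (a / (a + c)) / (b / (b + d))
  se <- sqrt(1 / a - 1 / (a + c) + 1 / b - 1 / (b + d))
  bad <- a == 0 | b == 0
  est[bad] <- NA_real_
  tibble::tibble(prr = est,
                 prr_low = exp(log(est) - 1.96 * se),
                 prr_high = exp(log(est) + 1.96 * se))
}

#' Reporting odds ratio with 95% Woolf CI
#'
#' ROR = ad/(bc) with exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' Not estimable when any cell is zero (no continuity correction in the
#' headline analysis).
#'
#' @inheritParams prr
#' @return Tibble with columns `ror`, `ror_low`, `ror_high`.
#' @export
ror <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  bad <- a == 0 | b == 0 | c == 0 | d == 0
  est[bad] <- NA_real_
  tibble::tibble(ror = est,
                 ror_low = exp(log(est) - 1.96 * se),
                 ror_high = exp(log(est) + 1.96 * se))
}

#' Yates continuity-corrected chi-square for a 2x2 table
#'
#' N (max(0, |ad - bc| - N/2))^2 / \[(a+b)(c+d)(a+c)(b+d)\], clamped at zero
#' when the continuity correction exceeds |ad - bc|.  Not estimable when any
#' margin is zero.
#'
#' @inheritParams prr
#' @return Numeric vector of statistics.
#' @export
chi2_yates <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- pmax(0, abs(a * d - b * c) - n / 2)
  out <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  out[(a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0] <- NA_real_
  out
}

#' BCPNN information component with asymmetric 95% credibility bounds
#'
#' The shrunk observed-to-expected log-ratio of the Bayesian confidence
#' propagation neural network framework: with E = (a+b)(a+c)/N,
#' IC = log2((a + 0.5)/(E + 0.5)).  The credibility bounds use the standard
#' asymmetric expansion in powers of (a + 0.5)^(-1/2):
#' IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2) and
#' IC975 = IC + 2.4 (a+0.5)^(-1/2) - 0.5 (a+0.5)^(-3/2).  The shrinkage
#' makes every cell configuration estimable.
#'
#' @inheritParams prr
#' @return Tibble with columns `ic`, `ic025`, `ic975`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  s <- (a + 0.5)^(-0.5)
  s3 <- (a + 0.5)^(-1.5)
  tibble::tibble(ic = ic,
                 ic025 = ic - 3.3 * s - 2 * s3,
                 ic975 = ic + 2.4 * s - 0.5 * s3)
}

#' Per-metric pharmacovigilance signal flags
#'
#' Standard criteria: PRR signal when `a >= 3`, `PRR >= 2` and Yates
#' chi-square `>= 4` (the Evans criterion); ROR signal when `a >= 3` and the
#' lower 95% bound exceeds 1; IC signal when IC025 exceeds 0.  `any_signal`
#' is their disjunction.  Non-estimable statistics never flag.
#'
#' @param stats A tibble holding at least `a`, `prr`, `chi2`, `ror_low`,
#'   `ic025` (as produced by [disproportionality()]).
#' @return The input with logical columns `prr_signal`, `ror_signal`,
#'   `ic_signal`, `any_signal` appended.
#' @export
flag_signals <- function(stats) {
  stats |>
    dplyr::mutate(
      prr_signal = !is.na(.data$prr) & .data$a >= 3 & .data$prr >= 2 &
        !is.na(.data$chi2) & .data$chi2 >= 4,
      ror_signal = !is.na(.data$ror_low) & .data$a >= 3 & .data$ror_low > 1,
      ic_signal = !is.na(.data$ic025) & .data$ic025 > 0,
      any_signal = .data$prr_signal | .data$ror_signal | .data$ic_signal
    )
}

#' Full disproportionality stack for a set of contingency tables
#'
#' Computes PRR, ROR (each with 95% CI), the Yates-corrected chi-square and
#' the BCPNN information component with credibility bounds for every row,
#' and appends per-metric signal flags.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (and typically
#'   `drug`, `endpoint`), e.g. from [contingency_tables()] or a pre-tabulated
#'   counts file.
#' @return The input plus all statistic and flag columns.
#' @export
disproportionality <- function(tables) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(tables))) {
    stop("tables must carry columns a, b, c, d", call. = FALSE)
  }
  if (any(tables[need] < 0) || any(tables[need] != round(tables[need]))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  dplyr::bind_cols(
    tables,
    prr(tables$a, tables$b, tables$c, tables$d),
    tibble::tibble(chi2 = chi2_yates(tables$a, tables$b, tables$c, tables$d)),
    ror(tables$a, tables$b, tables$c, tables$d),
    bcpnn_ic(tables$a, tables$b, tables$c, tables$d)
  ) |>
    flag_signals()
}

#' Drugs-by-endpoints signal matrix
#'
#' @param results Output of [disproportionality()] with `drug` and `endpoint`
#'   columns.
#' @param which Flag column to pivot (default `any_signal`).
#' @return Wide tibble, one row per drug, values `"signal"` / `"no-signal"`.
#' @export
signal_matrix <- function(results, which = "any_signal") {
  results |>
    dplyr::mutate(value = ifelse(.data[[which]], "signal", "no-signal")) |>
    dplyr::select("drug", "endpoint", "value") |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "value")
}

#' Published drug x endpoint contingency counts
#'
#' The 32 printed (drug, endpoint, a, b, c, d) rows of the source analysis's
#' disproportionality table (eight antidepressants by four arrhythmia
#' endpoints over 746,507 depression/MDD reports), shipped as a plain-text
#' fixture so the statistical core can be exercised and checked without any
#' raw report data.
#'
#' @param path CSV location; defaults to the shipped fixture.
#' @return Tibble with columns drug, endpoint, a, b, c, d.
#' @export
table2_counts <- function(path = pv_extdata("table2_counts.csv")) {
  readr::read_csv(path, col_types = "ccdddd", progress = FALSE)
}
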