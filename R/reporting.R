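median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

pct_breakdown <- function(characteristic, x, levels) {
  x <- factor(x, levels = levels)
  n <- table(x)
  tibble::tibble(characteristic = characteristic, level = levels,
                 n = as.integer(n),
                 pct = if (sum(n) > 0) round(100 * as.integer(n) / sum(n), 1)
                       else rep(NA_real_, length(levels)))
}

#' Descriptive summary of one endpoint's reports
#'
#' Baseline-characteristics style summary over the cohort cases reporting an
#' endpoint: report count, median and IQR of age (years) and weight (kg) over
#' known values (type-6 quantiles, the (n+1)p linear-interpolation
#' convention), and percentage breakdowns with explicit unknown strata for
#' sex, reporting region (US / other / unknown), seriousness, and the
#' individual serious-outcome codes.  For a specific outcome, `yes` means
#' the code was reported, `no` means other outcome codes were reported but
#' not this one, and `unknown` means the report carries no outcome record.
#'
#' @param cohort An `analysis_cohort`.
#' @param endpoint Endpoint code.
#' @param outc Optional outcome table (`primaryid`-free tibble with `caseid`,
#'   `outcome_code`) for the per-code breakdowns; taken from the cohort cases'
#'   severity information when omitted.
#' @return A list of class `descriptive_summary`: `endpoint`, `n`,
#'   `age` and `weight` (median/q1/q3), and `breakdowns` (long tibble).
#' @export
descriptive_summary <- function(cohort, endpoint, outc = NULL) {
  stopifnot(inherits(cohort, "analysis_cohort"))
  ids <- cohort$events$caseid[cohort$events$endpoint == endpoint]
  sub <- cohort$cases[cohort$cases$caseid %in% ids, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(structure(list(endpoint = endpoint, n = 0L,
                          age = median_iqr(numeric()),
                          weight = median_iqr(numeric()),
                          breakdowns = tibble::tibble()),
                     class = "descriptive_summary"))
  }
  region <- dplyr::case_when(
    sub$reporter_country == "US" ~ "united_states",
    sub$reporter_country == "unknown" ~ "unknown",
    .default = "other"
  )
  outcome_yn <- function(code_present) {
    dplyr::case_when(code_present ~ "yes",
                     sub$has_outcome ~ "no",
                     .default = "unknown")
  }
  per_code <- NULL
  if (!is.null(outc)) {
    codes <- c(hospitalization = "HO", death = "DE", disability = "DS",
               life_threatening = "LT")
    per_code <- dplyr::bind_rows(lapply(names(codes), function(nm) {
      with_code <- unique(outc$caseid[outc$outcome_code == codes[[nm]]])
      pct_breakdown(nm, outcome_yn(sub$caseid %in% with_code),
                    c("yes", "no", "unknown"))
    }))
  }
  breakdowns <- dplyr::bind_rows(
    pct_breakdown("sex", sub$sex, c("male", "female", "unknown")),
    pct_breakdown("region", region, c("united_states", "other", "unknown")),
    pct_breakdown("seriousness",
                  ifelse(sub$has_outcome, "serious", "non_serious"),
                  c("serious", "non_serious")),
    per_code
  )
  structure(list(endpoint = endpoint, n = nrow(sub),
                 age = median_iqr(sub$age_years),
                 weight = median_iqr(sub$weight_kg),
                 breakdowns = breakdowns),
            class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("<descriptive_summary %s> n = %d; age %s (%s, %s); weight %s (%s, %s)\n",
              x$endpoint, x$n,
              format(x$age[["median"]]), format(x$age[["q1"]]),
              format(x$age[["q3"]]), format(x$weight[["median"]]),
              format(x$weight[["q1"]]), format(x$weight[["q3"]])))
  invisible(x)
}

descriptive_table <- function(summaries) {
  dplyr::bind_rows(lapply(summaries, function(s) {
    dplyr::bind_rows(
      tibble::tibble(endpoint = s$endpoint, characteristic = "total",
                     level = "n", n = s$n, pct = NA_real_, value = s$n),
      tibble::tibble(endpoint = s$endpoint,
                     characteristic = c("age_years", "age_years", "age_years",
                                        "weight_kg", "weight_kg", "weight_kg"),
                     level = rep(c("median", "q1", "q3"), 2),
                     n = NA_integer_, pct = NA_real_,
                     value = c(s$age, s$weight)),
      if (s$n > 0) dplyr::mutate(s$breakdowns, endpoint = s$endpoint,
                                 value = NA_real_)
    )
  }))
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates ingest (or simulation, or pre-tabulated counts), case
#' deduplication, cohort construction, disproportionality statistics,
#' pairwise constituent-ratio and severity comparisons, and descriptive
#' summaries, writing tidy CSV artifacts plus a run manifest with counts at
#' every stage.  Identical configuration and seed produce identical outputs.
#'
#' Exactly one input mode must be configured:
#' \describe{
#'   \item{`simulate`}{a [simulation_config()] (or a list of its arguments).}
#'   \item{`input`}{a list of per-quarter path sets for [parse_quarter()],
#'     i.e. `list("2015Q1" = list(demo = ..., drug = ..., ...), ...)`.}
#'   \item{`from_counts`}{path to a pre-tabulated counts CSV with columns
#'     drug, endpoint, a, b, c, d.  Bypasses I/O and cohort stages and
#'     exercises the statistical core alone; no descriptive or severity
#'     output.}
#' }
#'
#' @param config A named list (or YAML file path) with one input mode plus
#'   optional `drug_dictionary` / `endpoint_dictionary` paths,
#'   `indication_terms`, `exposure_roles`, and `seed`.
#' @param out_dir Output directory for artifacts.
#' @return Invisibly, a list with the signal results, pairwise results,
#'   descriptive table (when applicable), and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  modes <- c("simulate", "input", "from_counts")
  present <- modes[modes %in% names(config)]
  if (length(present) != 1) {
    stop("config must set exactly one of: ", paste(modes, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = present, seed = config$seed %||% NA,
                   stages = list())
  log_stage <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  results <- pairs_constituent <- pairs_severity <- desc <- NULL

  if (present == "from_counts") {
    tables <- tryCatch(
      readr::read_csv(config$from_counts, col_types = "ccdddd",
                      progress = FALSE),
      error = function(e) stop("stage signal_stats: cannot read counts file: ",
                               conditionMessage(e), call. = FALSE))
    log_stage("from_counts", rows = nrow(tables))
  } else {
    if (present == "simulate") {
      sim <- config$simulate
      if (!inherits(sim, "simulation_config")) {
        if (!is.null(config$seed)) sim$seed <- config$seed
        sim <- do.call(simulation_config, sim)
      }
      bundles <- generate_reports(sim)
      log_stage("simulate", quarters = length(bundles),
                demo_rows = sum(vapply(bundles, function(b) nrow(b$demo),
                                       numeric(1))))
    } else {
      bundles <- tryCatch(
        lapply(names(config$input), function(q) {
          parse_quarter(config$input[[q]], quarter = q)
        }),
        error = function(e) stop("stage faers_io: ", conditionMessage(e),
                                 call. = FALSE))
      log_stage("ingest", quarters = length(bundles),
                demo_rows = sum(vapply(bundles, function(b) nrow(b$demo),
                                       numeric(1))),
                rejects = sum(vapply(bundles, function(b) nrow(b$rejects),
                                     numeric(1))))
      rejects <- dplyr::bind_rows(lapply(bundles, `[[`, "rejects"))
      readr::write_csv(rejects, file.path(out_dir, "rejects.csv"))
    }
    cases <- deduplicate(bundles)
    log_stage("deduplicate", cases = cases$n_cases,
              versions_dropped = cases$n_versions_dropped)
    dict_d <- tryCatch({
      if (!is.null(config$drug_dictionary))
        read_drug_dictionary(config$drug_dictionary)
      else read_drug_dictionary()
    }, error = function(e) stop("stage cohort_mapping: ",
                                conditionMessage(e), call. = FALSE))
    dict_e <- tryCatch({
      if (!is.null(config$endpoint_dictionary))
        read_endpoint_dictionary(config$endpoint_dictionary)
      else read_endpoint_dictionary()
    }, error = function(e) stop("stage cohort_mapping: ",
                                conditionMessage(e), call. = FALSE))
    cohort <- build_cohort(
      cases, dict_d, dict_e,
      indication_terms = config$indication_terms %||%
        c("Depression", "Major depression"),
      exposure_roles = config$exposure_roles %||% c("PS", "SS"))
    log_stage("cohort", cases = cohort$n, exposures = nrow(cohort$exposure),
              events = nrow(cohort$events))
    tables <- contingency_tables(cohort)
    desc <- descriptive_table(lapply(cohort$endpoints, function(e) {
      outc_map <- tibble::tibble(
        caseid = case_id_of(cases$demo, cases$outc$primaryid),
        outcome_code = cases$outc$outcome_code)
      descriptive_summary(cohort, e, outc = outc_map)
    }))
    readr::write_csv(desc, file.path(out_dir, "descriptive.csv"))
    pairs_severity <- dplyr::bind_rows(lapply(cohort$endpoints, function(e) {
      all_pairs(cohort, e, drugs = cohort$drugs, kind = "severity")
    }))
    readr::write_csv(pairs_severity,
                     file.path(out_dir, "pairwise_severity.csv"))
  }

  results <- disproportionality(tables)
  log_stage("signal_stats", pairs = nrow(results),
            flagged = sum(results$any_signal))
  readr::write_csv(results, file.path(out_dir, "signals.csv"))
  readr::write_csv(signal_matrix(results),
                   file.path(out_dir, "signal_matrix.csv"))
  pairs_constituent <- dplyr::bind_rows(
    lapply(unique(results$endpoint), function(e) {
      all_pairs(tables, e, drugs = unique(results$drug),
                kind = "constituent-ratio")
    }))
  log_stage("comparative_stats", pairs = nrow(pairs_constituent))
  readr::write_csv(pairs_constituent,
                   file.path(out_dir, "pairwise_constituent.csv"))
  manifest$config <- config[setdiff(names(config), "simulate")]
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(signals = results, pairwise_constituent = pairs_constituent,
                 pairwise_severity = pairs_severity, descriptive = desc,
                 manifest = manifest))
}
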