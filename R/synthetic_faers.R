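#' Default drug catalog for the synthetic generator
#'
#' The eight study antidepressants at their observed report-margin shares in
#' the 746,507-report depression cohort (per-drug (a+c)/N), each with a few
#' verbatim spellings (brand, salt, dosed forms) to exercise name
#' normalization.
#'
#' @return Tibble with columns `generic`, `share`, `synonyms`.
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    generic = c("citalopram", "escitalopram", "sertraline", "venlafaxine",
                "fluoxetine", "mirtazapine", "duloxetine", "quetiapine"),
    share = c(50205, 50598, 82268, 78379, 50692, 35765, 79265, 22763) / 746507,
    synonyms = list(
      c("CITALOPRAM", "CITALOPRAM HYDROBROMIDE", "CELEXA"),
      c("ESCITALOPRAM", "ESCITALOPRAM OXALATE 10MG", "LEXAPRO"),
      c("SERTRALINE", "SERTRALINE HYDROCHLORIDE", "ZOLOFT"),
      c("VENLAFAXINE", "VENLAFAXINE HCL 75 MG", "EFFEXOR XR"),
      c("FLUOXETINE", "FLUOXETINE HYDROCHLORIDE", "PROZAC"),
      c("MIRTAZAPINE", "MIRTAZAPINE 15MG TABLETS", "REMERON"),
      c("DULOXETINE", "DULOXETINE HYDROCHLORIDE", "CYMBALTA"),
      c("QUETIAPINE", "QUETIAPINE FUMARATE", "SEROQUEL")
    )
  )
}

#' Default background endpoint reporting rates
#'
#' The study's per-endpoint event margins over its grand total
#' (2671 / 689 / 655 / 616 out of 746,507 reports).
#'
#' @return Named numeric vector of per-report probabilities.
#' @export
default_endpoint_rates <- function() {
  c(qt_prolongation_tdp = 2671, atrial_fibrillation = 689,
    heart_block = 655, ventricular_arrhythmia = 616) / 746507
}

# neutral filler reaction PTs carried by every report (50 terms)
.filler_pts <- c(
  "Nausea", "Headache", "Dizziness", "Fatigue", "Insomnia", "Somnolence",
  "Diarrhoea", "Constipation", "Vomiting", "Dry mouth", "Decreased appetite",
  "Weight increased", "Weight decreased", "Anxiety", "Tremor",
  "Hyperhidrosis", "Rash", "Pruritus", "Arthralgia", "Myalgia",
  "Back pain", "Abdominal pain", "Dyspepsia", "Paraesthesia", "Vision blurred",
  "Tinnitus", "Vertigo", "Asthenia", "Malaise", "Irritability",
  "Agitation", "Confusional state", "Memory impairment", "Libido decreased",
  "Yawning", "Restlessness", "Nightmare", "Dysgeusia", "Photosensitivity reaction",
  "Alopecia", "Epistaxis", "Urinary retention", "Oedema peripheral",
  "Hot flush", "Chills", "Pyrexia", "Cough", "Nasopharyngitis",
  "Influenza like illness", "Fall"
)

.other_drug_pool <- sprintf("FILLERDRUG %02d", 1:30)

.nondep_indications <- c("Hypertension", "Diabetes mellitus", "Anxiety",
                         "Insomnia", "Pain")

quarter_seq <- function(from = "2015Q1", to = "2023Q3") {
  fy <- as.integer(substr(from, 1, 4)); fq <- as.integer(substr(from, 6, 6))
  ty <- as.integer(substr(to, 1, 4)); tq <- as.integer(substr(to, 6, 6))
  idx <- seq(fy * 4 + fq - 1, ty * 4 + tq - 1)
  sprintf("%dQ%d", idx %/% 4, idx %% 4 + 1)
}

quarter_start <- function(q) {
  as.Date(sprintf("%s-%02d-01", substr(q, 1, 4),
                  (as.integer(substr(q, 6, 6)) - 1) * 3 + 1))
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defaults reproduce the statistical conditions of the source cohort: the
#' eight study antidepressants at their observed report shares, the four
#' arrhythmia endpoints at their observed background reporting rates, and a
#' grand total of 746,507 reports.  Planted reporting-rate ratios multiply an
#' endpoint's background rate for a given drug, giving known ground truth for
#' estimator checks.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param n_reports Number of distinct cases to simulate.
#' @param drug_catalog Tibble with columns `generic`, `share`, `synonyms`
#'   (list of verbatim spellings).  Shares must sum to at most 1; the
#'   remainder is a pool of unrelated drugs.
#' @param endpoint_rates Named vector of background per-report endpoint
#'   probabilities.
#' @param endpoint_pts Named list endpoint -> preferred terms to draw from
#'   (defaults to the shipped endpoint dictionary).
#' @param planted_rrr Tibble (`drug`, `endpoint`, `rrr`) of reporting-rate
#'   multipliers; pairs not listed have ratio 1.
#' @param severity_profile Tibble (`drug`, `endpoint`, `p_severe`,
#'   `p_other_serious`, `p_none`) overriding, for endpoint-positive reports
#'   of that pair, the default outcome-severity split of 0.35 / 0.60 / 0.05
#'   (non-endpoint reports use 0.05 / 0.55 / 0.40).
#' @param duplicate_fraction Probability that a case emits a second, later
#'   report version (removed again by deduplication).
#' @param indication_share Fraction of reports carrying a depression/MDD
#'   indication (the rest are excluded by the cohort filter).
#' @param quarters Quarter labels over which reports are spread uniformly.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_reports = 746507L,
                              drug_catalog = default_drug_catalog(),
                              endpoint_rates = default_endpoint_rates(),
                              endpoint_pts = yaml::read_yaml(
                                pv_extdata("endpoint_dictionary.yaml")),
                              planted_rrr = NULL,
                              severity_profile = NULL,
                              duplicate_fraction = 0.05,
                              indication_share = 0.9,
                              quarters = quarter_seq("2015Q1", "2023Q3")) {
  stopifnot(n_reports >= 1, length(quarters) >= 1)
  if (sum(drug_catalog$share) > 1 + 1e-12) {
    stop("drug catalog shares sum to more than 1", call. = FALSE)
  }
  if (any(endpoint_rates < 0 | endpoint_rates > 1) ||
      duplicate_fraction < 0 || duplicate_fraction > 1 ||
      indication_share < 0 || indication_share > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(names(endpoint_rates) %in% names(endpoint_pts))) {
    stop("every endpoint rate needs a PT group", call. = FALSE)
  }
  if (is.null(planted_rrr)) {
    planted_rrr <- tibble::tibble(drug = character(), endpoint = character(),
                                  rrr = numeric())
  }
  if (any(!is.finite(planted_rrr$rrr)) || any(planted_rrr$rrr < 0)) {
    stop("planted reporting-rate ratios must be finite and >= 0",
         call. = FALSE)
  }
  eff <- planted_rrr$rrr * unname(endpoint_rates[planted_rrr$endpoint])
  if (any(eff > 1)) {
    stop("ill-posed config: rate x multiplier exceeds 1 for ",
         paste(planted_rrr$drug[eff > 1], planted_rrr$endpoint[eff > 1],
               sep = "/", collapse = ", "),
         call. = FALSE)
  }
  if (is.null(severity_profile)) {
    severity_profile <- tibble::tibble(drug = character(),
                                       endpoint = character(),
                                       p_severe = numeric(),
                                       p_other_serious = numeric(),
                                       p_none = numeric())
  } else {
    sums <- severity_profile$p_severe + severity_profile$p_other_serious +
      severity_profile$p_none
    if (any(abs(sums - 1) > 1e-8)) {
      stop("severity profile rows must sum to 1", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog, endpoint_rates = endpoint_rates,
                 endpoint_pts = endpoint_pts, planted_rrr = planted_rrr,
                 severity_profile = severity_profile,
                 duplicate_fraction = duplicate_fraction,
                 indication_share = indication_share, quarters = quarters),
            class = "simulation_config")
}

#' Generate synthetic FAERS-like quarterly bundles
#'
#' Each simulated case carries one suspect antidepressant drawn from the
#' catalog (or the unrelated-drug pool), endpoint reactions drawn at
#' background rate times the planted reporting-rate ratio, filler reactions,
#' outcome codes drawn from the severity profile, an indication, and -- at
#' the configured duplicate fraction -- a second report version with a later
#' receipt date.  Reports are assigned uniformly to the configured quarters.
#'
#' @param config A [simulation_config()].
#' @return A list of `faers_quarter` bundles (one per quarter that received
#'   at least one report), with attribute `ground_truth` recording the
#'   planted per-report drug and endpoint assignments.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  cat_tbl <- config$drug_catalog
  eps <- names(config$endpoint_rates)

  caseid <- as.character(90000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # suspect drug per report
  pool_share <- 1 - sum(cat_tbl$share)
  drug_idx <- sample.int(nrow(cat_tbl) + 1L, n, replace = TRUE,
                         prob = c(cat_tbl$share, pool_share))
  is_study <- drug_idx <= nrow(cat_tbl)
  drug <- ifelse(is_study, cat_tbl$generic[drug_idx], "other")
  verbatim <- character(n)
  for (i in seq_len(nrow(cat_tbl))) {
    sel <- drug_idx == i
    verbatim[sel] <- sample(cat_tbl$synonyms[[i]], sum(sel), replace = TRUE)
  }
  verbatim[!is_study] <- sample(.other_drug_pool, sum(!is_study),
                                replace = TRUE)

  # endpoint occurrences at rate x planted ratio
  rrr <- matrix(1, nrow = nrow(cat_tbl) + 1L, ncol = length(eps),
                dimnames = list(c(cat_tbl$generic, "other"), eps))
  if (nrow(config$planted_rrr) > 0) {
    rrr[cbind(config$planted_rrr$drug, config$planted_rrr$endpoint)] <-
      config$planted_rrr$rrr
  }
  occurs <- matrix(FALSE, n, length(eps), dimnames = list(NULL, eps))
  for (e in seq_along(eps)) {
    p <- config$endpoint_rates[[eps[e]]] * rrr[drug_idx, e]
    occurs[, e] <- runif(n) < p
  }

  # reaction PTs: endpoint terms plus 1-3 neutral fillers
  ep_rows <- lapply(eps, function(e) {
    idx <- which(occurs[, e])
    tibble::tibble(primaryid = primaryid[idx],
                   pt = sample(config$endpoint_pts[[e]], length(idx),
                               replace = TRUE))
  })
  n_fill <- 1L + rpois(n, 1)
  reac <- dplyr::bind_rows(
    dplyr::bind_rows(ep_rows),
    tibble::tibble(primaryid = rep(primaryid, n_fill),
                   pt = sample(.filler_pts, sum(n_fill), replace = TRUE))
  )

  # outcome severity: default split, overridable per (drug, endpoint)
  has_ep <- rowSums(occurs) > 0
  p_severe <- ifelse(has_ep, 0.35, 0.05)
  p_none <- ifelse(has_ep, 0.05, 0.40)
  if (nrow(config$severity_profile) > 0) {
    for (k in seq_len(nrow(config$severity_profile))) {
      row <- config$severity_profile[k, ]
      sel <- drug == row$drug & occurs[, row$endpoint]
      p_severe[sel] <- row$p_severe
      p_none[sel] <- row$p_none
    }
  }
  u <- runif(n)
  category <- ifelse(u < p_severe, "severe",
                     ifelse(u < 1 - p_none, "other", "none"))
  sev_idx <- which(category == "severe")
  oth_idx <- which(category == "other")
  outc <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid[sev_idx],
                   outcome_code = ifelse(runif(length(sev_idx)) < 0.4,
                                         "DE", "LT")),
    tibble::tibble(primaryid = primaryid[sev_idx][
      runif(length(sev_idx)) < 0.5], outcome_code = "HO"),
    tibble::tibble(primaryid = primaryid[oth_idx],
                   outcome_code = sample(c("HO", "DS", "OT"),
                                         length(oth_idx), replace = TRUE,
                                         prob = c(0.7, 0.1, 0.2)))
  )

  # indication
  dep <- runif(n) < config$indication_share
  indi_pt <- character(n)
  indi_pt[dep] <- sample(c("Depression", "Major depression"), sum(dep),
                         replace = TRUE, prob = c(0.7, 0.3))
  indi_pt[!dep] <- sample(.nondep_indications, sum(!dep), replace = TRUE)
  indi <- tibble::tibble(primaryid = primaryid, indi_pt = indi_pt)

  # demographics and dates
  quarter <- sample(config$quarters, n, replace = TRUE)
  q_start <- quarter_start(quarter)
  fda_dt <- q_start + sample.int(90, n, replace = TRUE) - 1L
  event_dt <- fda_dt - sample.int(180, n, replace = TRUE)
  age <- round(pmin(pmax(rnorm(n, 55, 18), 18), 99))
  age[runif(n) < 0.10] <- NA
  wt <- round(pmin(pmax(rnorm(n, 75, 16), 40), 140), 1)
  wt[runif(n) < 0.40] <- NA
  sex <- sample(c("male", "female", "unknown"), n, replace = TRUE,
                prob = c(0.32, 0.58, 0.10))
  country <- sample(c("US", "GB", "FR", "JP", "CA", "unknown"), n,
                    replace = TRUE, prob = c(0.4, 0.15, 0.12, 0.1, 0.08, 0.15))
  demo <- tibble::tibble(primaryid = primaryid, caseid = caseid,
                         event_date = event_dt, age_years = age,
                         weight_kg = wt, sex = sex,
                         reporter_country = country,
                         fda_receipt_date = fda_dt)

  # suspect mention (mostly primary-suspect) plus concomitant filler drugs
  role <- sample(c("PS", "SS"), n, replace = TRUE, prob = c(0.85, 0.15))
  n_con <- pmin(rpois(n, 0.8), 2L)
  con_pid <- rep(primaryid, n_con)
  drug_tbl <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid, drug_seq = 1L,
                   verbatim_name = verbatim, role_code = role),
    tibble::tibble(primaryid = con_pid,
                   drug_seq = unlist(lapply(n_con[n_con > 0], seq_len),
                                     use.names = FALSE) + 1L,
                   verbatim_name = sample(.other_drug_pool, length(con_pid),
                                          replace = TRUE),
                   role_code = "C")
  )

  # duplicate case versions: same case, later receipt date, higher version id
  dup <- which(runif(n) < config$duplicate_fraction)
  if (length(dup) > 0) {
    pid2 <- paste0(caseid[dup], "2")
    remap <- function(tbl) {
      sub <- tbl[tbl$primaryid %in% primaryid[dup], , drop = FALSE]
      sub$primaryid <- paste0(substr(sub$primaryid, 1,
                                     nchar(sub$primaryid) - 1L), "2")
      sub
    }
    demo2 <- demo[dup, ]
    demo2$primaryid <- pid2
    demo2$fda_receipt_date <- demo2$fda_receipt_date +
      sample.int(180, length(dup), replace = TRUE)
    demo <- dplyr::bind_rows(demo, demo2)
    drug_tbl <- dplyr::bind_rows(drug_tbl, remap(drug_tbl))
    reac <- dplyr::bind_rows(reac, remap(reac))
    outc <- dplyr::bind_rows(outc, remap(outc))
    indi <- dplyr::bind_rows(indi, remap(indi))
    quarter <- c(quarter, quarter[dup])
  }

  # split into per-quarter bundles (order stable within quarter)
  bundles <- lapply(sort(unique(quarter)), function(q) {
    keep <- demo$primaryid[quarter == q]
    sel <- function(tbl) tbl[tbl$primaryid %in% keep, , drop = FALSE]
    new_faers_quarter(q, demo[quarter == q, ], sel(drug_tbl), sel(reac),
                      sel(outc), sel(indi))
  })
  attr(bundles, "ground_truth") <- tibble::tibble(
    caseid = caseid, drug = drug, depression = dep,
    tibble::as_tibble(occurs)
  )
  bundles
}

#' Generate a synthetic dataset and write it as quarterly extract files
#'
#' @param config A [simulation_config()].
#' @param dir Output directory; one DEMO/DRUG/REAC/OUTC/INDI file set per
#'   quarter.
#' @return Invisibly, a list with the bundles and the written file paths.
#' @export
simulate_faers <- function(config, dir) {
  bundles <- generate_reports(config)
  paths <- lapply(bundles, write_quarter, dir = dir)
  names(paths) <- vapply(bundles, `[[`, character(1), "quarter")
  invisible(list(bundles = bundles, paths = paths))
}
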