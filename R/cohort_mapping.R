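# tokens stripped from verbatim drug names before dictionary lookup:
# salt forms, hydrate states, formulation/release qualifiers, dose units
.drug_strip_tokens <- c(
  "hydrobromide", "hydrochloride", "hcl", "oxalate", "fumarate", "succinate",
  "maleate", "citrate", "besylate", "mesylate", "tartrate", "bitartrate",
  "sodium", "potassium", "calcium", "monohydrate", "hemihydrate", "dihydrate",
  "anhydrous", "extended release", "delayed release", "xr", "er", "sr", "cr",
  "odt", "oral", "tablet", "tablets", "capsule", "capsules", "solution",
  "injection"
)

#' Normalize a verbatim drug name for dictionary lookup
#'
#' Case-folds, trims, removes dose tokens (e.g. `20MG`, `37.5 MG`), and strips
#' salt / hydrate / formulation suffixes by rule list.  Idempotent.
#'
#' @param verbatim Character vector of free-text drug names.
#' @return Normalized tokens (lower case, single-spaced).
#' @export
normalize_drug_name <- function(verbatim) {
  x <- tolower(trimws(verbatim %||% NA_character_))
  x <- gsub("[0-9]+(\\.[0-9]+)?\\s*(mg|mcg|g|ml|mg/ml)\\b", " ", x)
  pat <- paste0("\\b(", paste(.drug_strip_tokens, collapse = "|"), ")\\b")
  x <- gsub(pat, " ", x)
  x <- gsub("[[:punct:]]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Drug dictionary: generic name -> synonym set
#'
#' @param synonyms Named list: generic name -> character vector of verbatim
#'   synonyms (brands, salts).  Synonyms are normalized on load; the generic
#'   itself is always included.  Synonym sets must be pairwise disjoint
#'   across generics.
#' @return A named list of class `drug_dictionary`.
#' @export
drug_dictionary <- function(synonyms) {
  if (length(synonyms) == 0) stop("drug dictionary is empty", call. = FALSE)
  dict <- lapply(seq_along(synonyms), function(i) {
    unique(normalize_drug_name(c(names(synonyms)[i], synonyms[[i]])))
  })
  names(dict) <- normalize_drug_name(names(synonyms))
  all_syn <- unlist(dict, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    stop("drug synonym sets overlap across generics: ",
         paste(unique(all_syn[duplicated(all_syn)]), collapse = ", "),
         call. = FALSE)
  }
  structure(dict, class = "drug_dictionary")
}

#' @rdname drug_dictionary
#' @param path YAML file mapping generic names to synonym lists; defaults to
#'   the dictionary of the eight study antidepressants shipped with the
#'   package.
#' @export
read_drug_dictionary <- function(path = pv_extdata("drug_dictionary.yaml")) {
  drug_dictionary(yaml::read_yaml(path))
}

#' Endpoint dictionary: arrhythmia endpoint -> MedDRA preferred-term set
#'
#' The shipped default is an editable placeholder patterned on SMQ-narrow
#' grouping (licensed MedDRA SMQ content is not redistributed).  PT sets must
#' be pairwise disjoint across endpoints because each endpoint is tabulated
#' separately.
#'
#' @param groups Named list: endpoint code -> character vector of PTs.
#' @return A named list of class `endpoint_dictionary` (PTs case-folded).
#' @export
endpoint_dictionary <- function(groups) {
  if (length(groups) == 0) stop("endpoint dictionary is empty", call. = FALSE)
  dict <- lapply(groups, function(pts) {
    pts <- unique(tolower(trimws(pts)))
    if (length(pts) == 0) stop("endpoint with empty PT set", call. = FALSE)
    pts
  })
  all_pt <- unlist(dict, use.names = FALSE)
  if (anyDuplicated(all_pt)) {
    stop("endpoint PT sets overlap: ",
         paste(unique(all_pt[duplicated(all_pt)]), collapse = ", "),
         call. = FALSE)
  }
  structure(dict, class = "endpoint_dictionary")
}

#' @rdname endpoint_dictionary
#' @param path YAML file mapping endpoint codes to PT lists.
#' @export
read_endpoint_dictionary <- function(path = pv_extdata("endpoint_dictionary.yaml")) {
  endpoint_dictionary(yaml::read_yaml(path))
}

#' Classify a report's outcome codes into a severity category
#'
#' `severe` if death (`DE`) or a life-threatening event (`LT`) was reported;
#' `serious-non-severe` if any other serious outcome code is present
#' (hospitalization, disability, congenital anomaly, required intervention,
#' other serious); `non-serious` when no outcome record exists.
#'
#' @param outcomes List of character vectors of outcome codes (one element
#'   per report), or a single character vector for one report.
#' @return Character vector of categories.
#' @export
severity_category <- function(outcomes) {
  if (!is.list(outcomes)) outcomes <- list(outcomes)
  vapply(outcomes, function(x) {
    x <- toupper(x[!is.na(x)])
    if (any(x %in% c("DE", "LT"))) "severe"
    else if (length(x) > 0) "serious-non-severe"
    else "non-serious"
  }, character(1))
}

#' Build the indication-restricted analysis cohort
#'
#' Restricts deduplicated cases to those carrying at least one qualifying
#' indication PT (default: depression / major depression), then derives per
#' case: the exposed-drug set (suspect-role mentions matched through the drug
#' dictionary), the endpoint set (reaction PTs matched through the endpoint
#' dictionary), the severity category, and whether any outcome was recorded.
#'
#' @param cases A `faers_cases` from [deduplicate()].
#' @param drugs A `drug_dictionary`.
#' @param endpoints An `endpoint_dictionary`.
#' @param indication_terms Indication PTs (case-insensitive exact match)
#'   defining the cohort.
#' @param exposure_roles Drug role codes counted as exposure; suspect-only
#'   (`PS`, `SS`) by default.
#' @return An `analysis_cohort`: `cases` (one row per case with demographics,
#'   severity, `has_outcome`), `exposure` (long: caseid, drug), `events`
#'   (long: caseid, endpoint), `n` (grand total), plus the dictionaries used.
#' @export
build_cohort <- function(cases, drugs, endpoints,
                         indication_terms = c("Depression", "Major depression"),
                         exposure_roles = c("PS", "SS")) {
  stopifnot(inherits(cases, "faers_cases"),
            inherits(drugs, "drug_dictionary"),
            inherits(endpoints, "endpoint_dictionary"))
  if (length(indication_terms) == 0) {
    stop("indication term list is empty", call. = FALSE)
  }
  ind <- tolower(trimws(indication_terms))

  keep_pid <- unique(cases$indi$primaryid[
    tolower(trimws(cases$indi$indi_pt)) %in% ind])
  demo <- cases$demo[cases$demo$primaryid %in% keep_pid, , drop = FALSE]

  # exposure: suspect-role mentions resolving to a dictionary generic
  syn_to_generic <- stats::setNames(
    rep(names(drugs), lengths(drugs)), unlist(drugs, use.names = FALSE))
  drug_tbl <- cases$drug[cases$drug$primaryid %in% demo$primaryid &
                           cases$drug$role_code %in% exposure_roles, ,
                         drop = FALSE]
  generic <- unname(syn_to_generic[normalize_drug_name(drug_tbl$verbatim_name)])
  exposure <- tibble::tibble(
    caseid = case_id_of(demo, drug_tbl$primaryid),
    drug = generic
  ) |>
    dplyr::filter(!is.na(.data$drug)) |>
    dplyr::distinct()

  # endpoint flags: any reaction PT inside an endpoint's PT group
  pt_to_endpoint <- stats::setNames(
    rep(names(endpoints), lengths(endpoints)),
    unlist(endpoints, use.names = FALSE))
  reac_tbl <- cases$reac[cases$reac$primaryid %in% demo$primaryid, ,
                         drop = FALSE]
  ep <- unname(pt_to_endpoint[tolower(trimws(reac_tbl$pt))])
  events <- tibble::tibble(
    caseid = case_id_of(demo, reac_tbl$primaryid),
    endpoint = ep
  ) |>
    dplyr::filter(!is.na(.data$endpoint)) |>
    dplyr::distinct()

  outc_tbl <- cases$outc[cases$outc$primaryid %in% demo$primaryid, ,
                         drop = FALSE]
  outcome_sets <- split(outc_tbl$outcome_code,
                        factor(case_id_of(demo, outc_tbl$primaryid),
                               levels = demo$caseid))
  cohort_cases <- demo |>
    dplyr::select("caseid", "age_years", "weight_kg", "sex",
                  "reporter_country") |>
    dplyr::mutate(
      severity = unname(severity_category(outcome_sets[.data$caseid])),
      has_outcome = .data$severity != "non-serious"
    )

  structure(list(cases = cohort_cases, exposure = exposure, events = events,
                 n = nrow(cohort_cases), drugs = names(drugs),
                 endpoints = names(endpoints)),
            class = "analysis_cohort")
}

case_id_of <- function(demo, primaryid) {
  demo$caseid[match(primaryid, demo$primaryid)]
}

#' @export
print.analysis_cohort <- function(x, ...) {
  cat(sprintf(
    "<analysis_cohort> %d cases, %d drug exposures, %d endpoint events\n",
    x$n, nrow(x$exposure), nrow(x$events)))
  invisible(x)
}
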