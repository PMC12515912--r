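#' Column schema for a FAERS-style quarterly extract
#'
#' Quarterly ASCII extracts ship one table per file (DEMO, DRUG, REAC, OUTC,
#' INDI), "$"-delimited, one header row.  Column names have drifted across
#' quarters; a schema profile maps the canonical field names used by this
#' package to the column names actually present in the files, so a dialect
#' change is a configuration edit, not a code change.  Unknown extra columns
#' are ignored.
#'
#' @param delim Field delimiter (default `"$"`; set `","` for CSV exports).
#' @param encoding File encoding.  FAERS extracts are not valid UTF-8;
#'   Latin-1 with replacement of undecodable bytes is the safe default.
#' @param demo,drug,reac,outc,indi Named character vectors mapping canonical
#'   field names (the names) to file column names (the values).
#' @return A list with class `faers_schema`.
#' @export
faers_schema <- function(delim = "$",
                         encoding = "latin1",
                         demo = c(primaryid = "primaryid", caseid = "caseid",
                                  event_dt = "event_dt", age = "age",
                                  age_cod = "age_cod", sex = "sex",
                                  wt = "wt", wt_cod = "wt_cod",
                                  reporter_country = "reporter_country",
                                  fda_dt = "fda_dt"),
                         drug = c(primaryid = "primaryid", caseid = "caseid",
                                  drug_seq = "drug_seq", role_cod = "role_cod",
                                  drugname = "drugname"),
                         reac = c(primaryid = "primaryid", caseid = "caseid",
                                  pt = "pt"),
                         outc = c(primaryid = "primaryid", caseid = "caseid",
                                  outc_cod = "outc_cod"),
                         indi = c(primaryid = "primaryid", caseid = "caseid",
                                  indi_pt = "indi_pt")) {
  structure(list(delim = delim, encoding = encoding, demo = demo, drug = drug,
                 reac = reac, outc = outc, indi = indi),
            class = "faers_schema")
}

read_faers_table <- function(path, table, schema) {
  mapping <- schema[[table]]
  raw <- readr::read_delim(
    path,
    delim = schema$delim,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = schema$encoding),
    na = c("", "NA"),
    trim_ws = TRUE,
    progress = FALSE,
    show_col_types = FALSE
  )
  names(raw) <- tolower(names(raw))
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' is missing mandatory column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

# ---- field normalizers ------------------------------------------------------

# age-unit codes and their year multipliers; unknown codes -> missing age
.age_unit_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                     DY = 1 / 365.25, HR = 1 / 8766)

normalize_age_years <- function(age, age_cod) {
  value <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(age_cod %||% NA_character_))
  mult <- unname(.age_unit_years[unit])
  # missing unit code with a plausible value is conventionally years
  mult[is.na(unit) & !is.na(value)] <- 1
  years <- value * mult
  years[!is.na(years) & (years <= 0 | years >= 120)] <- NA_real_
  years
}

.weight_unit_kg <- c(KG = 1, KGS = 1, LBS = 0.45359237, GMS = 0.001)

normalize_weight_kg <- function(wt, wt_cod) {
  value <- suppressWarnings(as.numeric(wt))
  unit <- toupper(trimws(wt_cod %||% NA_character_))
  mult <- unname(.weight_unit_kg[unit])
  mult[is.na(unit) & !is.na(value)] <- 1
  kg <- value * mult
  kg[!is.na(kg) & kg <= 0] <- NA_real_
  kg
}

normalize_sex <- function(sex) {
  s <- toupper(trimws(sex %||% NA_character_))
  dplyr::case_when(s == "M" ~ "male", s == "F" ~ "female", .default = "unknown")
}

parse_faers_date <- function(x) {
  x <- trimws(x %||% NA_character_)
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# ---- quarter bundle ---------------------------------------------------------

new_faers_quarter <- function(quarter, demo, drug, reac, outc, indi,
                              rejects = empty_rejects()) {
  structure(list(quarter = quarter, demo = demo, drug = drug, reac = reac,
                 outc = outc, indi = indi, rejects = rejects),
            class = "faers_quarter")
}

empty_rejects <- function() {
  tibble::tibble(file = character(), line = integer(), reason = character())
}

reject_rows <- function(tbl, bad, file, reason, rejects) {
  if (!any(bad)) return(list(tbl = tbl, rejects = rejects))
  add <- tibble::tibble(file = file, line = which(bad) + 1L, reason = reason)
  list(tbl = tbl[!bad, , drop = FALSE],
       rejects = dplyr::bind_rows(rejects, add))
}

#' Parse one FAERS-style quarter into a typed bundle
#'
#' Reads the five per-quarter tables, renames columns to canonical names via
#' the schema profile, normalizes demographics (age to years, weight to kg,
#' sex and country to closed categories, dates to `Date`), and routes
#' unusable rows to a rejects log instead of failing.  Rows in the DRUG /
#' REAC / OUTC / INDI tables whose report identifier does not appear in DEMO
#' are rejected, so every surviving mention is linkable.
#'
#' @param paths Named list or vector with elements `demo`, `drug`, `reac`,
#'   `outc`, `indi` giving file locations.
#' @param quarter Quarter label, e.g. `"2015Q1"`.
#' @param schema A [faers_schema()].
#' @return A `faers_quarter`: tibbles `demo`, `drug`, `reac`, `outc`,
#'   `indi`, plus a `rejects` log with columns file / line / reason.
#' @export
parse_quarter <- function(paths, quarter, schema = faers_schema()) {
  paths <- as.list(paths)
  needed <- c("demo", "drug", "reac", "outc", "indi")
  if (!all(needed %in% names(paths))) {
    stop("paths must name all five tables: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  missing_files <- !vapply(paths[needed], file.exists, logical(1))
  if (any(missing_files)) {
    stop("input file(s) not found: ",
         paste(unlist(paths[needed][missing_files]), collapse = ", "),
         call. = FALSE)
  }
  rejects <- empty_rejects()

  demo <- read_faers_table(paths$demo, "demo", schema)
  r <- reject_rows(demo, is.na(demo$primaryid) | is.na(demo$caseid),
                   basename(paths$demo), "missing primaryid/caseid", rejects)
  demo <- r$tbl; rejects <- r$rejects
  demo <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    event_date = parse_faers_date(demo$event_dt),
    age_years = normalize_age_years(demo$age, demo$age_cod),
    weight_kg = normalize_weight_kg(demo$wt, demo$wt_cod),
    sex = normalize_sex(demo$sex),
    reporter_country = dplyr::coalesce(
      dplyr::na_if(trimws(demo$reporter_country), ""), "unknown"),
    fda_receipt_date = parse_faers_date(demo$fda_dt)
  )
  known <- demo$primaryid

  link_check <- function(tbl, file) {
    r <- reject_rows(tbl, is.na(tbl$primaryid), file, "missing primaryid",
                     rejects)
    r2 <- reject_rows(r$tbl, !(r$tbl$primaryid %in% known), file,
                      "primaryid not in DEMO", r$rejects)
    rejects <<- r2$rejects
    r2$tbl
  }

  drug <- link_check(read_faers_table(paths$drug, "drug", schema),
                     basename(paths$drug))
  bad_role <- !(toupper(trimws(drug$role_cod)) %in% names(.role_codes))
  r <- reject_rows(drug, bad_role, basename(paths$drug), "unknown role code",
                   rejects)
  drug <- r$tbl; rejects <- r$rejects
  drug <- tibble::tibble(
    primaryid = drug$primaryid,
    drug_seq = suppressWarnings(as.integer(drug$drug_seq)),
    verbatim_name = drug$drugname,
    role_code = toupper(trimws(drug$role_cod))
  )

  reac <- link_check(read_faers_table(paths$reac, "reac", schema),
                     basename(paths$reac))
  bad_pt <- is.na(reac$pt) | !nzchar(trimws(reac$pt))
  r <- reject_rows(reac, bad_pt, basename(paths$reac), "empty reaction PT",
                   rejects)
  reac <- r$tbl; rejects <- r$rejects
  reac <- tibble::tibble(primaryid = reac$primaryid, pt = trimws(reac$pt))
  if (nrow(reac) == 0) {
    warning("quarter ", quarter, ": no reaction rows", call. = FALSE)
  }

  outc <- link_check(read_faers_table(paths$outc, "outc", schema),
                     basename(paths$outc))
  bad_outc <- !(toupper(trimws(outc$outc_cod)) %in% names(.outcome_codes))
  r <- reject_rows(outc, bad_outc, basename(paths$outc),
                   "unknown outcome code", rejects)
  outc <- r$tbl; rejects <- r$rejects
  outc <- tibble::tibble(primaryid = outc$primaryid,
                         outcome_code = toupper(trimws(outc$outc_cod)))

  indi <- link_check(read_faers_table(paths$indi, "indi", schema),
                     basename(paths$indi))
  bad_ipt <- is.na(indi$indi_pt) | !nzchar(trimws(indi$indi_pt))
  r <- reject_rows(indi, bad_ipt, basename(paths$indi), "empty indication PT",
                   rejects)
  indi <- r$tbl; rejects <- r$rejects
  indi <- tibble::tibble(primaryid = indi$primaryid,
                         indi_pt = trimws(indi$indi_pt))

  new_faers_quarter(quarter, demo, drug, reac, outc, indi, rejects)
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat(sprintf(
    "<faers_quarter %s> demo: %d  drug: %d  reac: %d  outc: %d  indi: %d  rejects: %d\n",
    x$quarter, nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$outc),
    nrow(x$indi), nrow(x$rejects)))
  invisible(x)
}

#' Serialize a quarter bundle back to FAERS-layout files
#'
#' Writes the five "$"-delimited tables for one quarter (ages re-expressed in
#' years with unit code `YR`, weights in `KG`, dates as `yyyymmdd`), naming
#' files `DEMO<yy>Q<q>.txt` etc.  Re-parsing the written files reproduces the
#' bundle's normalized records.
#'
#' @param bundle A `faers_quarter`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_quarter <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_quarter"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sub("^[0-9]{2}", "", bundle$quarter)  # "2015Q1" -> "15Q1"
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))
  demo <- tibble::tibble(
    primaryid = bundle$demo$primaryid,
    caseid = bundle$demo$caseid,
    event_dt = fmt_date(bundle$demo$event_date),
    age = ifelse(is.na(bundle$demo$age_years), "",
                 format(bundle$demo$age_years, trim = TRUE, digits = 15)),
    age_cod = ifelse(is.na(bundle$demo$age_years), "", "YR"),
    sex = dplyr::case_when(bundle$demo$sex == "male" ~ "M",
                           bundle$demo$sex == "female" ~ "F",
                           .default = ""),
    wt = ifelse(is.na(bundle$demo$weight_kg), "",
                format(bundle$demo$weight_kg, trim = TRUE, digits = 15)),
    wt_cod = ifelse(is.na(bundle$demo$weight_kg), "", "KG"),
    reporter_country = ifelse(bundle$demo$reporter_country == "unknown", "",
                              bundle$demo$reporter_country),
    fda_dt = fmt_date(bundle$demo$fda_receipt_date)
  )
  drug <- tibble::tibble(
    primaryid = bundle$drug$primaryid,
    caseid = case_of(bundle, bundle$drug$primaryid),
    drug_seq = bundle$drug$drug_seq,
    role_cod = bundle$drug$role_code,
    drugname = bundle$drug$verbatim_name
  )
  reac <- tibble::tibble(primaryid = bundle$reac$primaryid,
                         caseid = case_of(bundle, bundle$reac$primaryid),
                         pt = bundle$reac$pt)
  outc <- tibble::tibble(primaryid = bundle$outc$primaryid,
                         caseid = case_of(bundle, bundle$outc$primaryid),
                         outc_cod = bundle$outc$outcome_code)
  indi <- tibble::tibble(primaryid = bundle$indi$primaryid,
                         caseid = case_of(bundle, bundle$indi$primaryid),
                         indi_pt = bundle$indi$indi_pt)
  tables <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                 INDI = indi)
  paths <- setNames(
    file.path(dir, paste0(names(tables), tag, ".txt")),
    tolower(names(tables)))
  for (i in seq_along(tables)) {
    readr::write_delim(tables[[i]], paths[i], delim = "$", na = "")
  }
  invisible(paths)
}

case_of <- function(bundle, primaryid) {
  bundle$demo$caseid[match(primaryid, bundle$demo$primaryid)]
}

#' Collapse multi-version cases to one report per case
#'
#' Spontaneous-report databases carry several versions of the same case as
#' follow-up information arrives.  For each case identifier the version with
#' the latest agency receipt date is retained; ties are broken by the largest
#' report-version identifier (numeric where possible).  Versions with no
#' receipt date lose to any dated version.  The operation is idempotent.
#'
#' @param bundles A list of `faers_quarter` objects (or a single one, or an
#'   already-deduplicated `faers_cases`, which is returned unchanged in
#'   content).
#' @return A `faers_cases`: `demo` with one winning row per case,
#'   `drug` / `reac` / `outc` / `indi` restricted to winning versions,
#'   `rejects` carried over, and counts `n_cases`, `n_versions_dropped`.
#' @export
deduplicate <- function(bundles) {
  if (inherits(bundles, "faers_cases")) {
    bundles <- list(new_faers_quarter("all", bundles$demo, bundles$drug,
                                      bundles$reac, bundles$outc,
                                      bundles$indi, bundles$rejects))
  }
  if (inherits(bundles, "faers_quarter")) bundles <- list(bundles)
  stopifnot(length(bundles) >= 1,
            all(vapply(bundles, inherits, logical(1), "faers_quarter")))
  pull_all <- function(what) {
    dplyr::bind_rows(lapply(bundles, `[[`, what))
  }
  demo <- pull_all("demo")
  winners <- demo |>
    dplyr::mutate(.pid_num = suppressWarnings(as.numeric(.data$primaryid))) |>
    dplyr::arrange(.data$caseid, dplyr::desc(is.na(.data$fda_receipt_date)),
                   .data$fda_receipt_date, .data$.pid_num, .data$primaryid) |>
    dplyr::group_by(.data$caseid) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select(-".pid_num")
  keep <- winners$primaryid
  filt <- function(tbl) tbl[tbl$primaryid %in% keep, , drop = FALSE]
  structure(list(
    demo = winners,
    drug = filt(pull_all("drug")),
    reac = filt(pull_all("reac")),
    outc = filt(pull_all("outc")),
    indi = filt(pull_all("indi")),
    rejects = pull_all("rejects"),
    n_cases = nrow(winners),
    n_versions_dropped = nrow(demo) - nrow(winners)
  ), class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d cases (%d duplicate versions dropped)\n",
              x$n_cases, x$n_versions_dropped))
  invisible(x)
}
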