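# Woolf odds ratio for a 2x2 (x1, y1) vs (x2, y2) contrast, with the
# Haldane-Anscombe +0.5 applied to all four cells when any is zero
woolf_or <- function(x1, y1, x2, y2) {
  x1 <- as.numeric(x1); y1 <- as.numeric(y1)
  x2 <- as.numeric(x2); y2 <- as.numeric(y2)
  corrected <- x1 == 0 | y1 == 0 | x2 == 0 | y2 == 0
  h <- ifelse(corrected, 0.5, 0)
  x1 <- x1 + h; y1 <- y1 + h; x2 <- x2 + h; y2 <- y2 + h
  est <- (x1 * y2) / (x2 * y1)
  se <- sqrt(1 / x1 + 1 / y1 + 1 / x2 + 1 / y2)
  tibble::tibble(or_value = est,
                 ci_low = exp(log(est) - 1.96 * se),
                 ci_high = exp(log(est) + 1.96 * se),
                 corrected = corrected)
}

#' Between-drug constituent-ratio odds ratio for one endpoint
#'
#' Contrasts the event-versus-non-event composition of two drugs' report
#' sets: OR = (a_i c_j) / (a_j c_i) from the drugs' (a, c) contingency cells,
#' with a Woolf 95% CI on the log scale and the Haldane-Anscombe +0.5
#' correction to all four cells when any is zero.
#'
#' @param tables Contingency tables (tibble with drug, endpoint, a, c).
#' @param endpoint Endpoint code.
#' @param drug_i,drug_j The two drugs; the OR is reported for `drug_i`
#'   relative to `drug_j`.
#' @return One-row tibble: endpoint, drug_i, drug_j, kind, or_value, ci_low,
#'   ci_high, corrected, and the cells used.
#' @export
constituent_ratio_or <- function(tables, endpoint, drug_i, drug_j) {
  cells <- function(dr) {
    row <- tables[tables$drug == dr & tables$endpoint == endpoint, ]
    if (nrow(row) != 1) {
      stop("no contingency table for ", dr, " x ", endpoint, call. = FALSE)
    }
    row
  }
  ri <- cells(drug_i); rj <- cells(drug_j)
  dplyr::bind_cols(
    tibble::tibble(endpoint = endpoint, drug_i = drug_i, drug_j = drug_j,
                   kind = "constituent-ratio"),
    woolf_or(ri$a, ri$c, rj$a, rj$c),
    tibble::tibble(x_i = ri$a, y_i = ri$c, x_j = rj$a, y_j = rj$c)
  )
}

#' Between-drug severe-outcome odds ratio for one endpoint
#'
#' Among each drug's endpoint-positive reports with a known outcome, severe
#' (death or life-threatening) versus non-severe serious outcomes are
#' contrasted across the two drugs.  Reports with no outcome record are
#' excluded from the denominators.  Woolf CI; Haldane-Anscombe correction on
#' zero cells; not estimable when a drug has no known-outcome endpoint
#' reports.
#'
#' @param cohort An `analysis_cohort`.
#' @param endpoint Endpoint code.
#' @param drug_i,drug_j The two drugs (OR for `drug_i` relative to `drug_j`).
#' @return One-row tibble shaped like [constituent_ratio_or()].
#' @export
severity_or <- function(cohort, endpoint, drug_i, drug_j) {
  stopifnot(inherits(cohort, "analysis_cohort"))
  ev_cases <- cohort$events$caseid[cohort$events$endpoint == endpoint]
  counts <- function(dr) {
    ex <- cohort$exposure$caseid[cohort$exposure$drug == dr]
    ids <- intersect(ex, ev_cases)
    sub <- cohort$cases[cohort$cases$caseid %in% ids &
                          cohort$cases$has_outcome, , drop = FALSE]
    c(severe = sum(sub$severity == "severe"),
      nonsevere = sum(sub$severity != "severe"))
  }
  ci <- counts(drug_i); cj <- counts(drug_j)
  base <- tibble::tibble(endpoint = endpoint, drug_i = drug_i,
                         drug_j = drug_j, kind = "severity")
  if (sum(ci) == 0 || sum(cj) == 0) {
    return(dplyr::bind_cols(base, tibble::tibble(
      or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      corrected = NA,
      x_i = ci[["severe"]], y_i = ci[["nonsevere"]],
      x_j = cj[["severe"]], y_j = cj[["nonsevere"]])))
  }
  dplyr::bind_cols(
    base,
    woolf_or(ci[["severe"]], ci[["nonsevere"]],
             cj[["severe"]], cj[["nonsevere"]]),
    tibble::tibble(x_i = ci[["severe"]], y_i = ci[["nonsevere"]],
                   x_j = cj[["severe"]], y_j = cj[["nonsevere"]])
  )
}

#' All pairwise between-drug odds ratios for one endpoint
#'
#' Builds the full drugs-by-drugs matrix of pairwise odds ratios of the
#' requested kind: unit diagonal, reciprocal off-diagonal entries (with
#' reciprocal interval bounds), and a significance mark where the 95% CI
#' excludes 1.
#'
#' @param x Contingency tables (for `kind = "constituent-ratio"`) or an
#'   `analysis_cohort` (for `kind = "severity"`).
#' @param endpoint Endpoint code.
#' @param drugs Drugs to compare (default: all in `x`).
#' @param kind `"constituent-ratio"` or `"severity"`.
#' @return Long tibble over all ordered drug pairs with `or_value`, `ci_low`,
#'   `ci_high`, `corrected`, `significant`.
#' @export
all_pairs <- function(x, endpoint, drugs = NULL,
                      kind = c("constituent-ratio", "severity")) {
  kind <- match.arg(kind)
  if (is.null(drugs)) {
    drugs <- if (inherits(x, "analysis_cohort")) x$drugs else unique(x$drug)
  }
  if (length(drugs) < 2) stop("need at least two drugs", call. = FALSE)
  one <- function(di, dj) {
    if (di == dj) {
      return(tibble::tibble(endpoint = endpoint, drug_i = di, drug_j = dj,
                            kind = kind, or_value = 1, ci_low = 1,
                            ci_high = 1, corrected = FALSE,
                            x_i = NA_real_, y_i = NA_real_,
                            x_j = NA_real_, y_j = NA_real_))
    }
    if (kind == "constituent-ratio") constituent_ratio_or(x, endpoint, di, dj)
    else severity_or(x, endpoint, di, dj)
  }
  grid <- tidyr::expand_grid(drug_i = drugs, drug_j = drugs)
  purrr::pmap(grid, function(drug_i, drug_j) one(drug_i, drug_j)) |>
    dplyr::bind_rows() |>
    dplyr::mutate(significant = !is.na(.data$ci_low) &
                    (.data$ci_low > 1 | .data$ci_high < 1))
}

#' Reshape pairwise results to a square odds-ratio matrix
#'
#' @param pairs Output of [all_pairs()].
#' @return A numeric matrix (rows = drug_i, columns = drug_j).
#' @export
or_matrix <- function(pairs) {
  wide <- pairs |>
    dplyr::select("drug_i", "drug_j", "or_value") |>
    tidyr::pivot_wider(names_from = "drug_j", values_from = "or_value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$drug_i
  m
}
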