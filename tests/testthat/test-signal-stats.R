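test_that("degenerate and symmetric tables behave as defined", {
  # symmetric table: all ratio metrics at their null value
  expect_equal(prr(10, 10, 90, 90)$prr, 1)
  expect_equal(ror(10, 10, 90, 90)$ror, 1)
  expect_equal(chi2_yates(10, 10, 90, 90), 0)
  # a equals its expectation: IC is exactly zero
  expect_equal(bcpnn_ic(10, 90, 90, 810)$ic, 0)
  # zero cells: PRR/ROR not estimable, chi2 NA on a zero margin
  expect_true(is.na(prr(0, 10, 90, 90)$prr))
  expect_true(is.na(ror(5, 0, 90, 90)$ror))
  expect_true(is.na(chi2_yates(0, 0, 90, 90)))
  # shrinkage keeps IC finite even on an all-but-empty table
  expect_true(is.finite(bcpnn_ic(0, 0, 0, 10)$ic))
  expect_error(disproportionality(tibble::tibble(a = -1, b = 1, c = 1, d = 1)),
               "non-negative")
})

test_that("Yates chi-square agrees with stats::chisq.test and is conservative", {
  withr::local_seed(42)
  for (i in 1:50) {
    cells <- rpois(4, lambda = sample(c(3, 20, 200), 4, replace = TRUE)) + 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(chi2_yates(a, b, c, d), unname(ref$statistic),
                 tolerance = 1e-10)
    raw <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_lte(chi2_yates(a, b, c, d), unname(raw$statistic) + 1e-12)
  }
})

test_that("algebraic invariants hold across random tables", {
  withr::local_seed(7)
  for (i in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    c <- sample(1:500, 1); d <- sample(1:500, 1)
    r <- ror(a, b, c, d)$ror
    p <- prr(a, b, c, d)$prr
    # ROR and PRR sit on the same side of 1, with ROR the more extreme
    expect_equal(sign(r - p), sign(r - 1) * (r != p))
    ic <- bcpnn_ic(a, b, c, d)
    expect_lt(ic$ic025, ic$ic)
    expect_gt(ic$ic975, ic$ic)
  }
})

test_that("contingency tables preserve cohort margins", {
  cfg <- simulation_config(seed = 3, n_reports = 4000,
                           duplicate_fraction = 0.05, quarters = "2016Q1")
  cohort <- build_cohort(deduplicate(generate_reports(cfg)),
                         read_drug_dictionary(), read_endpoint_dictionary())
  tab <- contingency_tables(cohort)
  expect_equal(nrow(tab), 32)
  # every row sums to the cohort grand total
  expect_true(all(tab$a + tab$b + tab$c + tab$d == cohort$n))
  # for a fixed endpoint the event margin is the same for every drug
  margins <- tapply(tab$a + tab$b, tab$endpoint, function(x) length(unique(x)))
  expect_true(all(margins == 1))
  # and cohort ordering does not matter
  cohort2 <- build_cohort(deduplicate(rev(generate_reports(cfg))),
                          read_drug_dictionary(), read_endpoint_dictionary())
  expect_equal(cohort2$n, cohort$n)
  tab2 <- contingency_tables(cohort2)
  expect_equal(dplyr::arrange(tab2, drug, endpoint),
               dplyr::arrange(tab, drug, endpoint))
})

test_that("contingency cells match hand counts on a known micro-cohort", {
  q <- fixture_quarter()
  cohort <- build_cohort(deduplicate(list(q)), read_drug_dictionary(),
                         read_endpoint_dictionary())
  tab <- contingency_tables(cohort)
  qt_cital <- tab[tab$drug == "citalopram" &
                    tab$endpoint == "qt_prolongation_tdp", ]
  # 3 cases: citalopram+QT once; QT margin 1; citalopram margin 1
  expect_equal(unlist(qt_cital[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 0, 0, 2))
  va_quet <- tab[tab$drug == "quetiapine" &
                   tab$endpoint == "ventricular_arrhythmia", ]
  expect_equal(unlist(va_quet[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 0, 0, 2))
  # a drug with no exposed cases yields an a = c = 0 row
  va_dulox <- tab[tab$drug == "duloxetine" &
                    tab$endpoint == "ventricular_arrhythmia", ]
  expect_equal(va_dulox$a + va_dulox$c, 0)
})

test_that("signal flags combine thresholds as published criteria", {
  t2 <- disproportionality(table2_counts())
  pick <- function(drug, ep) t2[t2$drug == drug & t2$endpoint == ep, ]
  # strong signal on all three metrics
  r <- pick("citalopram", "qt_prolongation_tdp")
  expect_true(r$prr_signal && r$ror_signal && r$ic_signal)
  # PRR below 2 fails the Evans criterion while ROR and IC still flag
  r <- pick("escitalopram", "qt_prolongation_tdp")
  expect_false(r$prr_signal)
  expect_true(r$ror_signal && r$ic_signal)
  # credibility bound straddling zero de-flags IC while ROR flags
  r <- pick("escitalopram", "atrial_fibrillation")
  expect_false(r$ic_signal)
  expect_true(r$ror_signal)
  # small-count guard: a below 3 never flags PRR/ROR
  small <- disproportionality(tibble::tibble(a = 2, b = 1, c = 10, d = 1000))
  expect_false(small$prr_signal || small$ror_signal)
})

test_that("the signal matrix mirrors the flag pattern", {
  t2 <- disproportionality(table2_counts())
  m <- signal_matrix(t2, which = "ror_signal")
  expect_equal(dim(m), c(8, 5))
  expect_equal(m$qt_prolongation_tdp[m$drug == "citalopram"], "signal")
  expect_equal(m$heart_block[m$drug == "duloxetine"], "no-signal")
})
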