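test_that("drug name normalization strips dose and salt decorations", {
  expect_equal(normalize_drug_name("CITALOPRAM HYDROBROMIDE 20MG"),
               "citalopram")
  expect_equal(normalize_drug_name("Escitalopram"), "escitalopram")
  expect_equal(normalize_drug_name("  QUETIAPINE FUMARATE "), "quetiapine")
  expect_equal(normalize_drug_name("VENLAFAXINE HCL 37.5 MG"), "venlafaxine")
  # idempotence over the shipped synonym lists
  syn <- unlist(yaml::read_yaml(
    system.file("extdata", "drug_dictionary.yaml", package = "pvsignal")))
  once <- normalize_drug_name(syn)
  expect_equal(normalize_drug_name(once), once)
})

test_that("dictionaries enforce non-emptiness and disjointness on load", {
  expect_error(drug_dictionary(list()), "empty")
  expect_error(
    drug_dictionary(list(citalopram = "celexa", escitalopram = "celexa")),
    "overlap")
  expect_error(endpoint_dictionary(list(qt = character())), "empty")
  expect_error(
    endpoint_dictionary(list(qt = "Torsade de pointes",
                             va = c("Ventricular tachycardia",
                                    "Torsade de pointes"))),
    "overlap")
  # shipped defaults load cleanly
  expect_length(read_drug_dictionary(), 8)
  expect_length(read_endpoint_dictionary(), 4)
})

test_that("severity is severe for fatal/life-threatening, serious otherwise", {
  expect_equal(severity_category(c("DE", "HO")), "severe")
  expect_equal(severity_category("LT"), "severe")
  expect_equal(severity_category("HO"), "serious-non-severe")
  expect_equal(severity_category(character()), "non-serious")
  expect_equal(severity_category(list(c("DS", "OT"), "DE", character())),
               c("serious-non-severe", "severe", "non-serious"))
})

test_that("cohort construction filters on indication and maps drugs/endpoints", {
  q <- fixture_quarter()
  cases <- deduplicate(list(q))
  cohort <- build_cohort(cases, read_drug_dictionary(),
                         read_endpoint_dictionary())
  expect_equal(cohort$n, 3)
  # case 100: citalopram suspect (concomitant aspirin ignored), two endpoints
  expect_setequal(cohort$exposure$drug[cohort$exposure$caseid == "100"],
                  "citalopram")
  expect_setequal(cohort$events$endpoint[cohort$events$caseid == "100"],
                  c("qt_prolongation_tdp", "atrial_fibrillation"))
  # case 200: sertraline secondary suspect counts; no endpoint PT
  expect_equal(cohort$exposure$drug[cohort$exposure$caseid == "200"],
               "sertraline")
  expect_false("200" %in% cohort$events$caseid)
  # severity flows from outcome codes
  sev <- cohort$cases$severity[match(c("100", "200", "300"),
                                     cohort$cases$caseid)]
  expect_equal(sev, c("severe", "serious-non-severe", "severe"))

  # a non-depression indication excludes the case
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir, demo = demo_fixture_rows, drug = drug_fixture_rows,
    reac = reac_fixture_rows, outc = outc_fixture_rows,
    indi = c("1001$100$Hypertension", "2001$200$Major depression",
             "3001$300$Depression"))
  cohort2 <- build_cohort(deduplicate(list(parse_quarter(paths, "2023Q1"))),
                          read_drug_dictionary(), read_endpoint_dictionary())
  expect_equal(cohort2$n, 2)
  expect_false("100" %in% cohort2$cases$caseid)
})

test_that("concomitant-only mentions of a study drug are not exposure", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir,
    demo = "5001$500$$45$YR$F$$$US$20230201",
    drug = "5001$500$1$C$CITALOPRAM",
    reac = "5001$500$Nausea",
    outc = character(),
    indi = "5001$500$Depression")
  cohort <- build_cohort(deduplicate(list(parse_quarter(paths, "2023Q1"))),
                         read_drug_dictionary(), read_endpoint_dictionary())
  expect_equal(nrow(cohort$exposure), 0)
})

test_that("endpoint flags are monotone in the reaction PT set", {
  base_reac <- "1001$100$Electrocardiogram QT prolonged"
  build <- function(reac_rows) {
    dir <- withr::local_tempdir()
    paths <- write_faers_fixture(
      dir, demo = demo_fixture_rows[1], drug = drug_fixture_rows[1],
      reac = reac_rows, outc = character(), indi = indi_fixture_rows[1])
    build_cohort(deduplicate(list(parse_quarter(paths, "2023Q1"))),
                 read_drug_dictionary(), read_endpoint_dictionary())
  }
  before <- build(base_reac)$events
  after <- build(c(base_reac, "1001$100$Atrial flutter",
                   "1001$100$Dizziness"))$events
  expect_true(all(paste(before$caseid, before$endpoint) %in%
                    paste(after$caseid, after$endpoint)))
  expect_setequal(after$endpoint,
                  c("qt_prolongation_tdp", "atrial_fibrillation"))
})

test_that("planted exposures and events are recovered exactly", {
  cfg <- simulation_config(seed = 13, n_reports = 3000,
                           duplicate_fraction = 0.1, quarters = "2017Q2")
  bundles <- generate_reports(cfg)
  truth <- attr(bundles, "ground_truth")
  cohort <- build_cohort(deduplicate(bundles), read_drug_dictionary(),
                         read_endpoint_dictionary())
  dep <- truth[truth$depression, ]
  expect_setequal(cohort$cases$caseid, dep$caseid)
  # exposure recovered for every depression case on a study drug
  expected <- dep[dep$drug != "other", c("caseid", "drug")]
  got <- cohort$exposure[order(cohort$exposure$caseid), ]
  expect_equal(got$caseid, expected$caseid[order(expected$caseid)])
  expect_equal(got$drug, expected$drug[order(expected$caseid)])
  # endpoint events recovered exactly
  for (ep in names(default_endpoint_rates())) {
    expect_setequal(cohort$events$caseid[cohort$events$endpoint == ep],
                    dep$caseid[dep[[ep]]])
  }
})
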