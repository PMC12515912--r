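test_that("parser normalizes ages, weights, sex and dates", {
  q <- suppressWarnings(fixture_quarter())
  expect_s3_class(q$demo, "tbl_df")
  expect_equal(nrow(q$demo), 3)
  # 60 YR, 6 decades, 600 months all normalize to years
  expect_equal(q$demo$age_years, c(60, 60, 50))
  # 154 lbs -> ~69.85 kg; missing weight stays missing
  expect_equal(q$demo$weight_kg, c(68, 154 * 0.45359237, NA), tolerance = 1e-9)
  expect_equal(q$demo$sex, c("female", "male", "unknown"))
  expect_equal(q$demo$reporter_country, c("US", "GB", "unknown"))
  expect_equal(q$demo$fda_receipt_date,
               as.Date(c("2023-01-10", "2023-01-11", "2023-01-12")))
  expect_true(is.na(q$demo$event_date[3]))
})

test_that("unusable rows are routed to the rejects log with reasons", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir,
    demo = c(demo_fixture_rows, "$999$$$$$$$$20230101"),   # no primaryid
    drug = c(drug_fixture_rows,
             "1001$100$3$XX$MYSTERYDRUG",                   # bad role code
             "7777$777$1$PS$ORPHANDRUG"),                   # pid not in DEMO
    reac = c(reac_fixture_rows, "1001$100$   "),            # blank PT
    outc = c(outc_fixture_rows, "1001$100$ZZ"),             # bad outcome code
    indi = indi_fixture_rows)
  q <- parse_quarter(paths, quarter = "2023Q1")
  expect_equal(nrow(q$demo), 3)
  expect_equal(nrow(q$drug), 4)
  expect_equal(nrow(q$reac), 4)
  expect_equal(nrow(q$outc), 4)
  expect_setequal(
    q$rejects$reason,
    c("missing primaryid/caseid", "unknown role code", "primaryid not in DEMO",
      "empty reaction PT", "unknown outcome code"))
  expect_true(all(q$rejects$line >= 2))  # line 1 is the header
})

test_that("an empty reaction table parses with a warning", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, demo = demo_fixture_rows,
                               drug = drug_fixture_rows,
                               outc = outc_fixture_rows,
                               indi = indi_fixture_rows)
  expect_warning(q <- parse_quarter(paths, quarter = "2023Q1"),
                 "no reaction rows")
  expect_equal(nrow(q$reac), 0)
})

test_that("a missing mandatory column fails naming the column", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, demo = demo_fixture_rows,
                               drug = drug_fixture_rows,
                               reac = reac_fixture_rows,
                               outc = outc_fixture_rows,
                               indi = indi_fixture_rows)
  writeLines(c("primaryid$caseid$pt_wrong", "1001$100$Nausea"), paths$reac)
  expect_error(parse_quarter(paths, quarter = "2023Q1"), "pt")
})

test_that("writing a quarter and re-parsing reproduces the records", {
  cfg <- simulation_config(seed = 11, n_reports = 400,
                           quarters = c("2019Q3", "2019Q4"),
                           duplicate_fraction = 0.1)
  bundles <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  paths <- write_quarter(bundles[[1]], dir)
  reparsed <- parse_quarter(paths, quarter = bundles[[1]]$quarter)
  for (tbl in c("demo", "drug", "reac", "outc", "indi")) {
    expect_equal(as.data.frame(reparsed[[tbl]]),
                 as.data.frame(bundles[[1]][[tbl]]),
                 tolerance = 1e-12, info = tbl)
  }
  expect_equal(nrow(reparsed$rejects), 0)
})

test_that("deduplication keeps the latest receipt date, then the largest id", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir,
    demo = c("1231$123$$50$YR$F$$$US$20200110",
             "1232$123$$50$YR$F$$$US$20200301",  # later date wins
             "4561$456$$40$YR$M$$$US$20200401",
             "4562$456$$40$YR$M$$$US$20200401",  # tie: larger primaryid wins
             "7891$789$$30$YR$F$$$US$20200501"),
    drug = c("1231$123$1$PS$CITALOPRAM", "1232$123$1$PS$CITALOPRAM",
             "4561$456$1$PS$SERTRALINE", "4562$456$1$PS$SERTRALINE",
             "7891$789$1$PS$FLUOXETINE"),
    reac = c("1231$123$Nausea", "1232$123$Nausea", "4561$456$Headache",
             "4562$456$Headache", "7891$789$Fatigue"),
    outc = "1232$123$HO",
    indi = c("1232$123$Depression", "4562$456$Depression",
             "7891$789$Depression"))
  q <- parse_quarter(paths, quarter = "2020Q1")
  cases <- deduplicate(list(q))
  expect_equal(cases$n_cases, 3)
  expect_equal(cases$n_versions_dropped, 2)
  winners <- cases$demo$primaryid[match(c("123", "456", "789"),
                                        cases$demo$caseid)]
  expect_equal(winners, c("1232", "4562", "7891"))
  # attached tables restricted to winning versions
  expect_setequal(cases$drug$primaryid, winners)

  # idempotence
  again <- deduplicate(cases)
  expect_equal(again$demo, cases$demo)
  expect_equal(again$n_versions_dropped, 0)

  # case count never exceeds total demo rows
  expect_lte(cases$n_cases, nrow(q$demo))
})
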