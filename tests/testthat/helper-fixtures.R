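# write a minimal FAERS-layout quarter to disk from row vectors and return
# the path set parse_quarter() expects
write_faers_fixture <- function(dir,
                                demo = character(),
                                drug = character(),
                                reac = character(),
                                outc = character(),
                                indi = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  headers <- list(
    demo = "primaryid$caseid$event_dt$age$age_cod$sex$wt$wt_cod$reporter_country$fda_dt",
    drug = "primaryid$caseid$drug_seq$role_cod$drugname",
    reac = "primaryid$caseid$pt",
    outc = "primaryid$caseid$outc_cod",
    indi = "primaryid$caseid$indi_pt"
  )
  rows <- list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi)
  paths <- lapply(names(headers), function(tbl) {
    p <- file.path(dir, paste0(toupper(tbl), "23Q1.txt"))
    writeLines(c(headers[[tbl]], rows[[tbl]]), p)
    p
  })
  stats::setNames(paths, names(headers))
}

# a small, fully known quarter: three depression cases on study drugs
demo_fixture_rows <- c(
  "1001$100$20230105$60$YR$F$68$KG$US$20230110",
  "2001$200$20230106$6$DEC$M$154$LBS$GB$20230111",
  "3001$300$$600$MON$$$$$20230112"
)
drug_fixture_rows <- c(
  "1001$100$1$PS$CITALOPRAM HYDROBROMIDE 20MG",
  "1001$100$2$C$ASPIRIN",
  "2001$200$1$SS$Sertraline",
  "3001$300$1$PS$  QUETIAPINE FUMARATE "
)
reac_fixture_rows <- c(
  "1001$100$Electrocardiogram QT prolonged",
  "1001$100$Atrial fibrillation",
  "2001$200$Nausea",
  "3001$300$Ventricular tachycardia"
)
outc_fixture_rows <- c(
  "1001$100$DE",
  "1001$100$HO",
  "2001$200$HO",
  "3001$300$LT"
)
indi_fixture_rows <- c(
  "1001$100$Depression",
  "2001$200$Major depression",
  "3001$300$Depression"
)

fixture_quarter <- function(dir = withr::local_tempdir()) {
  parse_quarter(
    write_faers_fixture(dir,
                        demo = demo_fixture_rows,
                        drug = drug_fixture_rows,
                        reac = reac_fixture_rows,
                        outc = outc_fixture_rows,
                        indi = indi_fixture_rows),
    quarter = "2023Q1")
}

# printed reference values shipped alongside the tests
table2_printed <- function() {
  readr::read_csv(test_path("table2_printed_stats.csv"),
                  col_types = readr::cols(), progress = FALSE)
}

constituent_printed <- function() {
  readr::read_csv(test_path("constituent_printed.csv"),
                  col_types = readr::cols(), progress = FALSE)
}
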