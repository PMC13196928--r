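test_that("fields are selected by header name and data lines map to records", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$caseversion$fda_dt",
               "1001$10$1$20190101",
               "1002$11$2$20200315"), f)
  demo <- read_faers_table(f, "DEMO")
  expect_equal(nrow(demo), 2L)
  expect_equal(demo$caseid, c("10", "11"))
  expect_equal(demo$caseversion, c(1L, 2L))

  # header order must not matter
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("role_cod$drugname$drug_seq$primaryid",
               "PS$SPIRIVA$1$101"), g)
  drug <- read_faers_table(g, "DRUG")
  expect_equal(drug$primaryid, "101")
  expect_equal(drug$drugname, "SPIRIVA")
  expect_equal(drug$role_cod, "PS")
})

test_that("schema and file errors are fatal; malformed lines are skipped with numbers", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseversion$fda_dt", "1$1$20190101"), f)
  expect_error(read_faers_table(f, "DEMO"), "caseid",
               class = "pvsignal_schema_error")
  expect_error(read_faers_table(file.path(tempdir(), "nope.txt"), "DEMO"),
               class = "pvsignal_ingest_error")

  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$pt",
               "101$Dyspnoea",
               "only-one-field",        # wrong field count -> skipped
               "$Cough",                # empty primaryid -> skipped
               "102$Cough"), g)
  reac <- read_faers_table(g, "REAC")
  expect_equal(nrow(reac), 2L)
  log <- attr(reac, "ingest_log")
  expect_equal(log$n_skipped, 2L)
  expect_equal(sort(log$skipped_lines[[1]]), c(3L, 4L))
})

test_that("merging quarters is additive and keeps duplicate primaryids", {
  d1 <- tibble::tibble(primaryid = as.character(1:10), caseid = as.character(1:10),
                       caseversion = 1L, fda_dt = "20190101")
  d2 <- tibble::tibble(primaryid = as.character(c(1, 11:24)),
                       caseid = as.character(c(1, 11:24)),
                       caseversion = 1L, fda_dt = "20190401")
  merged <- merge_quarters(list(d1, d2))
  expect_equal(nrow(merged), 25L)
  expect_equal(sum(merged$primaryid == "1"), 2L)  # dedup is a separate stage
  expect_equal(nrow(merge_quarters(list())), 0L)
})

test_that("deduplication keeps max version, then latest date, then greatest primaryid", {
  demo <- tibble::tibble(
    caseid = c("7", "7", "8", "8", "9"),
    primaryid = c("71", "72", "81", "82", "91"),
    caseversion = c(1L, 2L, 3L, 3L, 1L),
    fda_dt = c("20190101", "20190101", "20190101", "20200101", "20180101")
  )
  kept <- deduplicate_cases(demo)
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$primaryid[kept$caseid == "7"], "72")  # max caseversion
  expect_equal(kept$primaryid[kept$caseid == "8"], "82")  # later fda_dt
  expect_equal(kept$primaryid[kept$caseid == "9"], "91")  # singleton kept

  tie <- tibble::tibble(caseid = "1", primaryid = c("19", "12"),
                        caseversion = 2L, fda_dt = "20200101")
  expect_equal(deduplicate_cases(tie)$primaryid, "19")  # greatest primaryid
})

test_that("dedup is idempotent, order-invariant, and conserves cases", {
  set.seed(101)
  for (rep in 1:5) {
    demo <- random_demo(40)
    kept <- deduplicate_cases(demo)
    expect_equal(nrow(kept), 40L)  # one CaseReport per caseid
    shuffled <- demo[sample.int(nrow(demo)), ]
    expect_equal(deduplicate_cases(shuffled), kept, ignore_attr = TRUE)
    expect_equal(deduplicate_cases(kept), kept, ignore_attr = TRUE)
  }
})

test_that("records without caseid are retained individually and logged", {
  demo <- tibble::tibble(
    caseid = c("1", NA, NA),
    primaryid = c("11", "90", "91"),
    caseversion = 1L, fda_dt = "20190101"
  )
  kept <- deduplicate_cases(demo)
  expect_equal(nrow(kept), 3L)
  expect_equal(attr(kept, "n_missing_caseid"), 2L)
})

test_that("assembled cases have set semantics and exclude superseded versions", {
  cases <- make_cases(
    drug_sets = list(c("SPIRIVA", "spiriva"), "ENTRESTO"),
    reac_sets = list(c("Dyspnoea", "Cough"), "Dyspnoea")
  )
  expect_s3_class(cases, "faers_cases")
  expect_equal(lengths(cases$drugs), c(1L, 1L))     # duplicate mention collapsed
  expect_equal(lengths(cases$reactions), c(2L, 1L))
  expect_equal(cases$drugs[[1]], "SPIRIVA")

  # a drug row pointing at a superseded primaryid is dropped and counted
  dedup <- tibble::tibble(caseid = "7", primaryid = "72", caseversion = 2L,
                          fda_dt = "20190101")
  drug <- tibble::tibble(primaryid = c("71", "72"), drugname = c("OLD", "NEW"),
                         role_cod = "PS")
  reac <- tibble::tibble(primaryid = "72", pt = "Cough")
  out <- assemble_cases(dedup, drug, reac)
  expect_equal(out$drugs[[1]], "NEW")
  expect_equal(attr(out, "assemble_log")$n_drug_dropped, 1L)
})

test_that("the default role filter counts suspect drugs only", {
  dedup <- tibble::tibble(caseid = c("1", "2"), primaryid = c("1", "2"),
                          caseversion = 1L, fda_dt = "20190101")
  drug <- tibble::tibble(primaryid = c("1", "2"), drugname = "X",
                         role_cod = c("PS", "C"))
  reac <- tibble::tibble(primaryid = c("1", "2"), pt = "Cough")
  suspect <- assemble_cases(dedup, drug, reac)
  expect_equal(lengths(suspect$drugs), c(1L, 0L))
  all_roles <- assemble_cases(dedup, drug, reac, roles = c("PS", "SS", "C", "I"))
  expect_equal(lengths(all_roles$drugs), c(1L, 1L))
})
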