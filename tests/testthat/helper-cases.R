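# Builders for tiny in-code fixtures.

# A faers_cases tibble from per-case drug/reaction sets, via the real assembly path.
make_cases <- function(drug_sets, reac_sets, synonyms = NULL, term_map = NULL,
                       roles = c("PS", "SS")) {
  n <- length(drug_sets)
  stopifnot(length(reac_sets) == n)
  pid <- as.character(seq_len(n))
  dedup <- tibble::tibble(caseid = pid, primaryid = pid, caseversion = 1L,
                          fda_dt = "20200101")
  drug <- tibble::tibble(
    primaryid = rep(pid, lengths(drug_sets)),
    drugname = unlist(drug_sets, use.names = FALSE) %||% character(),
    role_cod = "PS"
  )
  reac <- tibble::tibble(
    primaryid = rep(pid, lengths(reac_sets)),
    pt = unlist(reac_sets, use.names = FALSE) %||% character()
  )
  assemble_cases(dedup, drug, reac, synonyms = synonyms, term_map = term_map,
                 roles = roles)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write a tiny hand-rolled quarterly file set; returns the directory.
write_mini_quarter <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c(
    "primaryid$caseid$caseversion$fda_dt",
    "101$1$1$20190101",
    "201$2$1$20190215",
    "301$3$1$20190302"
  ), file.path(dir, "DEMO19Q1.txt"))
  writeLines(c(
    "primaryid$drug_seq$drugname$role_cod",
    "101$1$SPIRIVA$PS",
    "101$2$spiriva$SS",
    "201$1$ENTRESTO$PS",
    "301$1$ENTRESTO$C"
  ), file.path(dir, "DRUG19Q1.txt"))
  writeLines(c(
    "primaryid$pt",
    "101$Dyspnoea",
    "101$Cough",
    "201$Dyspnoea",
    "301$Cough"
  ), file.path(dir, "REAC19Q1.txt"))
  dir
}

# Random DEMO table with versioned cases, for dedup property tests.
random_demo <- function(n_cases, max_versions = 3) {
  rows <- lapply(seq_len(n_cases), function(i) {
    k <- sample.int(max_versions, 1L)
    tibble::tibble(
      caseid = as.character(i),
      caseversion = sample(seq_len(k)),  # shuffled so order carries no signal
      primaryid = paste0(i, "-", sample(seq_len(k))),
      fda_dt = format(as.Date("2019-01-01") + sample.int(1000, k), "%Y%m%d")
    )
  })
  dplyr::bind_rows(rows)
}
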