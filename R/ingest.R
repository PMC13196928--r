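# Reading, merging and deduplicating FAERS-dialect quarterly ASCII extracts.
#
# The quarterly files (DEMOyyQq.txt, DRUGyyQq.txt, REACyyQq.txt) are "$"-delimited
# with a header row and no quoting. A safety report (a "case", keyed by CASEID) can
# appear several times across quarters as successive versions, each with its own
# PRIMARYID; analyses must count each case exactly once, so ingestion ends with a
# case-level deduplication that keeps the latest version.

faers_schemas <- list(
  DEMO = c("primaryid", "caseid", "caseversion", "fda_dt"),
  DRUG = c("primaryid", "drugname", "role_cod"),
  REAC = c("primaryid", "pt")
)

#' Read one FAERS-dialect quarterly ASCII file
#'
#' Parses a "$"-delimited FAERS quarterly extract (no quoting, header row). Fields
#' are selected by header name, case-insensitively, never by position. Data lines
#' whose field count does not match the header, or whose PRIMARYID (or, for DRUG/REAC,
#' drug name / reaction term) is empty, are skipped and counted in the ingest log
#' rather than aborting the read. Invalid bytes are replaced so imperfect encodings
#' do not stop ingestion.
#'
#' @param path Path to the file.
#' @param schema One of `"DEMO"`, `"DRUG"`, `"REAC"`; decides the required columns
#'   (DEMO: primaryid, caseid, caseversion, fda_dt; DRUG: primaryid, drugname,
#'   role_cod; REAC: primaryid, pt).
#' @return A tibble with the schema's columns (lower-case names), one row per
#'   retained data line. The attribute `"ingest_log"` holds a one-row tibble with
#'   parsed/skipped counts and the skipped line numbers.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("primaryid$caseid$caseversion$fda_dt",
#'              "1001$10$1$20190101",
#'              "1002$11$1$20200315"), f)
#' read_faers_table(f, "DEMO")
#' @export
read_faers_table <- function(path, schema = c("DEMO", "DRUG", "REAC")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("FAERS ingest error: file not found: ", path),
          class = "pvsignal_ingest_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- iconv(lines, from = "", to = "UTF-8", sub = "byte")

  if (length(lines) == 0L) {
    abort(paste0("FAERS schema error in ", path, ": empty file (no header row)"),
          class = "pvsignal_schema_error")
  }
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  required <- faers_schemas[[schema]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    abort(paste0("FAERS schema error in ", path, ": header lacks required column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "pvsignal_schema_error")
  }

  body <- lines[-1L]
  body <- body[!(body == "" & seq_along(body) == length(body))]  # tolerate final blank line
  fields <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty field is dropped by strsplit; pad rows one short
  short <- nf == length(header) - 1L
  fields[short] <- lapply(fields[short], function(x) c(x, ""))
  nf[short] <- length(header)
  ok_shape <- nf == length(header)

  mat <- do.call(rbind, fields[ok_shape])
  if (is.null(mat)) mat <- matrix(character(), ncol = length(header))
  colnames(mat) <- header
  out <- as_tibble(mat[, required, drop = FALSE])
  line_no <- which(ok_shape) + 1L  # 1-based file line numbers

  key_ok <- trimws(out$primaryid) != ""
  if (schema == "DRUG") key_ok <- key_ok & trimws(out$drugname) != ""
  if (schema == "REAC") key_ok <- key_ok & trimws(out$pt) != ""

  skipped_lines <- sort(c(which(!ok_shape) + 1L, line_no[!key_ok]))
  out <- out[key_ok, , drop = FALSE]

  out <- mutate(out, across(everything(), trimws))
  if (schema == "DEMO") {
    out <- mutate(out,
      caseid = na_if(.data$caseid, ""),
      caseversion = suppressWarnings(as.integer(.data$caseversion)),
      fda_dt = na_if(.data$fda_dt, "")
    )
  }
  if (schema == "DRUG") {
    out <- mutate(out, role_cod = toupper(.data$role_cod),
                  role_cod = na_if(.data$role_cod, ""))
  }

  log <- tibble(
    file = basename(path), schema = schema,
    n_lines = length(body), n_parsed = nrow(out),
    n_skipped = length(skipped_lines),
    skipped_lines = list(skipped_lines)
  )
  attr(out, "ingest_log") <- log
  out
}

#' Combine parsed quarterly tables
#'
#' Row-binds quarterly tables of one schema into a single table keyed by PRIMARYID.
#' No deduplication happens here: the same PRIMARYID appearing in two quarters is
#' retained twice, and record counts add up exactly.
#'
#' @param tables A list of tibbles from [read_faers_table()], all of one schema.
#' @return A single tibble; the `"ingest_log"` attribute stacks the per-file logs.
#' @export
merge_quarters <- function(tables) {
  stopifnot(is.list(tables))
  if (length(tables) == 0L) return(tibble())
  cols <- lapply(tables, names)
  if (length(unique(lapply(cols, sort))) != 1L) {
    abort("merge_quarters(): tables have incompatible columns",
          class = "pvsignal_schema_error")
  }
  logs <- purrr::map(tables, ~ attr(.x, "ingest_log"))
  out <- bind_rows(tables)
  attr(out, "ingest_log") <- bind_rows(purrr::compact(logs))
  out
}

#' Deduplicate multi-version cases
#'
#' Reduces combined DEMO records to one retained report version per case: for each
#' CASEID the record with the highest CASEVERSION wins; ties are broken by the
#' latest FDA_DT, and remaining ties by the lexicographically greatest PRIMARYID,
#' so the result is deterministic and independent of input row order. Records with
#' an absent CASEID cannot be matched to a case and are each retained as their own
#' report, keyed by PRIMARYID alone.
#'
#' @param demo Combined DEMO tibble (columns primaryid, caseid, caseversion, fda_dt).
#' @return A tibble with one row per retained report (columns caseid, primaryid,
#'   caseversion, fda_dt), sorted by caseid. The attribute `"n_missing_caseid"`
#'   counts the caseid-absent records retained as-is.
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "caseversion", "fda_dt") %in% names(demo)))
  no_case <- is.na(demo$caseid) | demo$caseid == ""
  orphans <- demo[no_case, c("caseid", "primaryid", "caseversion", "fda_dt")]

  kept <- demo[!no_case, c("caseid", "primaryid", "caseversion", "fda_dt")] |>
    arrange(desc(coalesce(.data$caseversion, -1L)), desc(.data$fda_dt),
            desc(.data$primaryid)) |>
    distinct(.data$caseid, .keep_all = TRUE)

  out <- bind_rows(kept, orphans) |> arrange(.data$caseid, .data$primaryid)
  attr(out, "n_missing_caseid") <- nrow(orphans)
  out
}

#' Assemble deduplicated case reports
#'
#' Joins retained report versions with their drug mentions and reaction terms into
#' one row per case. Drug names and reaction terms pass through the normalizer
#' (see [normalize_drug()] / [normalize_term()]); repeated mentions of the same
#' canonical drug or term within a case collapse to set membership, so a case can
#' contribute at most 1 to any contingency cell. Drug/reaction rows pointing at a
#' superseded (non-retained) PRIMARYID are dropped and counted.
#'
#' @param dedup Output of [deduplicate_cases()].
#' @param drug Combined DRUG tibble.
#' @param reac Combined REAC tibble.
#' @param synonyms Optional drug synonym table ([read_mapping_table()]).
#' @param term_map Optional adverse-event term map.
#' @param roles Drug role codes to count as exposure; default `c("PS", "SS")`
#'   (suspect drugs only). Use `c("PS", "SS", "C", "I")` to include concomitant
#'   and interacting mentions.
#' @return A `faers_cases` tibble: columns caseid, primaryid, fda_dt and
#'   list-columns `drugs`, `reactions` (character sets). The `"assemble_log"`
#'   attribute records dropped orphan row counts.
#' @export
assemble_cases <- function(dedup, drug, reac, synonyms = NULL, term_map = NULL,
                           roles = c("PS", "SS")) {
  retained <- dedup["primaryid"]

  drug_rows <- drug
  if (!is.null(roles)) drug_rows <- filter(drug_rows, .data$role_cod %in% roles)
  n_drug_in <- nrow(drug_rows)
  drug_rows <- semi_join(drug_rows, retained, by = "primaryid")
  drugs_long <- drug_rows |>
    mutate(drug = normalize_drug(.data$drugname, synonyms)) |>
    distinct(.data$primaryid, .data$drug)

  n_reac_in <- nrow(reac)
  reac_rows <- semi_join(reac, retained, by = "primaryid")
  reac_long <- reac_rows |>
    mutate(reaction = normalize_term(.data$pt, term_map)) |>
    distinct(.data$primaryid, .data$reaction)

  drug_sets <- summarise(drugs_long, drugs = list(.data$drug), .by = "primaryid")
  reac_sets <- summarise(reac_long, reactions = list(.data$reaction), .by = "primaryid")

  out <- dedup |>
    select("caseid", "primaryid", "fda_dt") |>
    left_join(drug_sets, by = "primaryid") |>
    left_join(reac_sets, by = "primaryid") |>
    mutate(
      drugs = purrr::map(.data$drugs, ~ .x %||% character()),
      reactions = purrr::map(.data$reactions, ~ .x %||% character())
    )

  attr(out, "assemble_log") <- tibble(
    n_drug_rows = n_drug_in,
    n_drug_dropped = n_drug_in - nrow(drug_rows),
    n_reac_rows = n_reac_in,
    n_reac_dropped = n_reac_in - nrow(reac_rows)
  )
  class(out) <- c("faers_cases", class(tibble()))
  out
}

# long (primaryid, drug) / (primaryid, reaction) views of a faers_cases tibble
case_drug_pairs <- function(cases) {
  tibble(
    primaryid = rep(cases$primaryid, lengths(cases$drugs)),
    drug = unlist(cases$drugs, use.names = FALSE) %||% character()
  )
}

case_reaction_pairs <- function(cases) {
  tibble(
    primaryid = rep(cases$primaryid, lengths(cases$reactions)),
    reaction = unlist(cases$reactions, use.names = FALSE) %||% character()
  )
}
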