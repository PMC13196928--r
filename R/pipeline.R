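# End-to-end orchestration and the packaged published-table fixtures.

#' Configure a pipeline run
#'
#' @param input_dir Directory containing FAERS-dialect quarterly files
#'   (`DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`).
#' @param out_dir Directory for report files (written atomically: staged, then
#'   moved into place).
#' @param events Character vector (non-empty) of adverse-event terms to analyze.
#' @param top_n List length per event (default 30).
#' @param z CI multiplier (default 1.96).
#' @param roles Drug role codes counted as exposure (default suspect drugs).
#' @param criteria [signal_criteria()].
#' @param synonyms,term_map Optional mapping tables or paths to two-column TSVs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, events, top_n = 30, z = 1.96,
                            roles = c("PS", "SS"), criteria = signal_criteria(),
                            synonyms = NULL, term_map = NULL) {
  stopifnot(length(events) >= 1, top_n >= 1, z > 0)
  as_map <- function(x) {
    if (is.character(x) && length(x) == 1L) read_mapping_table(x) else x
  }
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 events = norm_key(events), top_n = top_n, z = z, roles = roles,
                 criteria = criteria, synonyms = as_map(synonyms),
                 term_map = as_map(term_map)),
            class = "pipeline_config")
}

read_schema_files <- function(input_dir, schema) {
  paths <- sort(list.files(input_dir, pattern = paste0("^", schema, ".*\\.txt$"),
                           full.names = TRUE))
  if (length(paths) == 0L) {
    abort(paste0("[ingest] no ", schema, " files found in ", input_dir),
          class = "pvsignal_ingest_error")
  }
  merge_quarters(lapply(paths, read_faers_table, schema = schema))
}

#' Run the full analysis pipeline
#'
#' Ingests and merges quarterly files, deduplicates cases, normalizes names and
#' terms, computes disproportionality statistics for the configured events, ranks
#' the top-N drugs per event, classifies multi-event membership (when two or more
#' events are configured), and writes the report tables. Any stage failure
#' propagates with a stage-named message; report files are staged in a temporary
#' sibling directory and moved into place only on success, and a rerun on the
#' same inputs produces identical bytes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_result` list: `cases`, `signals`, `topn`,
#'   `venn`, `log` (per-stage case counts), `paths` (files written).
#' @export
run_faers_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  demo <- read_schema_files(config$input_dir, "DEMO")
  drug <- read_schema_files(config$input_dir, "DRUG")
  reac <- read_schema_files(config$input_dir, "REAC")

  dedup <- deduplicate_cases(demo)
  cases <- assemble_cases(dedup, drug, reac, synonyms = config$synonyms,
                          term_map = config$term_map, roles = config$roles)

  signals <- compute_signals(cases, events = config$events, z = config$z,
                             criteria = config$criteria)
  topn <- rank_top_n(signals, n = config$top_n)
  venn <- if (length(config$events) >= 2L &&
              n_distinct(topn$event) >= 2L) classify_venn(topn) else NULL

  stage <- paste0(config$out_dir, ".staging-", Sys.getpid())
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  paths <- export_reports(topn = topn, classification = venn, out_dir = stage)
  log <- tibble(
    stage = c("parsed_demo", "parsed_drug", "parsed_reac", "deduplicated",
              "analyzed_pairs"),
    n = c(nrow(demo), nrow(drug), nrow(reac), nrow(dedup), nrow(signals))
  )
  readr::write_tsv(log, file.path(stage, "pipeline_log.tsv"), progress = FALSE)

  if (dir.exists(config$out_dir)) {
    staged <- list.files(stage, full.names = TRUE)
    file.copy(staged, config$out_dir, overwrite = TRUE)
  } else if (!file.rename(stage, config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
    file.copy(list.files(stage, full.names = TRUE), config$out_dir,
              overwrite = TRUE)
  }
  paths <- file.path(config$out_dir, basename(c(paths, "pipeline_log.tsv")))

  invisible(structure(
    list(cases = cases, signals = signals, topn = topn, venn = venn, log = log,
         paths = paths),
    class = "pipeline_result"
  ))
}

pv_extdata <- function(file) {
  system.file("extdata", file, package = "pvsignal", mustWork = TRUE)
}

#' Packaged published top-30 fixture lists
#'
#' The four published top-30 medication tables (dyspnoea, cough, palpitations,
#' chest pain; FAERS Jan 2018 - Dec 2022) with their printed frequencies, ROR
#' CIs and PRRs. These are data *about* the published full-scale analysis — not
#' recomputable at desk scale — and serve as the classification fixture. Names
#' are exactly as printed (brand/generic mixed); the chest-pain table's Pomalyst
#' CI comes from the accompanying text because the printed row is malformed.
#'
#' @param events Subset of the four event terms to load (default all).
#' @return A tibble with columns event, ranking, drug, a (frequency), ror,
#'   ror_low, ror_high, prr.
#' @export
fixture_top30 <- function(events = c("DYSPNOEA", "COUGH", "PALPITATIONS",
                                     "CHEST PAIN")) {
  files <- c(
    "DYSPNOEA" = "top30_dyspnoea.tsv", "COUGH" = "top30_cough.tsv",
    "PALPITATIONS" = "top30_palpitations.tsv",
    "CHEST PAIN" = "top30_chest_pain.tsv"
  )
  events <- norm_key(events)
  bad <- setdiff(events, names(files))
  if (length(bad) > 0L) {
    abort(paste0("fixture_top30(): no packaged list for: ",
                 paste(bad, collapse = ", ")),
          class = "pvsignal_config_error")
  }
  purrr::map(events, function(ev) {
    readr::read_tsv(pv_extdata(files[[ev]]), comment = "#",
                    col_types = "icidddd", progress = FALSE) |>
      mutate(event = ev) |>
      select("event", "ranking", drug = "medication", a = "frequency",
             "ror", "ror_low", "ror_high", "prr")
  }) |> bind_rows()
}

#' Packaged published panel ROR intervals
#'
#' The published ROR (95% CI) of the 12 FDA-approved pulmonary-hypertension
#' drugs for the four post-lung-surgery symptoms, in long format.
#'
#' @param canonical Map brand names to generics with [default_synonyms()]
#'   (Adcirca to Tadalafil, Adempas to Riociguat); default `FALSE` keeps the
#'   printed names.
#' @return A tibble with columns drug, event, ror, ror_low, ror_high.
#' @export
fixture_panel_ror <- function(canonical = FALSE) {
  out <- readr::read_tsv(pv_extdata("ph_panel_ror.tsv"), comment = "#",
                         col_types = "ccddd", progress = FALSE)
  if (canonical) {
    out <- mutate(out, drug = normalize_drug(.data$drug, default_synonyms()))
  } else {
    out <- mutate(out, drug = norm_key(.data$drug))
  }
  out
}

#' The 12-drug pulmonary-hypertension panel
#'
#' @inheritParams fixture_panel_ror
#' @return Character vector of 12 drug names.
#' @export
fixture_panel_drugs <- function(canonical = FALSE) {
  x <- readLines(pv_extdata("ph_panel_drugs.txt"))
  x <- x[!startsWith(x, "#") & trimws(x) != ""]
  if (canonical) normalize_drug(x, default_synonyms()) else norm_key(x)
}

#' Narrative per-drug event subsets for the panel exceptions
#'
#' The published narrative singles out three panel drugs as related to fewer
#' than all four symptoms (Iloprost, Riociguat, Sildenafil) and states their
#' event subsets; the other nine are stated to relate to all four. Note the
#' documented conflict: the printed CI table for Riociguat (Adempas) has all
#' four lower bounds above 1, which contradicts the narrative subset.
#'
#' @return A tibble with columns drug and a list-column events.
#' @export
fixture_reported_relations <- function() {
  readr::read_tsv(pv_extdata("panel_reported_relations.tsv"), comment = "#",
                  col_types = "cc", progress = FALSE) |>
    mutate(events = strsplit(.data$events, ";", fixed = TRUE))
}

#' Venn classification of the packaged published top-30 lists
#'
#' Feeds the four printed top-30 medication lists to [classify_venn()]; the
#' published analysis reports 4 drugs in all four lists and 10 in exactly three.
#'
#' @return A `venn_classification`.
#' @export
fixture_venn_classification <- function() {
  classify_venn(fixture_top30())
}
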