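# Synthetic spontaneous-report generator with planted drug-event associations.
#
# Emulates the FAERS quarterly structure (DEMO/DRUG/REAC, "$"-delimited, cases
# keyed by PRIMARYID/CASEID with versions) with known ground truth so the whole
# pipeline is testable without a FAERS download. Drug exposures are independent
# Bernoulli draws; each event occurs with its background probability on the odds
# scale, multiplied by the planted odds ratio rho of every exposed planted drug
# (multiplicatively when a case carries several). With a single planted drug per
# event the case-level odds ratio of the exposed/unexposed 2x2 table is exactly
# rho, so the recovered ROR estimates rho directly.

#' Configure a synthetic report set
#'
#' @param n_cases Number of distinct cases to generate.
#' @param drugs Named numeric vector: marginal exposure probability per drug,
#'   each in (0, 1).
#' @param events Named numeric vector: background (unexposed) occurrence
#'   probability per event term, each in (0, 1).
#' @param effects Optional data frame with columns drug, event, rho (target odds
#'   ratio, > 0) for planted associations; unlisted pairs have rho = 1.
#' @param duplicate_rate Probability that a case is emitted a second time as a
#'   higher CASEVERSION with a later FDA_DT (exercises deduplication).
#' @param role_mix Named probability vector over role codes for drug mentions.
#'   Default `c(PS = 0.7, SS = 0.3)`: generated mentions are suspect drugs, the
#'   roles the analysis counts by default.
#' @param seed Integer RNG seed; identical config + seed reproduces the output
#'   byte for byte.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases, drugs, events, effects = NULL,
                             duplicate_rate = 0, role_mix = c(PS = 0.7, SS = 0.3),
                             seed = 1L) {
  stopifnot(n_cases >= 1, length(drugs) >= 1, length(events) >= 1,
            !is.null(names(drugs)), !is.null(names(events)),
            all(drugs > 0 & drugs < 1), all(events > 0 & events < 1),
            duplicate_rate >= 0, duplicate_rate <= 1,
            !is.null(names(role_mix)), all(role_mix >= 0), sum(role_mix) > 0,
            all(names(role_mix) %in% c("PS", "SS", "C", "I")))
  names(drugs) <- norm_key(names(drugs))
  names(events) <- norm_key(names(events))
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    stopifnot(all(c("drug", "event", "rho") %in% names(effects)))
    effects <- mutate(effects, drug = norm_key(.data$drug),
                      event = norm_key(.data$event))
    bad <- setdiff(effects$drug, names(drugs))
    bad_e <- setdiff(effects$event, names(events))
    if (length(bad) + length(bad_e) > 0L || any(effects$rho <= 0)) {
      abort(paste0("synthetic_config(): invalid effects (unknown drug/event or ",
                   "rho <= 0): ",
                   paste(c(bad, bad_e), collapse = ", ")),
            class = "pvsignal_config_error")
    }
  }
  structure(list(n_cases = as.integer(n_cases), drugs = drugs, events = events,
                 effects = effects, duplicate_rate = duplicate_rate,
                 role_mix = role_mix / sum(role_mix), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic FAERS-dialect report set
#'
#' Draws cases under a [synthetic_config()], optionally writes quarterly
#' DEMO/DRUG/REAC files in the ingest dialect plus a `truth.tsv` of planted odds
#' ratios, and returns the in-memory tables. Case identifiers are sequential;
#' `PRIMARYID = CASEID * 100 + CASEVERSION`, which makes deduplication behaviour
#' transparent. Report dates are uniform over 2018-01-01..2022-12-31 and decide
#' the quarterly file each record lands in.
#'
#' @param config A `synthetic_config`.
#' @param dir Optional output directory for the quarterly files; created if
#'   missing.
#' @return A `synthetic_reports` list: tibbles `demo`, `drug`, `reac`, the
#'   `truth` table (drug, event, rho for every pair), `files` (paths written, or
#'   `NULL`), and the `config`.
#' @export
simulate_reports <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cases
  drug_names <- names(config$drugs)
  event_names <- names(config$events)

  expo <- vapply(config$drugs, function(p) rbinom(n, 1L, p) == 1L,
                 logical(n)) |> matrix(nrow = n)
  colnames(expo) <- drug_names

  occ <- matrix(FALSE, n, length(event_names), dimnames = list(NULL, event_names))
  for (ev in event_names) {
    p0 <- config$events[[ev]]
    lodds <- rep(log(p0 / (1 - p0)), n)
    if (!is.null(config$effects)) {
      eff <- filter(config$effects, .data$event == ev)
      for (i in seq_len(nrow(eff))) {
        lodds <- lodds + expo[, eff$drug[i]] * log(eff$rho[i])
      }
    }
    occ[, ev] <- rbinom(n, 1L, plogis(lodds)) == 1L
  }

  caseid <- seq_len(n)
  day0 <- as.Date("2018-01-01")
  dates <- day0 + sample.int(1826L, n, replace = TRUE) - 1L
  fda_dt <- format(dates, "%Y%m%d")

  demo <- tibble(
    primaryid = as.character(caseid * 100L + 1L),
    caseid = as.character(caseid),
    caseversion = 1L,
    fda_dt = fda_dt
  )

  drug_idx <- which(expo, arr.ind = TRUE)
  drug_tab <- tibble(
    case = drug_idx[, 1L],
    drugname = drug_names[drug_idx[, 2L]]
  ) |>
    arrange(.data$case, .data$drugname) |>
    mutate(role_cod = sample(names(config$role_mix), n(), replace = TRUE,
                             prob = config$role_mix)) |>
    group_by(.data$case) |>
    mutate(drug_seq = row_number()) |>
    ungroup()
  drug <- transmute(drug_tab,
                    primaryid = as.character(.data$case * 100L + 1L),
                    drug_seq = .data$drug_seq,
                    drugname = .data$drugname,
                    role_cod = .data$role_cod)

  reac_idx <- which(occ, arr.ind = TRUE)
  reac <- tibble(case = reac_idx[, 1L], pt = event_names[reac_idx[, 2L]]) |>
    arrange(.data$case, .data$pt) |>
    transmute(primaryid = as.character(.data$case * 100L + 1L), pt = .data$pt)

  if (config$duplicate_rate > 0) {
    dup <- which(runif(n) < config$duplicate_rate)
    if (length(dup) > 0L) {
      dup_id <- as.character(caseid[dup] * 100L + 2L)
      old_id <- as.character(caseid[dup] * 100L + 1L)
      demo2 <- tibble(
        primaryid = dup_id, caseid = as.character(caseid[dup]), caseversion = 2L,
        fda_dt = format(dates[dup] + sample.int(90L, length(dup), replace = TRUE),
                        "%Y%m%d")
      )
      id_map <- stats::setNames(dup_id, old_id)
      drug2 <- filter(drug, .data$primaryid %in% old_id) |>
        mutate(primaryid = unname(id_map[.data$primaryid]))
      reac2 <- filter(reac, .data$primaryid %in% old_id) |>
        mutate(primaryid = unname(id_map[.data$primaryid]))
      demo <- bind_rows(demo, demo2) |> arrange(as.numeric(.data$primaryid))
      drug <- bind_rows(drug, drug2) |> arrange(as.numeric(.data$primaryid),
                                                .data$drug_seq)
      reac <- bind_rows(reac, reac2) |> arrange(as.numeric(.data$primaryid),
                                                .data$pt)
    }
  }

  truth <- tidyr::expand_grid(drug = drug_names, event = event_names) |>
    mutate(rho = 1)
  if (!is.null(config$effects)) {
    truth <- truth |>
      left_join(rename(config$effects, rho_planted = "rho"),
                by = c("drug", "event")) |>
      mutate(rho = coalesce(.data$rho_planted, .data$rho)) |>
      select(-"rho_planted")
  }

  files <- NULL
  if (!is.null(dir)) {
    files <- write_faers_files(demo, drug, reac, truth, dir)
  }
  structure(list(demo = demo, drug = drug, reac = reac, truth = truth,
                 files = files, config = config),
            class = "synthetic_reports")
}

quarter_label <- function(fda_dt) {
  yy <- substr(fda_dt, 3L, 4L)
  q <- (as.integer(substr(fda_dt, 5L, 6L)) - 1L) %/% 3L + 1L
  paste0(yy, "Q", q)
}

write_dollar_file <- function(df, path) {
  lines <- c(paste(names(df), collapse = "$"),
             do.call(paste, c(lapply(df, as.character), sep = "$")))
  writeLines(lines, path)
  path
}

# one DEMO/DRUG/REAC file per calendar quarter, quarter taken from the case date
write_faers_files <- function(demo, drug, reac, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qtr <- stats::setNames(quarter_label(demo$fda_dt), demo$primaryid)
  paths <- character()
  for (q in sort(unique(qtr))) {
    ids <- names(qtr)[qtr == q]
    paths <- c(
      paths,
      write_dollar_file(filter(demo, .data$primaryid %in% ids),
                        file.path(dir, paste0("DEMO", q, ".txt"))),
      write_dollar_file(filter(drug, .data$primaryid %in% ids),
                        file.path(dir, paste0("DRUG", q, ".txt"))),
      write_dollar_file(filter(reac, .data$primaryid %in% ids),
                        file.path(dir, paste0("REAC", q, ".txt")))
    )
  }
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_path, progress = FALSE)
  c(paths, truth_path)
}
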