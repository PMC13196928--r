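# Top-N ranking, multi-event Venn classification, and drug-panel profiling.

#' Rank the top-N drugs per event by report frequency
#'
#' Sorts the pairs of each event by co-report count `a` descending, breaking ties
#' by higher ROR and then lexicographic drug name so the ranking is deterministic,
#' and keeps the first `n` drugs per event.
#'
#' @param stats A `pv_signals` tibble (or any data frame with columns drug, event,
#'   a, ror).
#' @param n List length per event (default 30).
#' @return A tibble with a `ranking` column, grouped rows per event; fewer than
#'   `n` available drugs yields a shorter list (with a message).
#' @export
rank_top_n <- function(stats, n = 30) {
  stopifnot(n >= 0)
  out <- stats |>
    filter(.data$a >= 1) |>
    arrange(.data$event, desc(.data$a), desc(.data$ror), .data$drug) |>
    group_by(.data$event) |>
    slice_head(n = n) |>
    mutate(ranking = row_number()) |>
    ungroup() |>
    relocate("event", "ranking")
  short <- count(out, .data$event) |> filter(.data$n < !!n)
  if (nrow(short) > 0L) {
    inform(paste0("rank_top_n(): fewer than ", n, " drugs available for: ",
                  paste(short$event, collapse = ", ")))
  }
  out
}

#' Classify drugs by membership across per-event top-N lists
#'
#' The multi-event signal classification: drugs present in the top-N list of
#' every event form the high-signal set; drugs present in exactly all-but-one
#' lists form the medium-signal set. Membership is computed on canonical drug
#' names, and the result is invariant to list order and within-list order.
#'
#' @param lists Either a data frame with columns `event` and `drug` (e.g. the
#'   output of [rank_top_n()], or the fixture tables with `drug` renamed), or a
#'   named list of character vectors, one per event.
#' @return A `venn_classification` object: list with elements `events`,
#'   `membership` (tibble drug / events list-column / n_events), `high_set`,
#'   `medium_set`, `n_lists`.
#' @examples
#' classify_venn(list(
#'   DYSPNOEA = c("A", "B", "C"), COUGH = c("A", "B"),
#'   PALPITATIONS = c("A", "C"), `CHEST PAIN` = c("A", "C")
#' ))
#' @export
classify_venn <- function(lists) {
  if (is.data.frame(lists)) {
    stopifnot(all(c("event", "drug") %in% names(lists)))
    df <- distinct(as_tibble(lists[c("event", "drug")]))
  } else {
    if (is.null(names(lists)) || anyDuplicated(names(lists)) > 0L ||
        any(names(lists) == "")) {
      abort("classify_venn(): lists must be uniquely named by event",
            class = "pvsignal_config_error")
    }
    df <- purrr::imap(lists, ~ tibble(event = .y, drug = unique(.x))) |> bind_rows()
  }
  events <- unique(df$event)
  if (length(events) < 2L) {
    abort("classify_venn(): need top-N lists for at least two distinct events",
          class = "pvsignal_config_error")
  }
  k <- length(events)
  membership <- df |>
    summarise(events = list(sort(unique(.data$event))), .by = "drug") |>
    mutate(n_events = lengths(.data$events)) |>
    arrange(desc(.data$n_events), .data$drug)

  structure(
    list(
      events = sort(events),
      membership = membership,
      high_set = sort(membership$drug[membership$n_events == k]),
      medium_set = sort(membership$drug[membership$n_events == k - 1L]),
      n_lists = k
    ),
    class = "venn_classification"
  )
}

#' Profile a drug panel across events
#'
#' Fills a |panel| x |events| matrix of disproportionality statistics and flags,
#' and derives the subset of panel drugs whose signal flag is positive for every
#' event ("related to all events"). Panel drugs absent from the statistics source
#' get a degenerate row (`present = FALSE`, flag `FALSE`), never a silent drop.
#'
#' @param stats A data frame of per-pair statistics: columns drug, event, ror,
#'   ror_low, ror_high, and optionally a/prr/chi2 (as produced by
#'   [compute_signals()], or a published-interval fixture such as
#'   [fixture_panel_ror()]).
#' @param panel Character vector of canonical panel drug names (order kept).
#' @param events Character vector of event terms (order kept); default: the
#'   events present in `stats`.
#' @param criteria [signal_criteria()] for the per-cell flag; cells without a
#'   report count are assessed on the CI condition alone.
#' @return A `panel_profile` object: list with `cells` (long tibble drug, event,
#'   statistics, present, signal), `panel`, `events`, `all_positive`.
#' @export
profile_panel <- function(stats, panel, events = NULL,
                          criteria = signal_criteria()) {
  panel <- norm_key(panel)
  stats <- mutate(as_tibble(stats), drug = norm_key(.data$drug),
                  event = norm_key(.data$event))
  if (is.null(events)) events <- unique(stats$event)
  events <- norm_key(events)
  if (anyDuplicated(panel) || anyDuplicated(events)) {
    abort("profile_panel(): panel drugs and events must be distinct",
          class = "pvsignal_config_error")
  }
  if (!"a" %in% names(stats)) stats$a <- NA_integer_

  cells <- tidyr::expand_grid(drug = panel, event = events) |>
    left_join(filter(stats, .data$event %in% events), by = c("drug", "event")) |>
    mutate(present = !is.na(.data$ror))
  cells$signal <- flag_signal(cells, criteria) & cells$present
  cells$signal[is.na(cells$signal)] <- FALSE

  all_positive <- cells |>
    summarise(all_pos = all(.data$signal), .by = "drug") |>
    filter(.data$all_pos)

  structure(
    list(cells = cells, panel = panel, events = events,
         all_positive = all_positive$drug, criteria = criteria),
    class = "panel_profile"
  )
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

fmt2 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.2f", round_half_up(x, 2)))
}

fmt_ror_ci <- function(ror, low, high) {
  ifelse(is.na(ror), "", paste0(fmt2(ror), "(", fmt2(low), "-", fmt2(high), ")"))
}

#' Export classification and panel reports as TSV tables
#'
#' Writes (i) one top-N table per event in the conventional published layout
#' (Ranking, Medication, Frequency, ROR(95% CI), PRR), (ii) a Venn membership
#' table, and (iii) the panel profile in wide and long form. Estimates are
#' printed to two decimals (half-up); output bytes are stable for fixed inputs.
#'
#' @param topn Output of [rank_top_n()] (or `NULL` to skip).
#' @param classification A `venn_classification` (or `NULL`).
#' @param profile A `panel_profile` (or `NULL`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_reports <- function(topn = NULL, classification = NULL, profile = NULL,
                           out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("export_reports(): cannot create ", out_dir),
                   class = "pvsignal_io_error")
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    abort(paste0("export_reports(): directory not writable: ", out_dir),
          class = "pvsignal_io_error")
  }
  paths <- character()

  if (!is.null(topn)) {
    for (ev in unique(topn$event)) {
      tab <- filter(topn, .data$event == ev) |>
        transmute(
          Ranking = .data$ranking, Medication = .data$drug, Frequency = .data$a,
          `ROR(95% CI)` = fmt_ror_ci(.data$ror, .data$ror_low, .data$ror_high),
          PRR = fmt2(.data$prr)
        )
      slug <- tolower(gsub("[^A-Za-z0-9]+", "_", ev))
      p <- file.path(out_dir, paste0("top_", slug, ".tsv"))
      readr::write_tsv(tab, p, progress = FALSE)
      paths <- c(paths, p)
    }
  }

  if (!is.null(classification)) {
    stopifnot(inherits(classification, "venn_classification"))
    venn <- tidy(classification) |>
      mutate(events = purrr::map_chr(.data$events, paste, collapse = ";"))
    p <- file.path(out_dir, "venn.tsv")
    readr::write_tsv(venn, p, progress = FALSE)
    paths <- c(paths, p)
  }

  if (!is.null(profile)) {
    stopifnot(inherits(profile, "panel_profile"))
    long <- profile$cells |>
      select("drug", "event", "ror", ci_low = "ror_low", ci_high = "ror_high",
             "signal")
    p_long <- file.path(out_dir, "panel_long.tsv")
    readr::write_tsv(long, p_long, progress = FALSE)
    wide <- profile$cells |>
      mutate(cell = fmt_ror_ci(.data$ror, .data$ror_low, .data$ror_high)) |>
      select("drug", "event", "cell") |>
      tidyr::pivot_wider(names_from = "event", values_from = "cell")
    p_wide <- file.path(out_dir, "panel_wide.tsv")
    readr::write_tsv(wide, p_wide, progress = FALSE)
    paths <- c(paths, p_long, p_wide)
  }

  invisible(paths)
}
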