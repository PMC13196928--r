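# Disproportionality statistics on per-pair 2x2 contingency tables.
#
# For a drug D and event E over N deduplicated cases:
#       a = cases with D and E        b = cases with D, without E
#       c = cases with E, without D   d = cases with neither
# ROR = (a*d)/(b*c), the odds of reporting E with D vs with any other drug;
# PRR = [a/(a+b)] / [c/(c+d)], the proportion-based analogue. Confidence
# intervals use the Woolf (log-normal) method. Tables containing a zero cell get
# the Haldane-Anscombe correction (+0.5 to all four cells) so estimates stay
# finite; non-degenerate tables are never altered and the correction is flagged.

#' Build the 2x2 contingency table for one drug-event pair
#'
#' The counting unit is the deduplicated case: a case contributes 1 to `a` when its
#' drug set contains the drug and its reaction set contains the event, regardless
#' of how many times either was mentioned. The four cells partition the case set,
#' so `a + b + c + d` always equals the number of cases.
#'
#' @param cases A `faers_cases` tibble from [assemble_cases()].
#' @param drug Canonical drug name.
#' @param event Canonical (preferred) event term.
#' @return A one-row tibble with columns drug, event, a, b, c, d.
#' @export
build_contingency <- function(cases, drug, event) {
  stopifnot(is.character(drug), length(drug) == 1L,
            is.character(event), length(event) == 1L)
  has_drug <- purrr::map_lgl(cases$drugs, ~ drug %in% .x)
  has_event <- purrr::map_lgl(cases$reactions, ~ event %in% .x)
  tibble(
    drug = drug, event = event,
    a = sum(has_drug & has_event),
    b = sum(has_drug & !has_event),
    c = sum(!has_drug & has_event),
    d = sum(!has_drug & !has_event)
  )
}

haldane_correct <- function(a, b, c, d, correction = TRUE) {
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  if (any(corrected) && !correction) {
    abort("zero cell with Haldane-Anscombe correction disabled: estimate undefined",
          class = "pvsignal_estimate_error")
  }
  k <- ifelse(corrected, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = corrected)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ror = (a*d)/(b*c)`; `CI = exp(log(ror) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Vectorized over the cells. Tables with a zero cell are Haldane-Anscombe
#' corrected (+0.5 everywhere) before estimation and flagged.
#'
#' @param a,b,c,d Non-negative integer cell counts (recycled to common length).
#' @param z Normal CI multiplier; 1.96 gives the two-sided 95% interval.
#' @param correction Apply the zero-cell correction (default); with `FALSE` a zero
#'   cell is an error.
#' @return A tibble with columns ror, ror_low, ror_high, corrected.
#' @examples
#' ror_estimate(10, 90, 100, 9900)  # ror = 11, CI about (5.56, 21.77)
#' @export
ror_estimate <- function(a, b, c, d, z = 1.96, correction = TRUE) {
  cells <- haldane_correct(a, b, c, d, correction)
  est <- (cells$a * cells$d) / (cells$b * cells$c)
  se <- sqrt(1 / cells$a + 1 / cells$b + 1 / cells$c + 1 / cells$d)
  tibble(
    ror = est,
    ror_low = exp(log(est) - z * se),
    ror_high = exp(log(est) + z * se),
    corrected = cells$corrected
  )
}

#' Proportional reporting ratio with Woolf confidence interval
#'
#' `prr = [a/(a+b)] / [c/(c+d)]`;
#' `CI = exp(log(prr) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' Requires both margins `a+b` and `c+d` to be positive; zero cells are
#' Haldane-Anscombe corrected as for [ror_estimate()].
#'
#' @inheritParams ror_estimate
#' @return A tibble with columns prr, prr_low, prr_high, corrected.
#' @export
prr_estimate <- function(a, b, c, d, z = 1.96, correction = TRUE) {
  cells <- haldane_correct(a, b, c, d, correction)
  if (any(cells$a + cells$b == 0) || any(cells$c + cells$d == 0)) {
    abort("prr_estimate(): zero row margin (a+b or c+d), estimate undefined",
          class = "pvsignal_estimate_error")
  }
  est <- (cells$a / (cells$a + cells$b)) / (cells$c / (cells$c + cells$d))
  se <- sqrt(1 / cells$a - 1 / (cells$a + cells$b) +
             1 / cells$c - 1 / (cells$c + cells$d))
  tibble(
    prr = est,
    prr_low = exp(log(est) - z * se),
    prr_high = exp(log(est) + z * se),
    corrected = cells$corrected
  )
}

#' Yates-corrected chi-squared statistic of a 2x2 table
#'
#' `chi2 = N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `N = a+b+c+d`; identical to `stats::chisq.test(correct = TRUE)` on the same
#' table. Vectorized. All four margins must be positive.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return Numeric vector of chi-squared statistics.
#' @export
chi2_yates <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(a + b == 0 | c + d == 0 | a + c == 0 | b + d == 0)) {
    abort("chi2_yates(): zero margin, statistic undefined",
          class = "pvsignal_estimate_error")
  }
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Signal criteria configuration
#'
#' Disproportionality signal rules are configuration, not code. The default ROR
#' criterion is `a >= 3` and ROR 95% CI lower bound `> 1`; the default PRR
#' criterion is `a >= 3`, `PRR >= 2` and Yates chi-squared `>= 4`.
#'
#' @param method `"ror"` (default) or `"prr"`.
#' @param min_count Minimum co-report count `a`.
#' @param ror_ci_low ROR CI lower-bound threshold (exclusive).
#' @param prr_min PRR threshold (inclusive).
#' @param chi2_min Chi-squared threshold (inclusive).
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(method = c("ror", "prr"), min_count = 3,
                            ror_ci_low = 1, prr_min = 2, chi2_min = 4) {
  method <- match.arg(method)
  stopifnot(min_count >= 0, ror_ci_low > 0, prr_min > 0, chi2_min >= 0)
  structure(list(method = method, min_count = min_count, ror_ci_low = ror_ci_low,
                 prr_min = prr_min, chi2_min = chi2_min),
            class = "signal_criteria")
}

#' Flag drug-event pairs meeting the signal criteria
#'
#' @param stats A data frame with columns `a`, `ror_low` (for the ROR rule) or
#'   `a`, `prr`, `chi2` (for the PRR rule). Rows with `a = NA` (e.g. published
#'   interval fixtures without frequencies) are assessed on the remaining
#'   conditions.
#' @param criteria A [signal_criteria()] object.
#' @return Logical vector, one flag per row.
#' @export
flag_signal <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  count_ok <- is.na(stats$a) | stats$a >= criteria$min_count
  if (criteria$method == "ror") {
    count_ok & stats$ror_low > criteria$ror_ci_low
  } else {
    count_ok & stats$prr >= criteria$prr_min & stats$chi2 >= criteria$chi2_min
  }
}

#' Compute disproportionality statistics for drug-event pairs
#'
#' Builds every requested 2x2 table over the deduplicated case set in one pass
#' (cases are the counting unit; the comparator is all cases not mentioning the
#' drug) and computes ROR, PRR, their Woolf CIs, the Yates chi-squared and the
#' signal flag.
#'
#' @param cases A `faers_cases` tibble.
#' @param events Optional character vector of event terms to analyze (canonical);
#'   default: every reported event.
#' @param drugs Optional character vector restricting the drugs; when supplied,
#'   all drug x event combinations are returned even if never co-reported
#'   (`a = 0`, correction flagged); otherwise only pairs with `a >= 1`.
#' @param z CI multiplier (default 1.96).
#' @param criteria [signal_criteria()] used for the `signal` column.
#' @param correction Haldane-Anscombe zero-cell correction toggle.
#' @return A `pv_signals` tibble with columns drug, event, a, b, c, d, ror,
#'   ror_low, ror_high, prr, prr_low, prr_high, chi2, corrected, signal; the
#'   attribute `"n_cases"` is the deduplicated case count.
#' @export
compute_signals <- function(cases, events = NULL, drugs = NULL, z = 1.96,
                            criteria = signal_criteria(), correction = TRUE) {
  n_total <- nrow(cases)
  drug_long <- case_drug_pairs(cases)
  reac_long <- case_reaction_pairs(cases)
  if (!is.null(events)) {
    events <- norm_key(events)
    reac_long <- filter(reac_long, .data$reaction %in% events)
  } else {
    events <- sort(unique(reac_long$reaction))
  }
  if (!is.null(drugs)) {
    drugs <- norm_key(drugs)
    drug_long <- filter(drug_long, .data$drug %in% drugs)
  }

  n_drug <- count(drug_long, .data$drug, name = "n_drug")
  n_event <- count(reac_long, .data$reaction, name = "n_event")
  a_tab <- inner_join(drug_long, reac_long, by = "primaryid",
                      relationship = "many-to-many") |>
    count(.data$drug, .data$reaction, name = "a")

  if (is.null(drugs)) {
    grid <- a_tab
  } else {
    grid <- tidyr::expand_grid(drug = drugs, reaction = events) |>
      left_join(a_tab, by = c("drug", "reaction")) |>
      mutate(a = coalesce(.data$a, 0L))
  }

  out <- grid |>
    left_join(n_drug, by = "drug") |>
    left_join(n_event, by = "reaction") |>
    mutate(
      n_drug = coalesce(.data$n_drug, 0L),
      n_event = coalesce(.data$n_event, 0L),
      b = .data$n_drug - .data$a,
      c = .data$n_event - .data$a,
      d = n_total - .data$n_drug - .data$c
    ) |>
    select("drug", event = "reaction", "a", "b", "c", "d")

  ror <- ror_estimate(out$a, out$b, out$c, out$d, z = z, correction = correction)
  prr <- prr_estimate(out$a, out$b, out$c, out$d, z = z, correction = correction)
  cells <- haldane_correct(out$a, out$b, out$c, out$d, correction)
  out <- bind_cols(out, select(ror, -"corrected"), select(prr, -"corrected"))
  out$chi2 <- chi2_yates(cells$a, cells$b, cells$c, cells$d)
  out$corrected <- cells$corrected
  out$signal <- flag_signal(out, criteria)
  out <- arrange(out, .data$event, desc(.data$a), desc(.data$ror), .data$drug)
  attr(out, "n_cases") <- n_total
  class(out) <- c("pv_signals", class(tibble()))
  out
}
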