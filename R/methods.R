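# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @export
print.venn_classification <- function(x, ...) {
  cat("Multi-event signal classification (", x$n_lists, " events)\n", sep = "")
  cat("  events:", paste(x$events, collapse = ", "), "\n")
  cat("  high-signal drugs (all ", x$n_lists, " lists): ",
      paste(x$high_set, collapse = ", "), "\n", sep = "")
  cat("  medium-signal drugs (", x$n_lists - 1L, " lists): ",
      paste(x$medium_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a Venn classification
#'
#' @param x A `venn_classification`.
#' @param ... Unused.
#' @return One row per drug: drug, events (list-column), n_events, class
#'   (`"high"`, `"medium"` or `"other"`).
#' @method tidy venn_classification
#' @export
tidy.venn_classification <- function(x, ...) {
  x$membership |>
    mutate(class = case_when(
      .data$n_events == x$n_lists ~ "high",
      .data$n_events == x$n_lists - 1L ~ "medium",
      .default = "other"
    )) |>
    select("drug", "events", "n_events", "class")
}

#' @method glance venn_classification
#' @export
glance.venn_classification <- function(x, ...) {
  tibble(n_events = x$n_lists, n_drugs = nrow(x$membership),
         n_high = length(x$high_set), n_medium = length(x$medium_set))
}

#' Membership plot for a Venn classification
#'
#' Tile plot of drug x event top-N membership, drugs ordered by how many lists
#' they appear in (a plot-ready alternative to a Venn diagram).
#'
#' @param object A `venn_classification`.
#' @param min_events Hide drugs present in fewer lists than this (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot venn_classification
#' @export
autoplot.venn_classification <- function(object, min_events = 2, ...) {
  df <- tidy(object) |>
    filter(.data$n_events >= min_events) |>
    tidyr::unnest("events") |>
    mutate(drug = factor(.data$drug,
                         levels = rev(unique(tidy(object)$drug))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$events, y = .data$drug,
                                   fill = .data$class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "signal class") +
    ggplot2::theme_minimal()
}

#' @export
print.panel_profile <- function(x, ...) {
  cat("Drug panel profile: ", length(x$panel), " drugs x ",
      length(x$events), " events\n", sep = "")
  cat("  positive for every event: ",
      if (length(x$all_positive)) paste(x$all_positive, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Tidy a panel profile
#'
#' @param x A `panel_profile`.
#' @param ... Unused.
#' @return The long cell table: drug, event, statistics, present, signal.
#' @method tidy panel_profile
#' @export
tidy.panel_profile <- function(x, ...) {
  as_tibble(x$cells)
}

#' @method glance panel_profile
#' @export
glance.panel_profile <- function(x, ...) {
  tibble(n_drugs = length(x$panel), n_events = length(x$events),
         n_all_positive = length(x$all_positive),
         n_missing = sum(!x$cells$present))
}

#' Heatmap of a panel profile
#'
#' ROR heatmap of the panel x event matrix; cells whose CI lower bound does not
#' exceed the signal threshold are marked.
#'
#' @param object A `panel_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_profile
#' @export
autoplot.panel_profile <- function(object, ...) {
  df <- object$cells |>
    mutate(drug = factor(.data$drug, levels = rev(object$panel)),
           event = factor(.data$event, levels = object$events))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$drug,
                                   fill = .data$ror)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$signal, "", "ns")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#cb181d",
                                 na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "ROR") +
    ggplot2::theme_minimal()
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic report config: ", x$n_cases, " cases, ", length(x$drugs),
      " drugs, ", length(x$events), " events, ",
      if (is.null(x$effects)) 0L else nrow(x$effects),
      " planted effect(s), duplicate rate ", x$duplicate_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$log)
  invisible(x)
}
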