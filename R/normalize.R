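# Canonicalization of verbatim drug names and adverse-event terms.
#
# Spontaneous reports mix brand and generic drug names ("OPSUMIT" vs "MACITENTAN")
# and verbatim event descriptions ("heart attack" vs the preferred term
# "MYOCARDIAL INFARCTION"). Dictionaries like MedDRA are licensed, so mapping is
# driven by user-supplied two-column tables; unmapped inputs pass through in
# key-normalized form (uppercased, trimmed, internal whitespace collapsed) rather
# than being dropped, which keeps synthetic-data analyses dictionary-free.

norm_key <- function(x) {
  stringr::str_squish(toupper(x))
}

#' Build a name/term mapping table
#'
#' @param verbatim Character vector of verbatim names/terms (keys).
#' @param canonical Character vector of canonical names, same length.
#' @param provenance Free-text label describing where the mapping came from.
#' @return A `pv_mapping` tibble with key-normalized `key` and `canonical` columns.
#'   The mapping is made idempotent: every canonical name also maps to itself, and
#'   a key whose canonical value is itself a key of a *different* canonical value
#'   is rejected.
#' @export
mapping_table <- function(verbatim, canonical, provenance = "user") {
  stopifnot(length(verbatim) == length(canonical))
  key <- norm_key(verbatim)
  canonical <- norm_key(canonical)
  if (any(canonical == "")) {
    abort("mapping_table(): canonical names must be non-empty",
          class = "pvsignal_input_error")
  }
  tab <- distinct(tibble(key = key, canonical = canonical))
  dup <- tab$key[duplicated(tab$key)]
  if (length(dup) > 0L) {
    abort(paste0("mapping_table(): key(s) mapped to conflicting canonical names: ",
                 paste(unique(dup), collapse = ", ")),
          class = "pvsignal_input_error")
  }
  # idempotence: canonical names map to themselves
  chained <- tab$canonical %in% tab$key[tab$key != tab$canonical]
  if (any(chained)) {
    abort(paste0("mapping_table(): canonical name(s) are themselves remapped keys: ",
                 paste(unique(tab$canonical[chained]), collapse = ", ")),
          class = "pvsignal_input_error")
  }
  ident <- tibble(key = unique(tab$canonical), canonical = unique(tab$canonical))
  out <- bind_rows(tab, anti_join(ident, tab, by = "key"))
  attr(out, "provenance") <- provenance
  class(out) <- c("pv_mapping", class(tibble()))
  out
}

#' Read a mapping table from a two-column TSV
#'
#' Expects tab-separated `verbatim<TAB>canonical` rows; lines starting with `#`
#' are comments.
#'
#' @param path Path to the TSV file.
#' @param provenance Label stored on the table; defaults to the file name.
#' @return A `pv_mapping` tibble (see [mapping_table()]).
#' @export
read_mapping_table <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("mapping table not found: ", path), class = "pvsignal_ingest_error")
  }
  raw <- readr::read_tsv(path, comment = "#", col_names = c("verbatim", "canonical"),
                         col_types = "cc", progress = FALSE)
  mapping_table(raw$verbatim, raw$canonical, provenance = provenance)
}

#' Packaged default drug synonym table
#'
#' Covers only the brand/generic pairs needed to reconcile the pulmonary-
#' hypertension panel's mixed naming (Opsumit/Macitentan, Adempas/Riociguat,
#' Adcirca/Tadalafil). Treprostinil formulations (Tyvaso, Remodulin, Orenitram)
#' are distinct products and are deliberately not pooled.
#'
#' @return A `pv_mapping` tibble.
#' @export
default_synonyms <- function() {
  read_mapping_table(
    system.file("extdata", "synonyms_default.tsv", package = "pvsignal",
                mustWork = TRUE),
    provenance = "pvsignal default synonyms"
  )
}

map_with_table <- function(x, table, what) {
  if (any(is.na(x) | trimws(x) == "")) {
    abort(paste0("normalize_", what, "(): empty ", what, " rejected"),
          class = "pvsignal_input_error")
  }
  key <- norm_key(x)
  if (is.null(table)) return(key)
  stopifnot(inherits(table, "pv_mapping"))
  m <- match(key, table$key)
  ifelse(is.na(m), key, table$canonical[m])
}

#' Canonicalize drug names
#'
#' Key-normalizes (uppercase, trim, collapse internal whitespace) and applies a
#' synonym table. Names absent from the table pass through key-normalized, so the
#' operation is idempotent and total.
#'
#' @param name Character vector of verbatim drug names (non-empty).
#' @param table A `pv_mapping` synonym table, or `NULL` for key-normalization only.
#' @return Character vector of canonical names.
#' @examples
#' normalize_drug("  spiriva ")                      # "SPIRIVA"
#' normalize_drug("Opsumit", default_synonyms())     # "MACITENTAN"
#' @export
normalize_drug <- function(name, table = NULL) {
  map_with_table(name, table, "drug")
}

#' Standardize adverse-event terms
#'
#' Maps verbatim reaction terms to preferred terms via a user-supplied table
#' (standing in for a MedDRA lookup, e.g. "heart attack" to
#' "MYOCARDIAL INFARCTION"). Unmapped terms pass through key-normalized.
#'
#' @param term Character vector of verbatim terms (non-empty).
#' @param map A `pv_mapping` term map, or `NULL`.
#' @return Character vector of preferred terms.
#' @export
normalize_term <- function(term, map = NULL) {
  map_with_table(term, map, "term")
}
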