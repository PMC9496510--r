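#' CSV dialect configuration for the two-table exchange format
#'
#' @param delim Field delimiter, default comma.
#' @param quote Quoting character, default double quote.
#' @param verb_sep Intra-field separator splitting the `verbs` column into a
#'   list of verbs, default `";"`.
#' @return A `dm_dialect` list.
#' @export
csv_dialect <- function(delim = ",", quote = "\"", verb_sep = ";") {
  stopifnot(nchar(delim) == 1, nchar(quote) == 1, nchar(verb_sep) >= 1)
  structure(list(delim = delim, quote = quote, verb_sep = verb_sep),
            class = "dm_dialect")
}

entity_columns <- function() c("entity_id", "label", "compartment")
interaction_columns <- function() {
  c("source_id", "target_id", "pmid", "year", "sentence", "verbs")
}

new_ingest_report <- function(n_rows, records, errors, warnings) {
  list(
    n_rows = n_rows,
    n_records = records,
    errors = errors,       # tibble(row, message); row = file line number
    warnings = warnings,
    ok = nrow(errors) == 0
  )
}

empty_issues <- function() {
  tibble::tibble(row = integer(0), message = character(0))
}

#' Retrieve the ingest report attached to a table
#'
#' [read_entities()] and [read_interactions()] attach a report describing
#' skipped rows; errors are non-fatal unless `strict = TRUE`.
#'
#' @param x A tibble returned by an ingest function.
#' @return A list with `n_rows`, `n_records`, `errors`, `warnings`, `ok`.
#' @export
ingest_report <- function(x) {
  rep <- attr(x, "ingest_report", exact = TRUE)
  if (is.null(rep)) {
    rlang::abort("no ingest report attached; was this read by dmcurate?",
                 class = "dm_input_error")
  }
  rep
}

read_raw_table <- function(path, dialect, required) {
  if (!file.exists(path)) {
    rlang::abort(paste0("input file not found: ", path),
                 class = "dm_input_error")
  }
  raw <- readr::read_delim(
    path,
    delim = dialect$delim, quote = dialect$quote,
    col_types = readr::cols(.default = "c"),
    trim_ws = FALSE, progress = FALSE, na = character()
  )
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    rlang::abort(
      paste0("missing required column(s) in ", path, ": ",
             paste(miss, collapse = ", ")),
      class = "dm_input_error"
    )
  }
  dplyr::mutate(raw, dplyr::across(dplyr::all_of(required), stringr::str_trim))
}

finish_ingest <- function(records, n_rows, errors, strict, what) {
  if (strict && nrow(errors) > 0) {
    rlang::abort(
      paste0("strict ingest of ", what, " failed:\n",
             paste0("  row ", errors$row, ": ", errors$message,
                    collapse = "\n")),
      class = "dm_input_error"
    )
  }
  attr(records, "ingest_report") <-
    new_ingest_report(n_rows, nrow(records), errors, empty_issues())
  records
}

#' Read the entity table (mined entities and their localization)
#'
#' Expects a header `entity_id,label,compartment`. Whitespace is stripped
#' from every field. Rows with an empty field or a duplicated `entity_id`
#' are reported in the ingest report and skipped (or fatal under `strict`).
#' Entity-id matching is case-sensitive and exact; no label normalization is
#' performed -- synonym resolution is the upstream text miner's job.
#'
#' @param path Path to the entities CSV.
#' @param dialect A [csv_dialect()].
#' @param strict If `TRUE`, any row-level error aborts.
#' @return A tibble with columns `entity_id`, `label`, `compartment` and an
#'   ingest report retrievable with [ingest_report()].
#' @export
read_entities <- function(path, dialect = csv_dialect(), strict = FALSE) {
  raw <- read_raw_table(path, dialect, entity_columns())
  n <- nrow(raw)
  errors <- empty_issues()
  keep <- rep(TRUE, n)
  line <- seq_len(n) + 1L  # header is line 1

  add_error <- function(i, msg) {
    errors <<- tibble::add_row(errors, row = line[i], message = msg)
    keep[i] <<- FALSE
  }
  for (i in seq_len(n)) {
    if (raw$entity_id[i] == "") add_error(i, "empty entity_id")
    else if (raw$label[i] == "") add_error(i, "empty label")
    else if (raw$compartment[i] == "") add_error(i, "empty compartment")
  }
  seen <- character(0)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (raw$entity_id[i] %in% seen) {
      add_error(i, paste0("duplicate entity_id ", raw$entity_id[i]))
    } else {
      seen <- c(seen, raw$entity_id[i])
    }
  }
  records <- tibble::as_tibble(raw[keep, entity_columns()])
  finish_ingest(records, n, errors, strict, "entities")
}

#' Read the interaction table (sentence-level evidence)
#'
#' Expects a header `source_id,target_id,pmid,year,sentence,verbs`; one row
#' is one sentence-level mention of a directed pair. The `verbs` field is
#' split on the dialect's `verb_sep` into a list-column (an empty field
#' gives an empty verb list, which categorizes as `undefined` downstream).
#' Rows referencing entity ids absent from `entities`, or with a
#' non-numeric/out-of-range `pmid` or `year`, or an empty sentence, are
#' reported as errors and skipped.
#'
#' @param path Path to the interactions CSV.
#' @param entities Entity table from [read_entities()].
#' @param dialect A [csv_dialect()].
#' @param strict If `TRUE`, any row-level error aborts.
#' @return A tibble with columns `source_id`, `target_id`, `pmid` (int),
#'   `year` (int), `sentence` and list-column `verbs`, plus an ingest report.
#' @export
read_interactions <- function(path, entities, dialect = csv_dialect(),
                              strict = FALSE) {
  stopifnot(is.data.frame(entities), "entity_id" %in% names(entities))
  raw <- read_raw_table(path, dialect, interaction_columns())
  n <- nrow(raw)
  errors <- empty_issues()
  keep <- rep(TRUE, n)
  line <- seq_len(n) + 1L
  known <- entities$entity_id

  add_error <- function(i, msg) {
    errors <<- tibble::add_row(errors, row = line[i], message = msg)
    keep[i] <<- FALSE
  }
  pmid <- suppressWarnings(as.integer(raw$pmid))
  year <- suppressWarnings(as.integer(raw$year))
  for (i in seq_len(n)) {
    if (!(raw$source_id[i] %in% known)) {
      add_error(i, paste0("unknown entity ", raw$source_id[i]))
    } else if (!(raw$target_id[i] %in% known)) {
      add_error(i, paste0("unknown entity ", raw$target_id[i]))
    } else if (is.na(pmid[i]) || pmid[i] <= 0L) {
      add_error(i, paste0("pmid must be a positive integer, got '",
                          raw$pmid[i], "'"))
    } else if (is.na(year[i]) || year[i] < 1800L || year[i] > 2100L) {
      add_error(i, paste0("year must be an integer in 1800..2100, got '",
                          raw$year[i], "'"))
    } else if (raw$sentence[i] == "") {
      add_error(i, "empty sentence")
    }
  }
  verbs <- purrr::map(raw$verbs, function(v) {
    parts <- stringr::str_trim(stringr::str_split_1(v, stringr::fixed(dialect$verb_sep)))
    parts[parts != ""]
  })
  records <- tibble::tibble(
    source_id = raw$source_id[keep],
    target_id = raw$target_id[keep],
    pmid = pmid[keep],
    year = year[keep],
    sentence = raw$sentence[keep],
    verbs = verbs[keep]
  )
  finish_ingest(records, n, errors, strict, "interactions")
}
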