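#' Interaction categories
#'
#' The five interaction classes used throughout the package. Verb- and
#' evidence-level categories are restricted to the first four; `incoherent`
#' exists only at the edge level, where evidence for both activation and
#' inhibition of the same directed pair conflicts.
#'
#' @param edge_level If `TRUE` (default) return all five classes, otherwise
#'   the four verb-/evidence-level classes.
#' @return A character vector of category names.
#' @export
#' @examples
#' interaction_categories()
interaction_categories <- function(edge_level = TRUE) {
  base <- c("activate", "inhibit", "neutral", "undefined")
  if (edge_level) c(base, "incoherent") else base
}

#' Review statuses an edge can hold
#'
#' @return Character vector of the four review statuses.
#' @export
review_statuses <- function() {
  c("unreviewed", "accepted", "declined", "further_inspection_needed")
}

new_lexicon <- function(verb, category) {
  verb <- stringr::str_to_lower(stringr::str_trim(verb))
  if (anyDuplicated(verb)) {
    dup <- unique(verb[duplicated(verb)])
    rlang::abort(
      paste0("duplicate lexicon verbs: ", paste(dup, collapse = ", ")),
      class = "dm_input_error"
    )
  }
  bad <- setdiff(unique(category), c("activate", "inhibit", "neutral"))
  if (length(bad) > 0) {
    rlang::abort(
      paste0(
        "lexicon categories must be activate/inhibit/neutral ",
        "(absence from the lexicon is what 'undefined' means); got: ",
        paste(bad, collapse = ", ")
      ),
      class = "dm_input_error"
    )
  }
  structure(
    tibble::tibble(verb = verb, category = category),
    class = c("verb_lexicon", class(tibble::tibble()))
  )
}

#' The packaged default verb lexicon
#'
#' A replaceable mapping from normalized verb forms to one of the three
#' directional/neutral categories. Verbs absent from the lexicon categorize
#' as `undefined`; no verb maps to `undefined` or `incoherent` directly.
#' The default ships as plain CSV under `inst/extdata/verb_lexicon.csv` and
#' lists inflected forms explicitly -- no stemming is performed at lookup
#' time beyond lowercasing and punctuation stripping.
#'
#' @return A `verb_lexicon` tibble with columns `verb` and `category`.
#' @seealso [read_lexicon()] to load a custom lexicon.
#' @export
#' @examples
#' default_lexicon()
default_lexicon <- function() {
  path <- system.file("extdata", "verb_lexicon.csv", package = "dmcurate")
  read_lexicon(path)
}

#' Load a verb lexicon from a two-column CSV
#'
#' The file must have a header `verb,category`; categories are restricted to
#' `activate`, `inhibit`, `neutral`.
#'
#' @param path Path to a CSV file.
#' @return A `verb_lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("lexicon file not found: ", path),
                 class = "dm_input_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("verb", "category")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("lexicon is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "dm_input_error")
  }
  new_lexicon(raw$verb, stringr::str_trim(raw$category))
}

#' Categorize verbs against a lexicon
#'
#' Each verb is lowercased and stripped of surrounding punctuation before
#' lookup. Verbs not in the lexicon return `"undefined"`; the function is
#' total and vectorized.
#'
#' @param verbs Character vector of verb strings.
#' @param lexicon A `verb_lexicon`, by default [default_lexicon()].
#' @return Character vector of categories, same length as `verbs`.
#' @export
#' @examples
#' categorize_verb(c("Activates,", "binds", "flurbs"))
categorize_verb <- function(verbs, lexicon = default_lexicon()) {
  if (length(verbs) == 0) return(character(0))
  norm <- stringr::str_to_lower(stringr::str_trim(verbs))
  norm <- stringr::str_remove_all(norm, "^[[:punct:]]+|[[:punct:]]+$")
  idx <- match(norm, lexicon$verb)
  out <- lexicon$category[idx]
  out[is.na(out)] <- "undefined"
  out
}
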