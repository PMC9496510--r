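#' Aggregate verb- or evidence-level categories into a single class
#'
#' Aggregation has multiset semantics: it is order-invariant and unaffected
#' by duplication. Conflicting directional evidence (both `activate` and
#' `inhibit` present) yields `incoherent`; a single directional signal wins
#' over `neutral`, which in turn wins over `undefined`. The empty set is
#' `undefined`.
#'
#' @param categories Character vector drawn from
#'   `interaction_categories(edge_level = FALSE)`.
#' @return A single category string, possibly `"incoherent"`.
#' @export
#' @examples
#' aggregate_categories(c("neutral", "activate", "undefined"))
#' aggregate_categories(c("activate", "inhibit"))
#' aggregate_categories(character(0))
aggregate_categories <- function(categories) {
  ok <- interaction_categories(edge_level = FALSE)
  bad <- setdiff(unique(categories), ok)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("categories must be one of ", paste(ok, collapse = "/"),
             "; got: ", paste(bad, collapse = ", ")),
      class = "dm_input_error"
    )
  }
  has_act <- "activate" %in% categories
  has_inh <- "inhibit" %in% categories
  if (has_act && has_inh) return("incoherent")
  if (has_act) return("activate")
  if (has_inh) return("inhibit")
  if ("neutral" %in% categories) return("neutral")
  "undefined"
}

#' Categorize sentence-level interaction evidence
#'
#' Takes the interaction table produced by [read_interactions()] (one row =
#' one sentence-level mention) and attaches, per row, the category of each
#' verb and a single evidence-level category. A directional conflict *within
#' one sentence* demotes to `undefined`: the `incoherent` class is reserved
#' for conflict across evidences at the edge level, where it is recomputed
#' by [build_map()].
#'
#' @param interactions Tibble with at least columns `source_id`, `target_id`,
#'   `pmid`, `year`, `sentence` and a list-column `verbs`.
#' @param lexicon A `verb_lexicon`.
#' @return The input tibble with list-column `verb_categories` (aligned 1:1
#'   with `verbs`) and character column `evidence_category` added.
#' @export
#' @examples
#' rows <- tibble::tibble(
#'   source_id = "E1", target_id = "E2", pmid = 111L, year = 2001L,
#'   sentence = "E1 activates E2.", verbs = list("activates")
#' )
#' categorize_evidence(rows)$evidence_category
categorize_evidence <- function(interactions, lexicon = default_lexicon()) {
  stopifnot(is.data.frame(interactions))
  if (!is.list(interactions$verbs)) {
    rlang::abort("`verbs` must be a list-column of character vectors",
                 class = "dm_input_error")
  }
  verb_categories <- purrr::map(interactions$verbs, categorize_verb,
                                lexicon = lexicon)
  evidence_category <- purrr::map_chr(verb_categories, function(vc) {
    agg <- aggregate_categories(vc)
    if (agg == "incoherent") "undefined" else agg
  })
  dplyr::mutate(
    tibble::as_tibble(interactions),
    verb_categories = verb_categories,
    evidence_category = evidence_category
  )
}
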