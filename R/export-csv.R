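#' Review table for a disease map
#'
#' One row per edge, sorted by edge id: the connected entity labels, the
#' edge class and distinct-publication weight, the current review status
#' (spelled `unreviewed`, `accepted`, `declined`,
#' `further_inspection_needed`), and the supporting PubMed ids joined in
#' ascending order.
#'
#' @param map A `disease_map`.
#' @param pmid_sep Separator joining the PubMed ids, default `";"`.
#' @return A tibble with columns `edge_id`, `source_label`, `target_label`,
#'   `edge_class`, `weight`, `review_status`, `pmids`.
#' @export
to_review_csv <- function(map, pmid_sep = ";") {
  stopifnot(inherits(map, "disease_map"))
  label_of <- function(ids) {
    map$nodes$label[match(ids, map$nodes$node_id)]
  }
  out <- tibble::tibble(
    edge_id = map$edges$edge_id,
    source_label = label_of(map$edges$source),
    target_label = label_of(map$edges$target),
    edge_class = map$edges$edge_class,
    weight = as.integer(map$edges$weight),
    review_status = map$edges$review_status,
    pmids = purrr::map_chr(map$edges$evidences, function(ev) {
      paste(sort(unique(as.integer(ev$pmid))), collapse = pmid_sep)
    })
  )
  dplyr::arrange(out, .data$edge_id)
}

#' Write the review CSV for a disease map
#'
#' @param map A `disease_map`.
#' @param path Output file path.
#' @param pmid_sep Separator joining the PubMed ids, default `";"`.
#' @return `path`, invisibly.
#' @export
write_review_csv <- function(map, path, pmid_sep = ";") {
  readr::write_csv(to_review_csv(map, pmid_sep), path, progress = FALSE)
  invisible(path)
}

#' Write an entity table in the two-CSV exchange format
#'
#' Inverse of [read_entities()]: reading a file written here yields records
#' equal to the originals field by field.
#'
#' @param entities Tibble with `entity_id`, `label`, `compartment`.
#' @param path Output file path.
#' @param dialect A [csv_dialect()].
#' @return `path`, invisibly.
#' @export
write_entities_csv <- function(entities, path, dialect = csv_dialect()) {
  readr::write_delim(entities[, entity_columns()], path,
                     delim = dialect$delim, na = "", progress = FALSE)
  invisible(path)
}

#' Write an interaction table in the two-CSV exchange format
#'
#' Inverse of [read_interactions()]: the `verbs` list-column is joined with
#' the dialect's intra-field separator.
#'
#' @param interactions Tibble as returned by [read_interactions()].
#' @param path Output file path.
#' @param dialect A [csv_dialect()].
#' @return `path`, invisibly.
#' @export
write_interactions_csv <- function(interactions, path,
                                   dialect = csv_dialect()) {
  out <- tibble::tibble(
    source_id = interactions$source_id,
    target_id = interactions$target_id,
    pmid = as.integer(interactions$pmid),
    year = as.integer(interactions$year),
    sentence = interactions$sentence,
    verbs = purrr::map_chr(interactions$verbs, paste,
                           collapse = dialect$verb_sep)
  )
  readr::write_delim(out, path, delim = dialect$delim, na = "",
                     progress = FALSE)
  invisible(path)
}
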