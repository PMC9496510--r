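#' Filter edges by class and minimum publication count
#'
#' Pure edge operation mirroring the viewer's legend checkboxes and
#' minimum-publication slider: an edge survives iff its class is allowed and
#' its distinct-publication weight reaches `min_publications`. Nodes and
#' compartments are untouched (hiding isolated nodes is a viewer concern).
#' Filtering is idempotent, and filtering by class then by weight equals the
#' combined filter.
#'
#' @param map A `disease_map`.
#' @param classes Character vector of allowed edge classes; empty (the
#'   default) means all five classes are allowed.
#' @param min_publications Minimum distinct-publication weight, >= 1.
#' @return A new `disease_map` with the filtered edge set.
#' @export
filter_edges <- function(map, classes = character(0), min_publications = 1) {
  stopifnot(inherits(map, "disease_map"), min_publications >= 1)
  bad <- setdiff(classes, interaction_categories())
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown edge class(es): ",
                        paste(bad, collapse = ", ")),
                 class = "dm_input_error")
  }
  keep_class <- if (length(classes) == 0) {
    rep(TRUE, nrow(map$edges))
  } else {
    map$edges$edge_class %in% classes
  }
  map$edges <- map$edges[keep_class & map$edges$weight >= min_publications, ]
  map
}

recompute_edge <- function(ev) {
  list(weight = dplyr::n_distinct(ev$pmid),
       edge_class = aggregate_categories(ev$evidence_category))
}

#' Cumulative timeline snapshot of a disease map
#'
#' Restricts every edge's evidence to publications with year <= `year`
#' (knowledge-to-date, not a per-window slice). Edges left without evidence
#' are dropped; weight and class are recomputed from the surviving evidence,
#' so an edge whose directional conflict only arises later in the literature
#' can legitimately change class between snapshots. Review statuses carry
#' over.
#'
#' @param map A `disease_map`.
#' @param year Cutoff calendar year (inclusive).
#' @return A new `disease_map` restricted to evidence up to `year`.
#' @export
snapshot_by_year <- function(map, year) {
  stopifnot(inherits(map, "disease_map"), is.numeric(year), length(year) == 1)
  edges <- map$edges
  kept <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ev <- edges$evidences[[i]]
    ev <- ev[ev$year <= year, ]
    kept[i] <- nrow(ev) > 0
    if (kept[i]) {
      edges$evidences[[i]] <- ev
      rc <- recompute_edge(ev)
      edges$weight[i] <- rc$weight
      edges$edge_class[i] <- rc$edge_class
    }
  }
  map$edges <- edges[kept, ]
  map
}

#' Series of cumulative snapshots over a year range
#'
#' One snapshot per year in `start, start + step, ..., end` (inclusive);
#' the default range covers 1990 to 2020 in 5-year steps. Because snapshots
#' are cumulative, edge sets are nested along the series.
#'
#' @param map A `disease_map`.
#' @param start,end First and last cutoff years, `start <= end`.
#' @param step Step in years, >= 1.
#' @return A tibble with columns `year` and list-column `map`.
#' @export
snapshot_series <- function(map, start = 1990, end = 2020, step = 5) {
  stopifnot(inherits(map, "disease_map"))
  if (start > end || step < 1) {
    rlang::abort("need start <= end and step >= 1",
                 class = "dm_input_error")
  }
  years <- seq(start, end, by = step)
  tibble::tibble(
    year = as.integer(years),
    map = purrr::map(years, ~ snapshot_by_year(map, .x))
  )
}

#' Record an expert review decision on an edge
#'
#' Sets the edge's review status (last write wins) and appends the decision
#' to the audit trail in the map's metadata; graph topology, weights and
#' classes are never touched by review.
#'
#' @param map A `disease_map`.
#' @param edge_id Id of an existing edge.
#' @param status One of `accepted`, `declined`,
#'   `further_inspection_needed` -- a decision always sets a definite
#'   status, never `unreviewed`.
#' @param note Optional free-text note stored in the audit trail.
#' @param timestamp ISO-8601 instant; injectable for reproducible exports.
#' @return The updated `disease_map`.
#' @export
apply_review <- function(map, edge_id, status, note = NA_character_,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  stopifnot(inherits(map, "disease_map"))
  allowed <- setdiff(review_statuses(), "unreviewed")
  if (!status %in% allowed) {
    rlang::abort(paste0("invalid review status '", status,
                        "'; valid statuses: ",
                        paste(allowed, collapse = ", ")),
                 class = "dm_input_error")
  }
  i <- match(edge_id, map$edges$edge_id)
  if (is.na(i)) {
    rlang::abort(paste0("no edge with id ", edge_id),
                 class = "dm_input_error")
  }
  map$edges$review_status[i] <- status
  map$meta$audit <- tibble::add_row(
    map$meta$audit,
    edge_id = edge_id, status = status, note = note, timestamp = timestamp
  )
  map
}

#' Next edge awaiting review
#'
#' Iterates unreviewed edges in a stable order (sorted by edge id), cycling
#' past `after`, mirroring the viewer's "Next edge" button.
#'
#' @param map A `disease_map`.
#' @param after Optional edge id to continue from; the next unreviewed edge
#'   strictly after it is returned, wrapping around to the first.
#' @return An edge id, or `NULL` when every edge is reviewed.
#' @export
next_unreviewed <- function(map, after = NULL) {
  stopifnot(inherits(map, "disease_map"))
  ids <- sort(map$edges$edge_id[map$edges$review_status == "unreviewed"])
  if (length(ids) == 0) return(NULL)
  if (is.null(after)) return(ids[1])
  nxt <- ids[ids > after]
  if (length(nxt) > 0) nxt[1] else ids[1]
}

#' Review progress summary
#'
#' @param map A `disease_map`.
#' @return A one-row tibble with a count per review status and `n_edges`;
#'   the four counts always sum to the edge count.
#' @export
review_summary <- function(map) {
  stopifnot(inherits(map, "disease_map"))
  counts <- table(factor(map$edges$review_status, levels = review_statuses()))
  out <- tibble::as_tibble(as.list(as.integer(counts)),
                           .name_repair = "minimal")
  names(out) <- review_statuses()
  out$n_edges <- nrow(map$edges)
  out
}
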