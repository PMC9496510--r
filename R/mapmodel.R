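#' @importFrom rlang .data
NULL

new_disease_map <- function(compartments, nodes, edges, meta) {
  structure(
    list(compartments = compartments, nodes = nodes, edges = edges,
         meta = meta),
    class = "disease_map"
  )
}

empty_audit <- function() {
  tibble::tibble(edge_id = character(0), status = character(0),
                 note = character(0), timestamp = character(0))
}

evidence_prototype <- function() {
  tibble::tibble(
    pmid = integer(0), year = integer(0), sentence = character(0),
    verbs = list(), verb_categories = list(),
    evidence_category = character(0)
  )
}

#' Validate a disease map's structural invariants
#'
#' Checks referential integrity (edge endpoints resolve to nodes, node
#' parents to compartments), directed-pair uniqueness of edges, per-edge
#' weight/class consistency with the evidence, and legal review statuses.
#'
#' @param map A `disease_map`.
#' @return `map`, invisibly; aborts with all problems listed otherwise.
#' @export
validate_disease_map <- function(map) {
  stopifnot(inherits(map, "disease_map"))
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (anyDuplicated(map$compartments$compartment_id)) {
    note("duplicate compartment ids")
  }
  if (anyDuplicated(map$nodes$node_id)) note("duplicate node ids")
  bad_parent <- setdiff(map$nodes$parent, map$compartments$compartment_id)
  if (length(bad_parent) > 0) {
    note(paste0("node parent(s) not a compartment: ",
                paste(bad_parent, collapse = ", ")))
  }
  bad_src <- setdiff(map$edges$source, map$nodes$node_id)
  bad_tgt <- setdiff(map$edges$target, map$nodes$node_id)
  if (length(c(bad_src, bad_tgt)) > 0) {
    note(paste0("edge endpoint(s) not a node: ",
                paste(unique(c(bad_src, bad_tgt)), collapse = ", ")))
  }
  pair <- paste(map$edges$source, map$edges$target, sep = "\r")
  if (anyDuplicated(pair)) note("duplicate directed (source, target) pair")
  if (!all(map$edges$review_status %in% review_statuses())) {
    note("illegal review status")
  }
  for (i in seq_len(nrow(map$edges))) {
    ev <- map$edges$evidences[[i]]
    eid <- map$edges$edge_id[i]
    if (nrow(ev) == 0) note(paste0("edge ", eid, " has no evidence"))
    if (map$edges$weight[i] != dplyr::n_distinct(ev$pmid)) {
      note(paste0("edge ", eid, " weight inconsistent with distinct pmids"))
    }
    if (map$edges$edge_class[i] != aggregate_categories(ev$evidence_category)) {
      note(paste0("edge ", eid, " class inconsistent with evidence"))
    }
  }
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid disease map:\n",
                        paste0("  - ", problems, collapse = "\n")),
                 class = "dm_input_error")
  }
  invisible(map)
}

#' Build a disease map from entities and categorized evidence
#'
#' Aggregates sentence-level evidence into one directed edge per
#' (source, target) pair. The edge class is the multiset aggregation of the
#' evidence categories (conflicting directional evidence across publications
#' yields `incoherent`); the edge weight is the number of *distinct* PubMed
#' IDs supporting it, the quantity rendered as edge thickness by viewers.
#' Compartments are created from the distinct localization names. Positions
#' and compartment bounds are all zero until [assign_layout()] runs.
#'
#' @param entities Entity tibble from [read_entities()].
#' @param evidence Evidence tibble from [categorize_evidence()].
#' @param source_files Optional character vector recorded in provenance.
#' @param lexicon_id Identifier of the lexicon used, recorded in provenance.
#' @param clock Zero-argument function returning a POSIXct; injectable so
#'   exports can be reproduced byte-for-byte.
#' @return A `disease_map` object.
#' @export
#' @examples
#' ents <- tibble::tibble(
#'   entity_id = c("E1", "E2"), label = c("CFTR", "NHERF1"),
#'   compartment = c("membrane", "cytoplasm")
#' )
#' ev <- categorize_evidence(tibble::tibble(
#'   source_id = "E1", target_id = "E2", pmid = c(111L, 222L),
#'   year = c(2001L, 2005L), sentence = c("s1", "s2"),
#'   verbs = list("activates", "activates")
#' ))
#' m <- build_map(ents, ev)
#' m$edges$weight
build_map <- function(entities, evidence, source_files = character(0),
                      lexicon_id = "default", clock = Sys.time) {
  stopifnot(is.data.frame(entities), is.data.frame(evidence))
  need <- c("source_id", "target_id", "pmid", "year", "sentence",
            "verbs", "verb_categories", "evidence_category")
  miss <- setdiff(need, names(evidence))
  if (length(miss) > 0) {
    rlang::abort(paste0("evidence lacks column(s) ",
                        paste(miss, collapse = ", "),
                        "; run categorize_evidence() first"),
                 class = "dm_input_error")
  }

  comp_names <- sort(unique(entities$compartment))
  compartments <- tibble::tibble(
    compartment_id = comp_names, label = comp_names,
    x = 0, y = 0, width = 0, height = 0
  )
  nodes <- tibble::tibble(
    node_id = entities$entity_id, label = entities$label,
    parent = entities$compartment, x = 0, y = 0,
    extra = rep(list(list()), nrow(entities))
  )

  ev <- tibble::as_tibble(evidence)
  attr(ev, "ingest_report") <- NULL
  grouped <- ev |>
    dplyr::mutate(.pair = paste(.data$source_id, .data$target_id,
                                sep = "\r")) |>
    dplyr::arrange(.data$source_id, .data$target_id)
  edges <- grouped |>
    tidyr::nest(evidences = c("pmid", "year", "sentence", "verbs",
                              "verb_categories", "evidence_category")) |>
    dplyr::select(-".pair")
  edges <- edges |>
    dplyr::mutate(
      edge_id = paste0(.data$source_id, "->", .data$target_id),
      weight = purrr::map_int(.data$evidences,
                              ~ dplyr::n_distinct(.x$pmid)),
      edge_class = purrr::map_chr(.data$evidences,
                                  ~ aggregate_categories(.x$evidence_category)),
      review_status = "unreviewed",
      evidences = purrr::map(.data$evidences, function(x) {
        attr(x, "ingest_report") <- NULL
        x
      })
    ) |>
    dplyr::select(edge_id, source = "source_id", target = "target_id",
                  "edge_class", "weight", "review_status", "evidences")
  edges$extra <- rep(list(list()), nrow(edges))

  meta <- list(
    created = format(clock(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    source_files = source_files,
    lexicon = lexicon_id,
    tool = "dmcurate",
    version = as.character(utils::packageVersion("dmcurate")),
    audit = empty_audit()
  )
  map <- new_disease_map(compartments, nodes, edges, meta)
  validate_disease_map(map)
  map
}

#' Layout configuration for the compartmental cellular layout
#'
#' @param spacing Grid cell size in layout units between node centres.
#' @param margin Padding between a band border and the outermost grid cells.
#' @param band_gap Vertical gap between consecutive compartment bands.
#' @param order Canonical top-to-bottom compartment order (matched
#'   case-insensitively against compartment labels); unknown compartments
#'   are appended alphabetically below.
#' @return A `dm_layout_config` list.
#' @export
layout_config <- function(spacing = 80, margin = 30, band_gap = 10,
                          order = canonical_compartment_order()) {
  stopifnot(spacing > 0, margin >= 0, band_gap >= 0)
  structure(list(spacing = spacing, margin = margin, band_gap = band_gap,
                 order = stringr::str_to_lower(order)),
            class = "dm_layout_config")
}

#' Canonical outside-in compartment order
#'
#' The default top-to-bottom order of compartment bands, mimicking a section
#' through a cell: extracellular space at the top, nucleus at the bottom.
#'
#' @return Character vector of compartment names.
#' @export
canonical_compartment_order <- function() {
  c("extracellular", "plasma membrane", "membrane", "cytoplasm",
    "endoplasmic reticulum", "golgi apparatus", "mitochondrion",
    "endosome", "lysosome", "peroxisome", "nucleus")
}

#' Assign a deterministic banded cellular layout
#'
#' Compartments become vertically stacked horizontal bands in canonical
#' cellular order (extracellular at the top, nucleus at the bottom; unknown
#' compartments appended alphabetically below). Nodes are placed on a grid
#' inside their band, ordered by node id; a band with more nodes than one
#' row holds simply grows additional rows, never errors. The layout is pure
#' arithmetic: the same map and config always give byte-identical output.
#' Coordinates follow the screen convention (x rightward, y downward,
#' origin top-left) and are rounded to two decimals.
#'
#' @param map A `disease_map`.
#' @param config A [layout_config()].
#' @return The map with node positions and compartment bounds set; every
#'   node lies strictly inside its parent band and no two nodes are closer
#'   than the grid spacing.
#' @export
assign_layout <- function(map, config = layout_config()) {
  stopifnot(inherits(map, "disease_map"),
            inherits(config, "dm_layout_config"))
  comps <- map$compartments
  rank <- match(stringr::str_to_lower(comps$label), config$order)
  ord <- order(is.na(rank), dplyr::coalesce(rank, 0L), comps$label)
  comps <- comps[ord, ]

  counts <- purrr::map_int(comps$compartment_id,
                           ~ sum(map$nodes$parent == .x))
  ncols <- max(1L, ceiling(sqrt(max(counts, 1L))))
  width <- 2 * config$margin + ncols * config$spacing

  y0 <- 0
  nodes <- map$nodes
  for (i in seq_len(nrow(comps))) {
    n <- counts[i]
    rows <- max(1L, ceiling(n / ncols))
    height <- 2 * config$margin + rows * config$spacing
    comps$x[i] <- 0
    comps$y[i] <- round(y0, 2)
    comps$width[i] <- round(width, 2)
    comps$height[i] <- round(height, 2)

    idx <- which(nodes$parent == comps$compartment_id[i])
    idx <- idx[order(nodes$node_id[idx])]
    if (length(idx) > 0) {
      k <- seq_along(idx) - 1L
      col <- k %% ncols
      row <- k %/% ncols
      nodes$x[idx] <- round(config$margin + (col + 0.5) * config$spacing, 2)
      nodes$y[idx] <- round(y0 + config$margin + (row + 0.5) * config$spacing, 2)
    }
    y0 <- y0 + height + config$band_gap
  }
  map$compartments <- comps
  map$nodes <- nodes
  map
}

#' @export
print.disease_map <- function(x, ...) {
  cat("<disease_map> ", nrow(x$nodes), " nodes in ",
      nrow(x$compartments), " compartments, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges) > 0) {
    cls <- table(factor(x$edges$edge_class, levels = interaction_categories()))
    cat("  classes: ",
        paste0(names(cls), "=", as.integer(cls), collapse = " "), "\n",
        sep = "")
    rev <- table(factor(x$edges$review_status, levels = review_statuses()))
    cat("  review:  ",
        paste0(names(rev), "=", as.integer(rev), collapse = " "), "\n",
        sep = "")
  }
  cat("  created ", x$meta$created, " (lexicon: ", x$meta$lexicon, ")\n",
      sep = "")
  invisible(x)
}
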