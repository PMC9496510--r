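node_data_keys <- c("id", "label", "parent")
compartment_data_keys <- c("id", "label", "bounds")
edge_data_keys <- c("id", "source", "target", "weight", "review_status",
                    "references")
reference_keys <- c("pmid", "year", "sentence", "verbs", "verb_categories")

layout_missing <- function(map) {
  nrow(map$nodes) > 1 && all(map$nodes$x == 0) && all(map$nodes$y == 0)
}

json_num <- function(x) round(unname(x), 2)

reference_list <- function(ev) {
  purrr::pmap(ev, function(pmid, year, sentence, verbs, verb_categories,
                           evidence_category) {
    list(pmid = as.integer(pmid), year = as.integer(year),
         sentence = sentence,
         verbs = I(as.character(verbs)),
         verb_categories = I(as.character(verb_categories)))
  })
}

#' Serialize a disease map to viewer graph JSON
#'
#' The document is an object with an `elements` list (compartments first,
#' serialized as parentless container nodes carrying their band rectangle,
#' then entity nodes with `parent` set, then edges) and a `meta` provenance
#' object including the review audit trail. Every element has `group` and
#' `data`; node-group elements carry `position`, edge elements carry
#' `classes` and per-reference evidence (PubMed id, year, sentence, verbs
#' and their categorization). Key order is fixed and coordinates carry two
#' decimals, so serialize-parse-serialize is byte-identical. Unknown `data`
#' keys read by [from_map_json()] are re-emitted untouched.
#'
#' @param map A `disease_map` with layout assigned.
#' @return A JSON string (class `json`).
#' @export
to_map_json <- function(map) {
  validate_disease_map(map)
  if (layout_missing(map)) {
    rlang::abort(
      "map has no layout (all node positions are zero); run assign_layout() first",
      class = "dm_input_error"
    )
  }
  comp_elems <- purrr::pmap(map$compartments,
                            function(compartment_id, label, x, y, width,
                                     height) {
    list(
      group = "nodes",
      data = list(id = compartment_id, label = label,
                  bounds = json_num(c(x, y, width, height))),
      position = list(x = json_num(x + width / 2),
                      y = json_num(y + height / 2))
    )
  })
  node_elems <- purrr::pmap(map$nodes,
                            function(node_id, label, parent, x, y, extra) {
    el <- list(
      group = "nodes",
      data = c(list(id = node_id, label = label, parent = parent), extra),
      position = list(x = json_num(x), y = json_num(y))
    )
    el
  })
  edge_elems <- purrr::pmap(map$edges,
                            function(edge_id, source, target, edge_class,
                                     weight, review_status, evidences,
                                     extra) {
    list(
      group = "edges",
      data = c(list(id = edge_id, source = source, target = target,
                    weight = as.integer(weight),
                    review_status = review_status,
                    references = reference_list(evidences)),
               extra),
      classes = edge_class
    )
  })
  audit <- purrr::pmap(map$meta$audit,
                       function(edge_id, status, note, timestamp) {
    list(edge_id = edge_id, status = status,
         note = if (is.na(note)) NULL else note,
         timestamp = timestamp)
  })
  doc <- list(
    elements = c(comp_elems, node_elems, edge_elems),
    meta = list(
      created = map$meta$created,
      source_files = I(as.character(map$meta$source_files)),
      lexicon = map$meta$lexicon,
      tool = map$meta$tool,
      version = map$meta$version,
      audit = audit
    )
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2,
                   null = "null")
}

#' Write a disease map to a JSON file
#'
#' @param map A `disease_map` with layout assigned.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_json <- function(map, path) {
  writeLines(to_map_json(map), path, useBytes = TRUE)
  invisible(path)
}

chr0 <- function(x) if (is.null(x)) character(0) else as.character(unlist(x))

#' Validate a map JSON document against the packaged schema constraints
#'
#' Implements the constraints stated by the shipped schema
#' (`system.file("schema", "map-elements.schema.json", package =
#' "dmcurate")`): required keys per element group, legal edge classes and
#' review statuses, complete reference entries, and referential integrity of
#' parents and edge endpoints. Problem messages name the offending element
#' id and the missing or illegal key.
#'
#' @param document A JSON string, a file path to one, or an already-parsed
#'   list.
#' @return Character vector of problems; empty when the document is valid.
#' @export
validate_map_json <- function(document) {
  doc <- parse_json_document(document)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!is.list(doc) || !is.list(doc$elements)) {
    return("document must be an object with an 'elements' list")
  }
  if (!is.list(doc$meta)) note("document lacks a 'meta' object")

  comp_ids <- character(0)
  node_ids <- character(0)
  for (el in doc$elements) {
    id <- el$data$id
    tag <- if (is.null(id)) "<missing id>" else id
    if (is.null(el$group) || !el$group %in% c("nodes", "edges")) {
      note(paste0("element ", tag, ": 'group' must be \"nodes\" or \"edges\""))
      next
    }
    if (is.null(el$data) || is.null(id) || !nzchar(id)) {
      note(paste0("element ", tag, ": missing 'data' or 'data.id'"))
      next
    }
    if (el$group == "nodes") {
      if (is.null(el$position) || is.null(el$position$x) ||
          is.null(el$position$y)) {
        note(paste0("element ", id, ": node lacks 'position' with x and y"))
      }
      if (is.null(el$data$label)) {
        note(paste0("element ", id, ": node lacks 'label'"))
      }
      if (!is.null(el$data$bounds)) {
        b <- unlist(el$data$bounds)
        if (length(b) != 4 || !is.numeric(b) || b[3] <= 0 || b[4] <= 0) {
          note(paste0("element ", id,
                      ": 'bounds' must be [x, y, width>0, height>0]"))
        }
        comp_ids <- c(comp_ids, id)
      } else if (is.null(el$data$parent)) {
        note(paste0("element ", id,
                    ": node lacks 'parent' (and is not a compartment)"))
      } else {
        node_ids <- c(node_ids, id)
      }
    } else {
      if (is.null(el$classes) ||
          !el$classes %in% interaction_categories()) {
        note(paste0("element ", id, ": edge 'classes' must be one of ",
                    paste(interaction_categories(), collapse = "/")))
      }
      for (key in c("source", "target", "weight", "review_status",
                    "references")) {
        if (is.null(el$data[[key]])) {
          note(paste0("element ", id, ": edge lacks '", key, "'"))
        }
      }
      if (!is.null(el$data$review_status) &&
          !el$data$review_status %in% review_statuses()) {
        note(paste0("element ", id, ": illegal review_status '",
                    el$data$review_status, "'"))
      }
      refs <- el$data$references
      if (is.list(refs)) {
        if (length(refs) == 0) {
          note(paste0("element ", id, ": 'references' must be non-empty"))
        }
        for (r in refs) {
          miss <- setdiff(reference_keys, names(r))
          if (length(miss) > 0) {
            note(paste0("element ", id, ": reference lacks '",
                        paste(miss, collapse = "', '"), "'"))
          } else if (length(chr0(r$verbs)) != length(chr0(r$verb_categories))) {
            note(paste0("element ", id,
                        ": verbs and verb_categories differ in length"))
          }
        }
      }
    }
  }
  # referential integrity
  for (el in doc$elements) {
    id <- el$data$id
    if (identical(el$group, "nodes") && !is.null(el$data$parent) &&
        is.null(el$data$bounds) && !el$data$parent %in% comp_ids) {
      note(paste0("element ", id, ": parent '", el$data$parent,
                  "' is not a compartment in the document"))
    }
    if (identical(el$group, "edges")) {
      for (key in c("source", "target")) {
        ref <- el$data[[key]]
        if (!is.null(ref) && !ref %in% node_ids) {
          note(paste0("element ", id, ": ", key, " '", ref,
                      "' is not a node in the document"))
        }
      }
    }
  }
  problems
}

parse_json_document <- function(document) {
  if (is.list(document)) return(document)
  stopifnot(is.character(document))
  txt <- paste(document, collapse = "\n")
  if (!grepl("^\\s*[{\\[]", txt) && file.exists(document[1])) {
    txt <- paste(readLines(document[1], warn = FALSE), collapse = "\n")
  }
  tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(paste0("not parseable as JSON: ", conditionMessage(e)),
                   class = "dm_input_error")
    }
  )
}

#' Reconstruct a disease map from viewer graph JSON
#'
#' Inverse of [to_map_json()]: `from_map_json(to_map_json(m))` equals `m`
#' field by field, including review statuses, the audit trail, and every
#' evidence sentence. The document is validated first; schema violations
#' abort with messages naming the offending element. Unknown `data` keys
#' are preserved opaquely and re-emitted on the next export.
#'
#' @param document A JSON string, file path, or parsed list.
#' @return A `disease_map`.
#' @export
from_map_json <- function(document) {
  doc <- parse_json_document(document)
  problems <- validate_map_json(doc)
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid map document:\n",
                        paste0("  - ", problems, collapse = "\n")),
                 class = "dm_input_error")
  }
  comps <- list(); nodes <- list(); edges <- list()
  for (el in doc$elements) {
    if (el$group == "nodes" && !is.null(el$data$bounds)) {
      b <- as.numeric(unlist(el$data$bounds))
      comps[[length(comps) + 1]] <- tibble::tibble(
        compartment_id = el$data$id, label = el$data$label,
        x = b[1], y = b[2], width = b[3], height = b[4]
      )
    } else if (el$group == "nodes") {
      extra <- el$data[setdiff(names(el$data), node_data_keys)]
      if (length(extra) == 0) extra <- list()
      nodes[[length(nodes) + 1]] <- tibble::tibble(
        node_id = el$data$id, label = el$data$label,
        parent = el$data$parent,
        x = as.numeric(el$position$x), y = as.numeric(el$position$y),
        extra = list(extra)
      )
    } else {
      ev <- purrr::map_dfr(el$data$references, function(r) {
        vc <- chr0(r$verb_categories)
        agg <- aggregate_categories(vc)
        tibble::tibble(
          pmid = as.integer(r$pmid), year = as.integer(r$year),
          sentence = r$sentence, verbs = list(chr0(r$verbs)),
          verb_categories = list(vc),
          evidence_category = if (agg == "incoherent") "undefined" else agg
        )
      })
      extra <- el$data[setdiff(names(el$data), edge_data_keys)]
      if (length(extra) == 0) extra <- list()
      edges[[length(edges) + 1]] <- tibble::tibble(
        edge_id = el$data$id, source = el$data$source,
        target = el$data$target, edge_class = el$classes,
        weight = as.integer(el$data$weight),
        review_status = el$data$review_status,
        evidences = list(ev), extra = list(extra)
      )
    }
  }
  audit <- purrr::map_dfr(doc$meta$audit, function(a) {
    tibble::tibble(
      edge_id = a$edge_id, status = a$status,
      note = if (is.null(a$note)) NA_character_ else a$note,
      timestamp = a$timestamp
    )
  })
  if (nrow(audit) == 0) audit <- empty_audit()
  meta <- list(
    created = doc$meta$created,
    source_files = chr0(doc$meta$source_files),
    lexicon = doc$meta$lexicon,
    tool = doc$meta$tool,
    version = doc$meta$version,
    audit = audit
  )
  empty_nodes <- tibble::tibble(node_id = character(0), label = character(0),
                                parent = character(0), x = numeric(0),
                                y = numeric(0), extra = list())
  empty_comps <- tibble::tibble(compartment_id = character(0),
                                label = character(0), x = numeric(0),
                                y = numeric(0), width = numeric(0),
                                height = numeric(0))
  empty_edges <- tibble::tibble(edge_id = character(0), source = character(0),
                                target = character(0),
                                edge_class = character(0),
                                weight = integer(0),
                                review_status = character(0),
                                evidences = list(), extra = list())
  map <- new_disease_map(
    if (length(comps) > 0) dplyr::bind_rows(comps) else empty_comps,
    if (length(nodes) > 0) dplyr::bind_rows(nodes) else empty_nodes,
    if (length(edges) > 0) dplyr::bind_rows(edges) else empty_edges,
    meta
  )
  validate_disease_map(map)
  map
}

#' Read a disease map from a JSON file
#'
#' @param path Path to a map JSON file written by [write_map_json()].
#' @return A `disease_map`.
#' @export
read_map_json <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("map file not found: ", path),
                 class = "dm_input_error")
  }
  from_map_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
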