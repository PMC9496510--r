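sbgn_ns <- "http://sbgn.org/libsbgn/0.2"
dm_ext_ns <- "https://dmcurate.invalid/ns"

arc_class_for <- function(edge_class) {
  switch(edge_class,
         activate = "positive influence",
         inhibit = "negative influence",
         "unknown influence")
}

#' Serialize a disease map as an SBGN-ML activity-flow document
#'
#' Compartments become compartment glyphs with their band rectangles as
#' bounding boxes; entities become biological-activity glyphs centred at
#' their layout positions; edges become arcs: `positive influence` for
#' activating, `negative influence` for inhibiting, and `unknown influence`
#' otherwise. Because the activity-flow vocabulary has no neutral, undefined
#' or incoherent arc, the original five-way class is preserved losslessly in
#' an `extension` annotation on each arc.
#'
#' @param map A `disease_map` with layout assigned.
#' @param node_w,node_h Activity glyph size in layout units.
#' @return An `xml_document`.
#' @export
to_sbgnml <- function(map, node_w = 60, node_h = 30) {
  validate_disease_map(map)
  if (layout_missing(map)) {
    rlang::abort(
      "map has no layout (all node positions are zero); run assign_layout() first",
      class = "dm_input_error"
    )
  }
  doc <- xml2::xml_new_root("sbgn", xmlns = sbgn_ns)
  sbgn_map <- xml2::xml_add_child(doc, "map", language = "activity flow")

  for (i in seq_len(nrow(map$compartments))) {
    c_ <- map$compartments[i, ]
    g <- xml2::xml_add_child(sbgn_map, "glyph", id = c_$compartment_id,
                             class = "compartment")
    xml2::xml_add_child(g, "label", text = c_$label)
    xml2::xml_add_child(g, "bbox", x = format(c_$x), y = format(c_$y),
                        w = format(c_$width), h = format(c_$height))
  }
  for (i in seq_len(nrow(map$nodes))) {
    n <- map$nodes[i, ]
    g <- xml2::xml_add_child(sbgn_map, "glyph", id = n$node_id,
                             class = "biological activity",
                             compartmentRef = n$parent)
    xml2::xml_add_child(g, "label", text = n$label)
    xml2::xml_add_child(g, "bbox",
                        x = format(round(n$x - node_w / 2, 2)),
                        y = format(round(n$y - node_h / 2, 2)),
                        w = format(node_w), h = format(node_h))
  }
  for (i in seq_len(nrow(map$edges))) {
    e <- map$edges[i, ]
    src <- map$nodes[match(e$source, map$nodes$node_id), ]
    tgt <- map$nodes[match(e$target, map$nodes$node_id), ]
    a <- xml2::xml_add_child(sbgn_map, "arc", id = e$edge_id,
                             class = arc_class_for(e$edge_class),
                             source = e$source, target = e$target)
    ext <- xml2::xml_add_child(a, "extension")
    xml2::xml_add_child(ext, "interactionClass", value = e$edge_class,
                        weight = format(e$weight), xmlns = dm_ext_ns)
    xml2::xml_add_child(a, "start", x = format(src$x), y = format(src$y))
    xml2::xml_add_child(a, "end", x = format(tgt$x), y = format(tgt$y))
  }
  doc
}

#' Write a disease map as SBGN-ML
#'
#' @param map A `disease_map` with layout assigned.
#' @param path Output file path.
#' @param ... Passed to [to_sbgnml()].
#' @return `path`, invisibly.
#' @export
write_sbgnml <- function(map, path, ...) {
  xml2::write_xml(to_sbgnml(map, ...), path)
  invisible(path)
}

#' Parse and structurally validate an SBGN-ML activity-flow document
#'
#' A reader independent of [to_sbgnml()]: it parses raw XML from any source
#' and checks SBGN-ML 0.2 structural rules -- the namespace, a `map`
#' element, glyphs with ids, classes and bounding boxes, and arcs whose
#' `source`/`target` reference glyph ids in the document. Violations abort
#' with a message naming the offending glyph or arc.
#'
#' @param x Path to an SBGN-ML file, an XML string, or an `xml_document`.
#' @return A list of two tibbles: `glyphs` (id, class, compartmentRef,
#'   label, bbox columns) and `arcs` (id, class, source, target).
#' @export
read_sbgnml <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    xml2::read_xml(as.character(x))  # re-parse: full independence from the writer
  } else {
    xml2::read_xml(x)
  }
  ns_urls <- unique(unname(unlist(xml2::xml_ns(doc))))
  if (!sbgn_ns %in% ns_urls) {
    rlang::abort("document is not in the SBGN-ML 0.2 namespace",
                 class = "dm_input_error")
  }
  map_node <- xml2::xml_find_first(doc, "./*[local-name()='map']")
  if (inherits(map_node, "xml_missing")) {
    rlang::abort("SBGN-ML document has no <map> element",
                 class = "dm_input_error")
  }
  glyph_nodes <- xml2::xml_find_all(map_node, "./*[local-name()='glyph']")
  glyphs <- purrr::map_dfr(glyph_nodes, function(g) {
    id <- xml2::xml_attr(g, "id")
    bbox <- xml2::xml_find_first(g, "./*[local-name()='bbox']")
    if (inherits(bbox, "xml_missing")) {
      rlang::abort(paste0("glyph ", id, " lacks a bbox"),
                   class = "dm_input_error")
    }
    tibble::tibble(
      id = id,
      class = xml2::xml_attr(g, "class"),
      compartmentRef = xml2::xml_attr(g, "compartmentRef"),
      label = xml2::xml_attr(
        xml2::xml_find_first(g, "./*[local-name()='label']"), "text"),
      x = as.numeric(xml2::xml_attr(bbox, "x")),
      y = as.numeric(xml2::xml_attr(bbox, "y")),
      w = as.numeric(xml2::xml_attr(bbox, "w")),
      h = as.numeric(xml2::xml_attr(bbox, "h"))
    )
  })
  if (nrow(glyphs) > 0 &&
      (anyNA(glyphs$id) || anyDuplicated(glyphs$id))) {
    rlang::abort("glyph ids must be present and unique",
                 class = "dm_input_error")
  }
  arc_nodes <- xml2::xml_find_all(map_node, "./*[local-name()='arc']")
  arcs <- purrr::map_dfr(arc_nodes, function(a) {
    tibble::tibble(
      id = xml2::xml_attr(a, "id"),
      class = xml2::xml_attr(a, "class"),
      source = xml2::xml_attr(a, "source"),
      target = xml2::xml_attr(a, "target")
    )
  })
  glyph_ids <- if (nrow(glyphs) > 0) glyphs$id else character(0)
  if (nrow(arcs) > 0) {
    bad <- !(arcs$source %in% glyph_ids) | !(arcs$target %in% glyph_ids)
    if (any(bad)) {
      rlang::abort(paste0("arc(s) referencing unknown glyphs: ",
                          paste(arcs$id[bad], collapse = ", ")),
                   class = "dm_input_error")
    }
  }
  if (nrow(glyphs) > 0) {
    comp_ids <- glyphs$id[glyphs$class == "compartment"]
    dangling <- !is.na(glyphs$compartmentRef) &
      !(glyphs$compartmentRef %in% comp_ids)
    if (any(dangling)) {
      rlang::abort(paste0("glyph(s) with unknown compartmentRef: ",
                          paste(glyphs$id[dangling], collapse = ", ")),
                   class = "dm_input_error")
    }
  }
  list(glyphs = glyphs, arcs = arcs)
}
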