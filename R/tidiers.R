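#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a disease map into a flat tibble
#'
#' @param x A `disease_map`.
#' @param what One of `"edges"` (default; one row per edge), `"nodes"`,
#'   `"compartments"`, or `"evidence"` (one row per sentence-level mention,
#'   with verbs collapsed to a `;`-joined string).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy disease_map
#' @export
tidy.disease_map <- function(x, what = c("edges", "nodes", "compartments",
                                         "evidence"), ...) {
  what <- match.arg(what)
  switch(what,
    edges = dplyr::select(x$edges, "edge_id", "source", "target",
                          "edge_class", "weight", "review_status"),
    nodes = dplyr::select(x$nodes, "node_id", "label", "parent", "x", "y"),
    compartments = x$compartments,
    evidence = x$edges |>
      dplyr::select("edge_id", "evidences") |>
      tidyr::unnest("evidences") |>
      dplyr::mutate(
        verbs = purrr::map_chr(.data$verbs, paste, collapse = ";"),
        verb_categories = purrr::map_chr(.data$verb_categories, paste,
                                         collapse = ";")
      )
  )
}

#' One-row summary of a disease map
#'
#' @param x A `disease_map`.
#' @param ... Unused.
#' @return A one-row tibble: node/compartment/edge/evidence counts, a count
#'   per edge class, and the number of reviewed edges.
#' @method glance disease_map
#' @export
glance.disease_map <- function(x, ...) {
  cls <- table(factor(x$edges$edge_class, levels = interaction_categories()))
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_compartments = nrow(x$compartments),
    n_edges = nrow(x$edges),
    n_evidence = sum(purrr::map_int(x$edges$evidences, nrow)),
    n_activate = as.integer(cls[["activate"]]),
    n_inhibit = as.integer(cls[["inhibit"]]),
    n_neutral = as.integer(cls[["neutral"]]),
    n_undefined = as.integer(cls[["undefined"]]),
    n_incoherent = as.integer(cls[["incoherent"]]),
    n_reviewed = sum(x$edges$review_status != "unreviewed")
  )
}

#' Edge-class colours used by viewers
#'
#' Activating edges are green, inhibiting red, neutral blue, undefined grey,
#' and incoherent (conflicting directional evidence) brown.
#'
#' @return Named character vector of colours.
#' @export
edge_class_colours <- function() {
  c(activate = "#1a9641", inhibit = "#d7191c", neutral = "#2b83ba",
    undefined = "#808080", incoherent = "#8c510a")
}

#' Plot a disease map in its cellular layout
#'
#' Compartment bands as rectangles, entities as labelled points, and edges
#' as segments coloured by class (green activate, red inhibit, blue
#' neutral, grey undefined, brown incoherent) with line width proportional
#' to the distinct-publication weight.
#'
#' @param object A `disease_map` with layout assigned.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disease_map
#' @export
autoplot.disease_map <- function(object, ...) {
  comps <- object$compartments
  nodes <- object$nodes
  edges <- dplyr::mutate(
    tidy(object, "edges"),
    x = nodes$x[match(.data$source, nodes$node_id)],
    y = nodes$y[match(.data$source, nodes$node_id)],
    xend = nodes$x[match(.data$target, nodes$node_id)],
    yend = nodes$y[match(.data$target, nodes$node_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = comps,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$width,
                   ymin = .data$y, ymax = .data$y + .data$height),
      fill = "grey95", colour = "grey40"
    ) +
    ggplot2::geom_text(
      data = comps,
      ggplot2::aes(x = .data$x + 4, y = .data$y + 10, label = .data$label),
      hjust = 0, size = 3, colour = "grey30"
    ) +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$edge_class,
                   linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt")), alpha = 0.8
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y - 8,
                                    label = .data$label), size = 2.5) +
    ggplot2::scale_colour_manual(values = edge_class_colours(),
                                 name = "class") +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 2),
                                        name = "publications") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
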