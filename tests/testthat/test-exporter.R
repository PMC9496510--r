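test_that("the JSON document has the documented element structure", {
  m <- tiny_map()
  doc <- jsonlite::fromJSON(to_map_json(m), simplifyVector = FALSE)
  els <- doc$elements
  # compartments first (with bounds), then nodes, then edges
  expect_equal(purrr::map_chr(els, "group"),
               c("nodes", "nodes", "nodes", "nodes", "nodes",
                 "edges", "edges"))
  comp <- els[[1]]
  expect_equal(length(comp$data$bounds), 4)
  node <- els[[3]]
  expect_true(!is.null(node$data$parent))
  expect_true(!is.null(node$position$x))
  edge <- els[[6]]
  expect_equal(edge$classes, "activate")
  expect_gte(length(edge$data$references), 1)
  ref <- edge$data$references[[1]]
  expect_named(ref, c("pmid", "year", "sentence", "verbs",
                      "verb_categories"))
  # evidence conservation: total references equal total evidence records
  n_refs <- sum(purrr::map_int(purrr::keep(els, ~ .x$group == "edges"),
                               ~ length(.x$data$references)))
  expect_equal(n_refs, sum(purrr::map_int(m$edges$evidences, nrow)))
})

test_that("serialize-parse-serialize is byte-identical and lossless over seeds", {
  for (seed in 1:10) {
    fx <- synth_map(seed, n_entities = 8, n_edges = 12)
    m <- fx$map
    m <- apply_review(m, m$edges$edge_id[1], "accepted", note = "n",
                      timestamp = "2026-01-02T00:00:00Z")
    j1 <- to_map_json(m)
    m2 <- from_map_json(j1)
    expect_identical(unclass(m2), unclass(m))
    j2 <- to_map_json(m2)
    expect_identical(as.character(j1), as.character(j2))
  }
})

test_that("exported documents validate; broken documents name the offender", {
  m <- tiny_map()
  expect_length(validate_map_json(to_map_json(m)), 0)
  doc <- jsonlite::fromJSON(to_map_json(m), simplifyVector = FALSE)
  # point an edge at a missing node
  i_edge <- which(purrr::map_chr(doc$elements, "group") == "edges")[1]
  doc$elements[[i_edge]]$data$source <- "ghost"
  problems <- validate_map_json(doc)
  expect_match(problems, "ghost", all = FALSE)
  expect_match(problems, doc$elements[[i_edge]]$data$id, fixed = TRUE,
               all = FALSE)
  expect_error(from_map_json(doc), "ghost", class = "dm_input_error")
  # drop a required reference key
  doc2 <- jsonlite::fromJSON(to_map_json(m), simplifyVector = FALSE)
  doc2$elements[[i_edge]]$data$references[[1]]$pmid <- NULL
  expect_match(validate_map_json(doc2), "pmid", all = FALSE)
})

test_that("an empty element list is a valid empty map", {
  doc <- list(elements = list(),
              meta = list(created = "c", source_files = list(),
                          lexicon = "default", tool = "dmcurate",
                          version = "0.1.0", audit = list()))
  m <- from_map_json(doc)
  expect_equal(nrow(m$edges), 0)
  expect_equal(nrow(m$nodes), 0)
})

test_that("unknown data keys survive a round trip opaquely", {
  m <- tiny_map()
  doc <- jsonlite::fromJSON(to_map_json(m), simplifyVector = FALSE)
  i_edge <- which(purrr::map_chr(doc$elements, "group") == "edges")[1]
  doc$elements[[i_edge]]$data$custom_score <- 0.7
  m2 <- from_map_json(doc)
  j <- to_map_json(m2)
  doc2 <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  expect_equal(doc2$elements[[i_edge]]$data$custom_score, 0.7)
})

test_that("serialization refuses a map that never got a layout", {
  m <- tiny_map(layout = FALSE)
  expect_error(to_map_json(m), "assign_layout", class = "dm_input_error")
  expect_error(to_sbgnml(m), "assign_layout", class = "dm_input_error")
})

test_that("review CSV rows are sorted, statuses spelled exactly, pmids ascending", {
  m <- tiny_map()
  m <- apply_review(m, "E2->E3", "further_inspection_needed",
                    timestamp = "t")
  csv <- to_review_csv(m)
  expect_equal(csv$edge_id, sort(csv$edge_id))
  expect_equal(csv$review_status, c("unreviewed",
                                    "further_inspection_needed"))
  expect_equal(csv$pmids[1], "111;222")
  expect_equal(csv$source_label[1], "CFTR")
  dir <- withr::local_tempdir()
  write_review_csv(m, file.path(dir, "r.csv"))
  back <- readr::read_csv(file.path(dir, "r.csv"), show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  # empty map gives a header-only file
  write_review_csv(filter_edges(m, "neutral"), file.path(dir, "empty.csv"))
  expect_length(readLines(file.path(dir, "empty.csv")), 1)
})

test_that("SBGN-ML output is structurally valid activity flow with class-mapped arcs", {
  m <- tiny_map()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.sbgn")
  write_sbgnml(m, p)
  parsed <- read_sbgnml(p)
  expect_equal(sum(parsed$glyphs$class == "compartment"),
               nrow(m$compartments))
  expect_equal(sum(parsed$glyphs$class == "biological activity"),
               nrow(m$nodes))
  expect_equal(nrow(parsed$arcs), nrow(m$edges))
  expect_equal(parsed$arcs$class[parsed$arcs$id == "E1->E2"],
               "positive influence")
  expect_equal(parsed$arcs$class[parsed$arcs$id == "E2->E3"],
               "negative influence")
  # activity bbox inside the compartment bbox
  g <- parsed$glyphs
  act <- g[g$class == "biological activity", ]
  comp <- g[match(act$compartmentRef, g$id), ]
  expect_true(all(act$x >= comp$x & act$x + act$w <= comp$x + comp$w))
  expect_true(all(act$y >= comp$y & act$y + act$h <= comp$y + comp$h))
  # incoherent/neutral/undefined map to the generic influence arc but keep
  # their class in the extension annotation
  fx <- synth_map(4, n_entities = 8, n_edges = 12, conflict_rate = 0.25)
  doc <- to_sbgnml(fx$map)
  txt <- as.character(doc)
  expect_match(txt, "unknown influence")
  expect_match(txt, "interactionClass")
  parsed2 <- read_sbgnml(doc)
  expect_equal(nrow(parsed2$arcs), nrow(fx$map$edges))
})

test_that("the SBGN reader rejects structurally broken documents", {
  bad <- paste0('<sbgn xmlns="http://sbgn.org/libsbgn/0.2"><map ',
                'language="activity flow"><arc id="a" class="positive ',
                'influence" source="x" target="y"/></map></sbgn>')
  expect_error(read_sbgnml(bad), "unknown glyph", class = "dm_input_error")
  expect_error(read_sbgnml("<notsbgn/>"), class = "dm_input_error")
})
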