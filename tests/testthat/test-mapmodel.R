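test_that("evidence aggregates into directed, weighted, classed edges", {
  m <- tiny_map(layout = FALSE)
  expect_equal(nrow(m$edges), 2)
  e12 <- m$edges[m$edges$edge_id == "E1->E2", ]
  # three evidence rows but two distinct pmids
  expect_equal(e12$weight, 2L)
  expect_equal(nrow(e12$evidences[[1]]), 3)
  expect_equal(e12$edge_class, "activate")
  e23 <- m$edges[m$edges$edge_id == "E2->E3", ]
  expect_equal(e23$edge_class, "inhibit")
  expect_equal(e23$weight, 1L)
  expect_equal(m$edges$review_status, rep("unreviewed", 2))
})

test_that("direction matters: opposite pairs give distinct edges", {
  ents <- tiny_entities()
  rows <- tibble::tibble(
    source_id = c("E1", "E2"), target_id = c("E2", "E1"),
    pmid = c(1L, 2L), year = 2000L, sentence = "s",
    verbs = list("activates", "inhibits")
  )
  m <- build_map(ents, categorize_evidence(rows), clock = fixed_clock)
  expect_setequal(m$edges$edge_id, c("E1->E2", "E2->E1"))
  expect_setequal(m$edges$edge_class, c("activate", "inhibit"))
})

test_that("cross-publication conflict yields an incoherent edge", {
  rows <- tibble::tibble(
    source_id = "E1", target_id = "E2", pmid = c(1L, 2L),
    year = c(1992L, 2004L), sentence = c("s1", "s2"),
    verbs = list("activates", "inhibits")
  )
  m <- build_map(tiny_entities(), categorize_evidence(rows),
                 clock = fixed_clock)
  expect_equal(m$edges$edge_class, "incoherent")
  expect_equal(m$edges$weight, 2L)
})

test_that("build_map conserves evidence and matches a brute-force weight oracle", {
  for (seed in 1:10) {
    fx <- synth_map(seed, n_entities = 12, n_edges = 25)
    m <- fx$map
    ints <- fx$corpus$interactions
    # conservation: no evidence row dropped
    expect_equal(sum(purrr::map_int(m$edges$evidences, nrow)), nrow(ints))
    # independent distinct-pmid count per directed pair (base R)
    key <- paste(ints$source_id, ints$target_id, sep = "->")
    oracle <- vapply(split(ints$pmid, key),
                     function(p) length(unique(p)), integer(1))
    expect_equal(m$edges$weight[match(names(oracle), m$edges$edge_id)],
                 unname(oracle))
    expect_true(all(m$edges$weight >= 1))
    expect_true(all(m$edges$weight <=
                      purrr::map_int(m$edges$evidences, nrow)))
  }
})

test_that("layout places every node strictly inside its compartment band", {
  cfg <- layout_config()
  for (seed in c(5, 6)) {
    fx <- synth_map(seed, n_entities = 40, n_edges = 60,
                    n_compartments = 5)
    m <- fx$map
    comp <- m$compartments[match(m$nodes$parent,
                                 m$compartments$compartment_id), ]
    expect_true(all(m$nodes$x > comp$x & m$nodes$x < comp$x + comp$width))
    expect_true(all(m$nodes$y > comp$y & m$nodes$y < comp$y + comp$height))
    # no two nodes closer than half the grid spacing
    d <- as.matrix(stats::dist(cbind(m$nodes$x, m$nodes$y)))
    diag(d) <- Inf
    expect_true(min(d) >= cfg$spacing / 2)
  }
})

test_that("layout is deterministic and canonically ordered", {
  m1 <- tiny_map()
  m2 <- assign_layout(tiny_map(layout = FALSE))
  expect_identical(m1, m2)
  expect_identical(as.character(to_map_json(m1)),
                   as.character(to_map_json(m2)))
  # plasma membrane band above cytoplasm; unknown names go below known ones
  ents <- tibble::tibble(
    entity_id = c("A", "B", "C"), label = c("a", "b", "c"),
    compartment = c("nucleus", "extracellular", "zz_custom")
  )
  rows <- tibble::tibble(source_id = "A", target_id = "B", pmid = 1L,
                         year = 2000L, sentence = "s",
                         verbs = list("binds"))
  m <- assign_layout(build_map(ents, categorize_evidence(rows),
                               clock = fixed_clock))
  expect_equal(m$compartments$label, c("extracellular", "nucleus",
                                       "zz_custom"))
  expect_true(all(diff(m$compartments$y) > 0))
})

test_that("single node sits at the band grid origin; pairs get distinct spots", {
  ents <- tibble::tibble(entity_id = c("A", "B"), label = c("a", "b"),
                         compartment = "cytoplasm")
  rows <- tibble::tibble(source_id = "A", target_id = "B", pmid = 1L,
                         year = 2000L, sentence = "s", verbs = list("binds"))
  cfg <- layout_config(spacing = 100, margin = 10)
  m <- assign_layout(build_map(ents, categorize_evidence(rows),
                               clock = fixed_clock), cfg)
  expect_false(isTRUE(all.equal(m$nodes$x, rev(m$nodes$x))) &&
                 isTRUE(all.equal(m$nodes$y, rev(m$nodes$y))))
  expect_equal(m$nodes$x[1], 10 + 0.5 * 100)  # first grid cell centre
  expect_equal(m$nodes$y[1], 10 + 0.5 * 100)
})

test_that("map invariants are enforced", {
  m <- tiny_map()
  m$edges$weight[1] <- 99L
  expect_error(validate_disease_map(m), "weight", class = "dm_input_error")
  m <- tiny_map()
  m$nodes$parent[1] <- "not-a-compartment"
  expect_error(validate_disease_map(m), "not a compartment",
               class = "dm_input_error")
})

test_that("tidy, glance and autoplot views are consistent with the map", {
  m <- tiny_map()
  te <- tidy(m)
  expect_equal(nrow(te), nrow(m$edges))
  tv <- tidy(m, "evidence")
  expect_equal(nrow(tv), 4)
  g <- glance(m)
  expect_equal(g$n_edges, 2L)
  expect_equal(g$n_evidence, 4L)
  expect_equal(g$n_activate + g$n_inhibit + g$n_neutral + g$n_undefined +
                 g$n_incoherent, g$n_edges)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
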