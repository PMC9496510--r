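test_that("filtering keeps exactly the allowed classes above the weight threshold", {
  m <- tiny_map()  # one activate (weight 2), one inhibit (weight 1)
  fa <- filter_edges(m, classes = "activate")
  expect_equal(fa$edges$edge_id, "E1->E2")
  expect_equal(nrow(fa$nodes), nrow(m$nodes))  # isolated nodes kept
  fw <- filter_edges(m, min_publications = 2)
  expect_equal(fw$edges$edge_id, "E1->E2")
  expect_equal(nrow(filter_edges(m)$edges), 2)  # empty classes = identity
  expect_error(filter_edges(m, classes = "bogus"), class = "dm_input_error")
})

test_that("filtering matches a brute-force oracle, is idempotent and commutes", {
  classes_all <- interaction_categories()
  withr::with_seed(99, {
    for (i in 1:20) {
      fx <- synth_map(sample.int(10000, 1), n_entities = 10, n_edges = 20)
      m <- fx$map
      allowed <- sample(classes_all, sample(0:5, 1))
      min_pub <- sample(1:4, 1)
      f <- filter_edges(m, allowed, min_pub)
      keep <- vapply(seq_len(nrow(m$edges)), function(j) {
        e_cls <- m$edges$edge_class[j]
        (length(allowed) == 0 || e_cls %in% allowed) &&
          m$edges$weight[j] >= min_pub
      }, logical(1))
      expect_identical(f$edges$edge_id, m$edges$edge_id[keep])
      # idempotence
      expect_identical(filter_edges(f, allowed, min_pub)$edges, f$edges)
      # class-then-weight commutes with the combined filter
      two_step <- filter_edges(filter_edges(m, allowed), min_publications = min_pub)
      expect_identical(two_step$edges, f$edges)
    }
  })
})

test_that("cumulative snapshots restrict evidence and recompute weight and class", {
  m <- tiny_map()  # E1->E2 evidence at 1991/1993 (pmid 111) and 1996 (222)
  s95 <- snapshot_by_year(m, 1995)
  e <- s95$edges[s95$edges$edge_id == "E1->E2", ]
  expect_equal(e$weight, 1L)
  expect_equal(nrow(e$evidences[[1]]), 2)
  expect_false("E2->E3" %in% s95$edges$edge_id)  # only evidence is 2004
  s89 <- snapshot_by_year(m, 1989)
  expect_equal(nrow(s89$edges), 0)
})

test_that("an early-activate late-inhibit edge flips to incoherent at the later cutoff", {
  ents <- tiny_entities()
  rows <- tibble::tibble(
    source_id = "E1", target_id = "E2", pmid = c(10L, 20L),
    year = c(1992L, 2004L), sentence = c("s1", "s2"),
    verbs = list("activates", "inhibits")
  )
  m <- build_map(ents, categorize_evidence(rows), clock = fixed_clock)
  expect_equal(snapshot_by_year(m, 1995)$edges$edge_class, "activate")
  expect_equal(snapshot_by_year(m, 2005)$edges$edge_class, "incoherent")
})

test_that("snapshot series covers the requested years and nests monotonically", {
  fx <- synth_map(11, n_entities = 12, n_edges = 25)
  series <- snapshot_series(fx$map, 1990, 2020, 5)
  expect_equal(series$year, as.integer(seq(1990, 2020, 5)))
  expect_equal(nrow(series), 7)
  for (i in seq_len(nrow(series) - 1)) {
    expect_true(all(series$map[[i]]$edges$edge_id %in%
                      series$map[[i + 1]]$edges$edge_id))
  }
  # snapshot at the max evidence year equals the full map
  max_year <- max(tidy(fx$map, "evidence")$year)
  full <- snapshot_by_year(fx$map, max_year)
  expect_identical(full$edges, fx$map$edges)
  expect_equal(nrow(snapshot_series(fx$map, 2000, 2000, 5)), 1)
  expect_error(snapshot_series(fx$map, 2020, 1990, 5),
               class = "dm_input_error")
})

test_that("review decisions set status, audit, and never touch the graph", {
  m <- tiny_map()
  m1 <- apply_review(m, "E1->E2", "declined", timestamp = "t1")
  expect_equal(m1$edges$review_status[m1$edges$edge_id == "E1->E2"],
               "declined")
  m2 <- apply_review(m1, "E1->E2", "accepted", note = "checked paper",
                     timestamp = "t2")
  expect_equal(m2$edges$review_status[m2$edges$edge_id == "E1->E2"],
               "accepted")
  expect_equal(nrow(m2$meta$audit), 2)
  expect_equal(m2$meta$audit$status, c("declined", "accepted"))
  # topology, weights and classes untouched
  expect_identical(m2$edges[c("edge_id", "source", "target", "edge_class",
                              "weight", "evidences")],
                   m$edges[c("edge_id", "source", "target", "edge_class",
                             "weight", "evidences")])
  expect_error(apply_review(m, "e99", "accepted"), "e99",
               class = "dm_input_error")
  expect_error(apply_review(m, "E1->E2", "unreviewed"),
               class = "dm_input_error")
})

test_that("next_unreviewed iterates in stable order and wraps", {
  m <- tiny_map()
  expect_equal(next_unreviewed(m), "E1->E2")
  expect_equal(next_unreviewed(m, after = "E1->E2"), "E2->E3")
  expect_equal(next_unreviewed(m, after = "E2->E3"), "E1->E2")  # wraps
  m <- apply_review(m, "E1->E2", "accepted")
  expect_equal(next_unreviewed(m, after = "E2->E3"), "E2->E3")
  m <- apply_review(m, "E2->E3", "declined")
  expect_null(next_unreviewed(m))
})

test_that("review summary counts always sum to the edge count", {
  fx <- synth_map(21, n_entities = 8, n_edges = 14)
  m <- fx$map
  withr::with_seed(1, {
    for (id in sample(m$edges$edge_id, 6)) {
      m <- apply_review(m, id,
                        sample(setdiff(review_statuses(), "unreviewed"), 1))
    }
  })
  s <- review_summary(m)
  expect_equal(s$unreviewed + s$accepted + s$declined +
                 s$further_inspection_needed, s$n_edges)
  expect_equal(s$n_edges, nrow(m$edges))
})
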