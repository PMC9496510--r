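# Shared fixtures, all generated in code at test time.

fixed_clock <- function() as.POSIXct("2026-01-01 00:00:00", tz = "UTC")

# Two entities, hand-written evidence rows; the smallest interesting map.
tiny_entities <- function() {
  tibble::tibble(
    entity_id = c("E1", "E2", "E3"),
    label = c("CFTR", "NHERF1", "CAL"),
    compartment = c("plasma membrane", "cytoplasm", "cytoplasm")
  )
}

tiny_interactions <- function() {
  tibble::tibble(
    source_id = c("E1", "E1", "E1", "E2"),
    target_id = c("E2", "E2", "E2", "E3"),
    pmid = c(111L, 111L, 222L, 333L),
    year = c(1991L, 1993L, 1996L, 2004L),
    sentence = c("CFTR activates NHERF1.", "CFTR binds NHERF1.",
                 "CFTR activates NHERF1 again.", "NHERF1 inhibits CAL."),
    verbs = list("activates", "binds", "activates", "inhibits")
  )
}

tiny_map <- function(layout = TRUE) {
  ev <- categorize_evidence(tiny_interactions())
  m <- build_map(tiny_entities(), ev, clock = fixed_clock)
  if (layout) m <- assign_layout(m) else m
}

# Seeded synthetic map for property-style tests.
synth_map <- function(seed, n_entities = 10, n_edges = 15, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  corp <- generate_corpus(
    synth_config(n_entities = n_entities, n_edges = n_edges, seed = seed, ...),
    dir = dir
  )
  list(
    corpus = corp,
    map = build_map_from_csv(file.path(dir, "entities.csv"),
                             file.path(dir, "interactions.csv"),
                             clock = fixed_clock)
  )
}

write_lines_to <- function(lines, dir, name) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# Independent rule-table oracle for category aggregation: category decided
# only by which of the four base categories are present, via a hand-built
# 16-row lookup over all presence subsets.
aggregate_oracle <- function(categories) {
  key <- paste0(
    as.integer("activate" %in% categories),
    as.integer("inhibit" %in% categories),
    as.integer("neutral" %in% categories),
    as.integer("undefined" %in% categories)
  )
  table <- c(
    "0000" = "undefined",  "0001" = "undefined",
    "0010" = "neutral",    "0011" = "neutral",
    "0100" = "inhibit",    "0101" = "inhibit",
    "0110" = "inhibit",    "0111" = "inhibit",
    "1000" = "activate",   "1001" = "activate",
    "1010" = "activate",   "1011" = "activate",
    "1100" = "incoherent", "1101" = "incoherent",
    "1110" = "incoherent", "1111" = "incoherent"
  )
  unname(table[key])
}

# drop the ingest report before field-by-field comparison with raw tibbles
strip_report <- function(x) {
  attr(x, "ingest_report") <- NULL
  x
}
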