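round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

unknown_verbs <- function() {
  c("flurbs", "zorps", "quuxes", "blims", "frobnicates", "glorps")
}

#' Configuration for the synthetic text-mining corpus generator
#'
#' The generator plants a known class and distinct-publication count on
#' every edge, so the full pipeline can be checked for exact recovery.
#' Planted incoherent/undefined edge counts use deterministic rounding
#' (half away from zero) of `conflict_rate`/`undefined_rate` times
#' `n_edges`, so the counts are exact, not expectations.
#'
#' @param n_compartments Number of subcellular compartments, >= 1.
#' @param n_entities Number of entities, >= 1.
#' @param n_edges Number of directed interaction edges, at most
#'   `n_entities * (n_entities - 1)`.
#' @param pmids_per_edge Length-2 integer range; each edge's distinct
#'   publication count is drawn uniformly from it.
#' @param conflict_rate Fraction of edges planted as incoherent (evidence
#'   for both activation and inhibition).
#' @param undefined_rate Fraction of edges whose sentences carry only
#'   out-of-lexicon verbs.
#' @param year_range Length-2 range publication years are drawn from.
#' @param seed RNG seed; the generator is deterministic given the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_compartments = 4, n_entities = 25, n_edges = 60,
                         pmids_per_edge = c(1L, 5L), conflict_rate = 0.1,
                         undefined_rate = 0.1, year_range = c(1990L, 2020L),
                         seed = 1L) {
  stopifnot(n_compartments >= 1, n_entities >= 1, n_edges >= 0,
            length(pmids_per_edge) == 2,
            pmids_per_edge[1] >= 1, pmids_per_edge[1] <= pmids_per_edge[2],
            length(year_range) == 2, year_range[1] <= year_range[2])
  if (conflict_rate < 0 || undefined_rate < 0 ||
      conflict_rate + undefined_rate > 1) {
    rlang::abort("need 0 <= conflict_rate + undefined_rate <= 1",
                 class = "dm_input_error")
  }
  if (n_edges > n_entities * (n_entities - 1)) {
    rlang::abort("n_edges exceeds the number of distinct directed pairs",
                 class = "dm_input_error")
  }
  structure(
    list(n_compartments = as.integer(n_compartments),
         n_entities = as.integer(n_entities),
         n_edges = as.integer(n_edges),
         pmids_per_edge = as.integer(pmids_per_edge),
         conflict_rate = conflict_rate, undefined_rate = undefined_rate,
         year_range = as.integer(year_range), seed = as.integer(seed)),
    class = "synth_config"
  )
}

save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic text-mining corpus with known ground truth
#'
#' Emits the two-table exchange format (entities with a compartment,
#' sentence-level interaction evidence) together with a ground-truth table
#' recording each edge's planted class, planted distinct-PubMed-id weight,
#' and evidence years. Evidence sentences are templated around lexicon verbs
#' matching the planted class: incoherent edges receive at least one
#' activating and one inhibiting evidence sentence, undefined edges only
#' out-of-lexicon verbs, and a share of directional edges additionally carry
#' a neutral verb to exercise aggregation precedence. PubMed ids never
#' collide across edges; years are uniform in `year_range`. Running the
#' full pipeline (ingest, categorize, build) on the output recovers every
#' planted class and weight exactly -- that recovery is this generator's
#' reason to exist.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, `entities.csv` and
#'   `interactions.csv` are written there in the exchange format.
#' @param dialect A [csv_dialect()] used when writing.
#' @return A list with tibbles `entities`, `interactions` (the shape
#'   [read_interactions()] returns), `truth` (source_id, target_id, class,
#'   weight, years), and `paths` when `dir` was given.
#' @export
#' @examples
#' corp <- generate_corpus(synth_config(n_entities = 6, n_edges = 8, seed = 7))
#' corp$truth
generate_corpus <- function(config = synth_config(), dir = NULL,
                            dialect = csv_dialect()) {
  stopifnot(inherits(config, "synth_config"))
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(config$seed)
  lex <- default_lexicon()
  verbs_of <- function(cat) lex$verb[lex$category == cat]

  comp_pool <- canonical_compartment_order()
  comp_pool <- setdiff(comp_pool, "membrane")  # avoid near-duplicate bands
  n_c <- config$n_compartments
  comps <- if (n_c <= length(comp_pool)) comp_pool[seq_len(n_c)] else {
    c(comp_pool, paste0("compartment_", seq_len(n_c - length(comp_pool))))
  }

  n <- config$n_entities
  entities <- tibble::tibble(
    entity_id = sprintf("E%03d", seq_len(n)),
    label = sprintf("GEN%d", seq_len(n)),
    compartment = sample(comps, n, replace = TRUE)
  )

  # directed pairs without replacement
  n_pairs <- n * (n - 1)
  pick <- sample.int(n_pairs, config$n_edges)
  src_i <- (pick - 1) %/% (n - 1) + 1
  off <- (pick - 1) %% (n - 1) + 1
  tgt_i <- ifelse(off >= src_i, off + 1, off)

  m <- config$n_edges
  n_inc <- as.integer(round_half_away(config$conflict_rate * m))
  n_und <- as.integer(round_half_away(config$undefined_rate * m))
  n_rest <- m - n_inc - n_und
  rest <- sample(c("activate", "inhibit", "neutral"), n_rest, replace = TRUE)
  classes <- sample(c(rep("incoherent", n_inc), rep("undefined", n_und), rest))

  k <- sample(seq(config$pmids_per_edge[1], config$pmids_per_edge[2]),
              m, replace = TRUE)
  k[classes == "incoherent"] <- pmax(k[classes == "incoherent"], 2L)
  pmid_pool <- sample.int(8999999L, sum(k)) + 1000000L
  pmid_split <- split(pmid_pool, rep(seq_len(m), k))

  rows <- vector("list", m)
  truth_years <- vector("list", m)
  for (e in seq_len(m)) {
    cls <- classes[e]
    ki <- k[e]
    ev_cats <- switch(cls,
      incoherent = {
        extra <- sample(c("activate", "inhibit"), max(0, ki - 2),
                        replace = TRUE)
        sample(c("activate", "inhibit", extra))
      },
      undefined = rep("undefined", ki),
      rep(cls, ki)
    )
    verbs <- purrr::map(ev_cats, function(cat) {
      v <- if (cat == "undefined") sample(unknown_verbs(), 1)
           else sample(verbs_of(cat), 1)
      # sometimes a neutral co-verb on directional evidence: precedence test
      if (cat %in% c("activate", "inhibit") && stats::runif(1) < 0.3) {
        c(v, sample(verbs_of("neutral"), 1))
      } else v
    })
    a <- entities$label[src_i[e]]
    b <- entities$label[tgt_i[e]]
    comp <- entities$compartment[src_i[e]]
    years <- sample(seq(config$year_range[1], config$year_range[2]),
                    ki, replace = TRUE)
    truth_years[[e]] <- sort(years)
    rows[[e]] <- tibble::tibble(
      source_id = entities$entity_id[src_i[e]],
      target_id = entities$entity_id[tgt_i[e]],
      pmid = as.integer(pmid_split[[e]]),
      year = as.integer(years),
      sentence = sprintf("%s strongly %s %s in the %s.", a,
                         purrr::map_chr(verbs, paste, collapse = " and "),
                         b, comp),
      verbs = verbs
    )
  }
  interactions <- if (m > 0) dplyr::bind_rows(rows) else tibble::tibble(
    source_id = character(0), target_id = character(0), pmid = integer(0),
    year = integer(0), sentence = character(0), verbs = list()
  )
  truth <- tibble::tibble(
    source_id = entities$entity_id[src_i],
    target_id = entities$entity_id[tgt_i],
    class = classes,
    weight = as.integer(k),
    years = truth_years
  )
  out <- list(entities = entities, interactions = interactions, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(entities = file.path(dir, "entities.csv"),
                  interactions = file.path(dir, "interactions.csv"))
    write_entities_csv(entities, paths$entities, dialect)
    write_interactions_csv(interactions, paths$interactions, dialect)
    out$paths <- paths
  }
  out
}

#' Run the full pipeline on a generated or on-disk corpus
#'
#' Convenience wrapper: ingest the two tables, categorize the evidence,
#' aggregate into a map, and assign the cellular layout.
#'
#' @param entities_path,interactions_path Paths to the two CSVs.
#' @param lexicon A `verb_lexicon`.
#' @param dialect A [csv_dialect()].
#' @param layout A [layout_config()], or `NULL` to skip layout.
#' @param strict Passed to the readers.
#' @param clock Passed to [build_map()].
#' @return A `disease_map`.
#' @export
build_map_from_csv <- function(entities_path, interactions_path,
                               lexicon = default_lexicon(),
                               dialect = csv_dialect(),
                               layout = layout_config(), strict = FALSE,
                               clock = Sys.time) {
  entities <- read_entities(entities_path, dialect, strict = strict)
  interactions <- read_interactions(interactions_path, entities, dialect,
                                    strict = strict)
  evidence <- categorize_evidence(interactions, lexicon)
  map <- build_map(entities, evidence,
                   source_files = basename(c(entities_path,
                                             interactions_path)),
                   clock = clock)
  if (!is.null(layout)) map <- assign_layout(map, layout)
  map
}
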