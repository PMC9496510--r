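---
title: "Curating text-mined disease maps: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating text-mined disease maps: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcurate)
```

## The problem

Text-mining systems can propose molecular interactions from the
literature far faster than human curators can read it, but their output
is not a disease map: it is a pile of sentence-level co-mentions of
entity pairs, each with a PubMed id, a year, and the verbs that linked
the pair in that sentence. `dmcurate` converts that pile into an
expert-reviewable map. This vignette explains the model it uses, the
parameters that matter, the choices made where the design was genuinely
open, and what the package's tests do and do not establish.

The package deliberately contains **no** text mining. Named-entity
recognition, synonym normalization and relation extraction are the
upstream system's job; `dmcurate` consumes the exchange format
downstream of all of that. Consequently it never second-guesses entity
identifiers: matching is exact and case-sensitive, and an id unknown to
the entity table is an ingest error, not something to be repaired.

## The exchange format

Two CSV tables with fixed headers:

* entities: `entity_id,label,compartment` — one row per entity with its
  subcellular localization;
* interactions: `source_id,target_id,pmid,year,sentence,verbs` — one row
  per *sentence-level mention* of a directed pair, verbs joined by a
  configurable separator (default `;`).

The upstream literature on this exchange pattern names the content of
the two tables but not their columns; fixing the headers (and defaulting
to comma/double-quote/`;`, all overridable via `csv_dialect()`) is what
makes the format reproducible across tools. One row = one sentence
mention is likewise a fixed contract here: aggregation into edges
happens inside the package, where it can be tested, not upstream.

Rows that violate the contract (unknown entity, non-numeric PubMed id,
year outside 1800–2100, empty sentence, duplicate entity id) are
*skipped and reported* in an ingest report rather than aborting the run;
a `strict` flag turns them fatal. A curation tool's first duty with
dirty input is to surface it, not to hide it — or silently die on it.

## Verb categorization and edge classes

Each verb is lowercased, stripped of surrounding punctuation, and looked
up in a lexicon mapping verb forms to `activate`, `inhibit`, or
`neutral`. Absence from the lexicon *is* the fourth category,
`undefined`; no verb may map to it directly. The packaged default
lexicon (~70 inflected forms over ~25 stems) is a documented,
replaceable starting point — pass any two-column CSV via
`read_lexicon()` or the CLI's `--lexicon`. There is deliberately no
stemming or lemmatization: lookup is deterministic and dependency-free,
and a lexicon can simply list inflections.

Categories aggregate with multiset semantics (order and duplication
never matter):

1. `activate` and `inhibit` both present → `incoherent`;
2. exactly one of them present → that class;
3. otherwise `neutral` if present;
4. otherwise `undefined` (including the empty set).

The fifth class, `incoherent`, is edge-level only. The interaction
viewers this package feeds render incoherent interactions as their own
(brown) class but leave its trigger undefined; conflicting directional
evidence is the only trigger consistent with the four base classes, and
that is the declared rule here. A second open point is *where* conflict
counts: this package reserves `incoherent` for conflict **across**
evidences of one edge — the notion is about interactions, not sentences
— so a single sentence containing both an activating and an inhibiting
verb demotes to `undefined` at evidence level instead.

## The map model

`build_map()` merges all evidence rows sharing a directed (source,
target) pair into one edge. Edges are directed because the rendered
arrow-shaped edges imply direction, and parallel per-publication edges
are ruled out because the thickness encoding requires aggregation: an
edge's weight is the number of *distinct* PubMed ids among its
evidences (several sentences from one paper count once). The edge class
is the aggregation of its evidence categories. Both quantities are
invariants of the object — `validate_disease_map()` recomputes and
checks them — so no operation can leave them stale.

Each entity has exactly one parent compartment. Multi-localized
entities must arrive as distinct rows from the upstream miner; guessing
a split here would amount to silent data invention.

## Layout

The layout is a deterministic banded grid, not a force simulation.
Compartments become full-width horizontal bands stacked in canonical
outside-in cellular order (`canonical_compartment_order()`:
extracellular → membranes → cytoplasm → organelles → nucleus; unknown
compartment names sort alphabetically below the known ones). Nodes are
placed on a grid inside their band in node-id order, with spacing
(default 80 layout units) and band margin (default 30) configurable. A
band with more nodes than a row holds grows additional rows rather than
erroring. Coordinates follow the screen convention — x rightward, y
downward, origin top-left — and are rounded to two decimals.

Determinism is the point: the same input and config give byte-identical
serialized output, which makes regression tests and file diffs
meaningful, and the containment guarantee (every node strictly inside
its band, pairwise node distance at least the grid spacing) is checked
property-style over generated maps. Force-directed prettiness is left
to interactive viewers, where users drag nodes anyway.

## Filtering, timelines and review

`filter_edges()` mirrors a viewer's legend checkboxes and
minimum-publication slider: it keeps exactly the edges whose class is
allowed and whose weight meets the threshold. An empty class set means
"all classes" (the identity on class), and nodes are never dropped —
hiding isolated nodes is a presentation concern, and keeping the filter
a pure edge operation gives it clean algebra (idempotent; class and
weight filters commute).

Timeline snapshots are **cumulative**: `snapshot_by_year(map, y)` keeps
evidence with year ≤ y, drops edges left without evidence, and
*recomputes* weight and class from what remains — so an edge whose
inhibiting report only appeared later genuinely shows as `activate` in
early snapshots and flips to `incoherent` at the later cutoff. A
per-window reading of "snapshots over the years" was the alternative;
knowledge-to-date is the natural reading for accumulating literature
and yields the testable property that edge sets nest monotonically
along the series (default 1990→2020 in 5-year steps). Per-window views
remain expressible by differencing snapshots.

Review is last-write-wins on a per-edge status (`accepted`, `declined`,
`further_inspection_needed`; a decision never sets `unreviewed`), with
every decision appended to an audit trail in the map metadata —
collaborative curation needs history even though only the current
status is displayed. Review never touches topology, weights or classes.
`next_unreviewed()` iterates pending edges in sorted-id order, cycling,
so "next edge" is deterministic.

## Serialization

The map JSON is Cytoscape-style elements JSON: one list of elements —
compartments first (as parentless container nodes carrying their band
rectangle), then nodes with `parent` set, then edges with `classes` and
a `references` list (pmid, year, sentence, verbs, verb categories per
evidence) — wrapped in an object alongside a `meta` provenance block
(creation time from an injectable clock, source files, lexicon
identity, tool version, audit trail). The wrapper is what makes the
round trip lossless for a resumed review session. Key order is fixed
and floats carry two decimals, so serialize → parse → serialize is
byte-identical; unknown `data` keys found on import are preserved
opaquely and re-emitted. The shipped schema
(`system.file("schema", "map-elements.schema.json", package = "dmcurate")`)
is the public contract, and `validate_map_json()` enforces exactly its
constraints with messages naming the offending element.

SBGN-ML export uses the 0.2 activity-flow language: compartment glyphs,
biological-activity glyphs at the layout positions, and arcs classed
`positive influence` (activate), `negative influence` (inhibit) or
`unknown influence` (everything else). Activity flow has no neutral,
undefined or incoherent arc class, so the original five-way class (and
the weight) ride along in an `extension` annotation — nothing is lost.
`read_sbgnml()` is an independent parser (separate code path over raw
XML) used as the structural oracle for the writer.

## The synthetic-corpus generator

`generate_corpus()` emits the exchange format with *planted* ground
truth: each edge gets a class, a distinct-PubMed-id count drawn
uniformly from `pmids_per_edge` (default 1–5), and years uniform in
`year_range` (default 1990–2020). Defaults of 4 compartments, 25
entities and 60 edges give corpora of the size a single text-mining run
over a focused disease query plausibly yields, while the acceptance
checks scale entities to 50 and edges toward 200. Incoherent edges are
planted with at least one activating and one inhibiting evidence;
undefined edges carry only out-of-lexicon verbs; planted
incoherent/undefined counts use round-half-away-from-zero of the
configured rates (default 0.1 each) so they are exact, not expected
values. About 30% of directional evidences carry an additional neutral
co-verb, exercising aggregation precedence. PubMed ids never collide
across edges, which is what makes exact weight recovery well-defined.

Sentences are template text ("GEN3 strongly inhibits GEN7 in the
cytoplasm."), because the categorizer consumes the `verbs` column, not
prose. That is also the generator's main limitation: it emulates the
*format and statistics* of text-mining output, not its failure modes.
Passing the recovery tests shows the aggregation, weighting and
round-trip machinery is exact; it says nothing about NER quality,
synonym collapse, negation, or speculative language in real corpora —
all of which live upstream by design.

## Numerical and degenerate-input choices

* Coordinates are rounded to two decimals at layout time, so JSON
  round trips compare exactly; no other floating-point arithmetic
  exists in the pipeline.
* Empty verb lists, header-only input files, empty filter results and
  empty maps are all legal and covered by tests; an edge with zero
  remaining evidence cannot exist (it is dropped).
* Timestamps come from injectable clocks (`build_map(clock = )`,
  `apply_review(timestamp = )`) so exports can be reproduced exactly.
* Edge ids are `source->target`, unique by the one-edge-per-directed-
  pair invariant and stable across export/import.
* The generator saves and restores the caller's RNG state.

## Problem sizes in the checks

The property suite runs on generated corpora of 6–50 entities and 8–200
edges: 50 corpora for ground-truth recovery, 100 fixtures for JSON
round trips, 100 random map/filter pairs against a set-comprehension
oracle, the full 5,461-case exhaustive table for aggregation, and
three 40-node/5-compartment maps for layout geometry. These sizes keep
the whole suite around a minute while covering every code path;
the pipeline itself is linear in evidence rows and comfortably handles
corpora orders of magnitude larger.

## Known limitations

* One compartment per entity; no nested compartment rectangles in the
  banded layout (the model validates nesting, the layout never emits it).
* No negation or speculation handling — "does not activate" counts as
  activation unless the upstream miner filters it.
* The review workflow is single-user last-write-wins; there is no
  locking, merging, or undo beyond the audit trail.
* SBGN-ML export is activity-flow only; process-description semantics
  (reactions, complexes) are out of scope for an entity-influence map.
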