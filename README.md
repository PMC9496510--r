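# dmcurate

Expert curation of text-mined disease maps, in R.

Disease maps — comprehensive systems-biology representations of disease
mechanisms — are still assembled largely by hand from the literature.
Text-mining pipelines can propose molecular interactions at scale, but
their output (entities, and the sentences in which pairs of them co-occur)
needs an expert eye before it belongs in a curated map. `dmcurate` sits
between the two: it takes the raw two-table output of any text-mining
system and turns it into an evidence-weighted, reviewable disease map that
a domain expert can filter, audit edge by edge, and export in
viewer-ready formats.

It is written for computational biologists and curators who receive
text-mining results as tables and want a reproducible, scriptable curation
workflow rather than a one-off spreadsheet.

## The model

The input is one sentence-level *evidence record* per row: a directed
entity pair, a PubMed id, a publication year, the sentence, and the verbs
found in it. `dmcurate` aggregates these into a graph as follows.

Each verb *v* is looked up in a replaceable lexicon
*L: v → {activate, inhibit, neutral}*; verbs absent from *L* are
`undefined`. Categories combine with multiset semantics under the
precedence

```
activate + inhibit → incoherent        (conflicting directional evidence)
one of {activate, inhibit} present → that class
else neutral present → neutral
else → undefined
```

with `incoherent` reserved for conflict *across* evidences on one edge
(a conflict inside a single sentence demotes to `undefined`). All
evidence rows sharing a directed pair merge into one edge whose class is
the aggregate of its evidence categories and whose weight

*w(e) = |{distinct PubMed ids supporting e}|*

is the quantity viewers render as edge thickness. Entities sit inside
their subcellular compartment, and a deterministic banded layout stacks
compartments in canonical cellular order (extracellular at the top,
nucleus at the bottom) with nodes on a grid inside their band.

On top of the graph the package provides class/weight filtering,
cumulative publication-year snapshots (the map as the literature knew it
up to a cutoff year), a review workflow (`accepted` / `declined` /
`further_inspection_needed`, with a full audit trail), and lossless
export to Cytoscape-style elements JSON, SBGN-ML activity-flow, and a
review CSV. A seeded synthetic-corpus generator with planted ground truth
makes the whole pipeline testable offline.

## Worked example

```r
library(dmcurate)

# a synthetic text-mining corpus with known ground truth
corp <- generate_corpus(synth_config(n_entities = 12, n_edges = 20, seed = 42),
                        dir = "demo")

# ingest -> categorize -> aggregate -> layout, in one call
map <- build_map_from_csv("demo/entities.csv", "demo/interactions.csv")
map
#> <disease_map> 12 nodes in 4 compartments, 20 edges
#>   classes: activate=3 inhibit=9 neutral=4 undefined=2 incoherent=2
#>   review:  unreviewed=20 accepted=0 declined=0 further_inspection_needed=0

glance(map)[, 1:7]
#> # A tibble: 1 × 7
#>   n_nodes n_compartments n_edges n_evidence n_activate n_inhibit n_neutral
#> 1      12              4      20         68          3         9         4

head(tidy(map), 3)
#> # A tibble: 3 × 6
#>   edge_id    source target edge_class weight review_status
#> 1 E001->E004 E001   E004   neutral         5 unreviewed
#> 2 E001->E006 E001   E006   inhibit         2 unreviewed
#> 3 E002->E010 E002   E010   incoherent      4 unreviewed
```

68 sentence-level mentions collapsed into 20 directed edges; `E001->E004`
is supported by 5 distinct publications, and `E002->E010` is `incoherent`
because different publications report activation and inhibition. Curation
then proceeds through review, snapshots and export:

```r
map <- apply_review(map, next_unreviewed(map), "accepted")
review_summary(map)
#> # A tibble: 1 × 5
#>   unreviewed accepted declined further_inspection_needed n_edges
#> 1         19        1        0                         0      20

nrow(snapshot_by_year(map, 2000)$edges)   # the map as known by 2000
#> [1] 12

write_map_json(map, "map.json")   # lossless; reload with read_map_json()
write_sbgnml(map, "map.sbgn")
write_review_csv(map, "review.csv")
autoplot(map)                     # ggplot of the cellular layout
```

The same pipeline is available from a shell via the bundled entry point
(`system.file("cli", "dmcurate", package = "dmcurate")`) with subcommands
`build`, `filter`, `snapshot`, `review`, `export-csv`, `synth`, and
`validate`:

```sh
dmcurate synth --out-dir demo --seed 42
dmcurate build -e demo/entities.csv -i demo/interactions.csv -o map.json
dmcurate review map.json --set "E001->E004=accepted" --csv review.csv
dmcurate snapshot map.json --start 1990 --end 2020 --step 5 --out-dir snaps/
```

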