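# ppinet

`ppinet` builds seed-centred protein–protein interaction (PPI) networks by
integrating curated interaction evidence from multiple primary databases.
It is aimed at researchers who have a list of proteins of interest (seeds)
and want a single, quality-controlled, confidence-scored table of their
literature-reported interactors — ready to import into Cytoscape or a
spreadsheet — without manually merging and cleaning downloads from several
repositories that disagree on format and curation completeness.

## What it computes

For each seed (HGNC gene symbol or Swiss-Prot accession for human; WormBase
`WBGene` ID for *C. elegans*), PSI-MITAB evidence is collected from seven
primary databases (bhf-ucl, BioGRID, InnateDB, IntAct, MBInfo, MINT,
UniProt) — live through PSICQUIC, or from local per-provider files for fully
reproducible offline runs. Each record then passes quality control: it is
discarded if it cites no PubMed ID or more than one PubMed ID, lacks an
interaction-detection-method annotation, carries an interactor from the
wrong species, or fails univocal mapping to a (gene name, Swiss-Prot,
Entrez) identifier triple. Detection-method codes (`MI:nnnn`) are converted
to technique categories via a conversion table so that technically similar
assays — e.g. two-hybrid and its array/pooling variants — count once.

Surviving evidence is merged across databases into unique undirected
interactions and scored per interaction:

- **MS** (Method.Score) — number of distinct method categories after
  conversion;
- **PS** (Publication.Score) — number of distinct PubMed IDs;
- **FS** (Final.Score) — MS + PS.

Since every retained record must carry at least one method and exactly one
PubMed ID, FS ≥ 2 always; FS = 2 flags an interaction seen by one technique
in one publication, and larger values indicate replication across methods
and/or studies.

Two filter regimes are available: **lenient** (maximises recall; unknown
method codes become their own singleton categories, records without taxid
annotations are tolerated) and **stringent** (additionally requires
taxonomy completeness and a conversion-table hit for every counted
method). Stringent output is always a subset of lenient output.

## Worked example

Generate a small synthetic offline corpus (six seed genes, five hundred
records with a controlled defect rate across seven provider dialects) and
run the pipeline on it:

```r
library(ppinet)

dir <- tempfile(); out <- tempfile()
man <- generate_fixtures(fixture_spec(n_records = 200, rng_seed = 42), dir)
res <- run_pipeline(man$seeds$symbol, species = "human",
                    offline_root = dir, out_dir = out,
                    method_table = load_method_table(file.path(dir, "method_table.tsv")),
                    mapping = read_mapping_table(file.path(dir, "mapping.tsv")))
print(res$report)
#> Interaction-integration run (human, lenient filter)
#>   seeds: 6 in, 6 valid
#>   records: 200 in, 137 retained, 63 discarded, 0 malformed lines
#>   interactions reported: 39
head(res$network, 2)
```

The run writes `final_network.txt` (the 11-column network table),
`final_network_log.txt` (every discarded seed and record with a one-token
reason), `final_network_providers.txt` (provider statuses) and
`run_report.json` into `out`. Each network row is one binary interaction:
the identifier triples of interactor A (the seed side) and B, then
`Method.Score`, the `;`-joined method categories, `Publication.Score`, the
`;`-joined PubMed IDs, and `Final.Score`. In Cytoscape, import with
`NameA`/`NameB` as source/target nodes.

The same pipeline answers *C. elegans* queries from a local
WormBase/Alliance-style dump:

```r
store <- build_worm_store("alliance_interactions.mitab")
query_worm(c("WBGene00000001", "WBGene00000002"), store)
```

A thin command-line wrapper is installed as `exec/ppinet` with subcommands
`run`, `build-worm-store` and `gen-fixtures`.

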