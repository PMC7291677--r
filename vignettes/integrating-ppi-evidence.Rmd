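---
title: "Integrating and scoring curated protein-protein interaction evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating and scoring curated protein-protein interaction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinet)
```

## The problem

No single interaction database covers the full extent of protein–protein
interactions (PPIs) reported in the literature, and the primary databases
differ both in MITAB dialect and in curation completeness. A researcher who
wants "all curated interactors of my proteins of interest" therefore faces
three chores: downloading from several repositories, removing incomplete or
non-univocal entries, and merging records that describe the same physical
interaction under different identifiers, orientations or method codes.
`ppinet` automates exactly this: acquisition, quality control, method
clustering, merging and confidence scoring, for human (seven PSICQUIC
providers) and *C. elegans* (a local WormBase-style dump).

## The scoring model

The unit of retained evidence is the tuple *(interactor pair, method
category, PubMed ID)*. After merging evidence for each unique undirected
pair, three integers are reported:

- **MS**, the number of distinct method categories — distinct *after*
  conversion, so that technically similar assays (classic two-hybrid,
  two-hybrid array, two-hybrid pooling) count as one technique rather than
  three database-specific codes;
- **PS**, the number of distinct publications (PubMed IDs);
- **FS = MS + PS**, the confidence score.

The model is deliberately transparent: every method category counts the
same, every publication counts the same. There is no per-assay reliability
weighting — users who want one can derive it from the `Method` column,
which is reported in full. Because quality control requires at least one
method and exactly one PubMed ID per record, FS ≥ 2 for any reported
interaction; FS = 2 means a single-study, single-technique observation
that should be treated as unreplicated.

## Quality-control rules and the two regimes

A record is discarded (with a one-token reason in the log) when:

- either interactor carries a taxonomy ID different from the query
  species (`wrong_taxid`);
- it cites no PubMed ID (`no_pmid`) or more than one *distinct* PubMed ID
  (`multiple_pmids`) — a multi-PMID entry is a curation ambiguity: it is
  unclear which publication supports the interaction, so the entry is
  dropped rather than split;
- it has no detection-method annotation (`no_method`);
- either interactor cannot be mapped to exactly one (gene name,
  Swiss-Prot, Entrez) triple (`unmapped`, `ambiguous`, `non_protein`).

Repeated identical PubMed tokens are deduplicated before the
multiple-PMID test: they are a curation artifact, not multiple
publications. Self-interactions (homodimers) are retained; they are
routinely curated and nothing in the model excludes them.

The **lenient** regime stops there. The **stringent** regime adds two
completeness screens: records missing a taxid on either interactor are
discarded (`missing_taxid`), and detection codes absent from the
conversion table are dropped rather than kept as singleton categories
(`unmapped_method` when a record has no mapped code left). These two
screens are kept in one policy block (`filter_record`) so they can be
revised without touching any other stage. By construction the stringent
evidence set is a subset of the lenient one; the test suite asserts this
on every generated corpus.

The discard-check order is fixed (taxonomy → PMID → method → mapping), so
a record failing several screens always reports the same reason —
important for reconciling the log against external expectations.

## Identifier handling

Human seeds may be HGNC symbols or Swiss-Prot accessions; accessions are
resolved to their symbol first so both entry forms behave identically.
Validation is purely lexical, case-sensitive, and total: invalid seeds are
logged, never fatal. Interactor resolution strips UniProt isoform (`-2`)
and processed-chain (`-PRO_...`) suffixes — these denote the same gene
product at the resolution granularity of the output — and falls back to a
record's alternative identifiers when the primary does not map. A mapping
is accepted only when exactly one snapshot row matches; one-to-many
mappings are discarded as ambiguous, matching the output contract that
every reported triple is univocal.

The mapping snapshot is a pluggable three-column file. The bundled
miniature covers ~30 well-known human genes so that examples and tests run
without downloads; real analyses should mount a current full snapshot. The
bundled worm mapping is synthetic (see the file name) and exists only to
exercise the code path that fills Swiss-Prot/Entrez columns for WBGene
IDs; unmapped worm genes keep the WBGene ID echoed in those columns so the
11-column layout is preserved.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `filter_mode` | `lenient` | QC regime; lenient maximises recall, stringent favours completeness of curation |
| `min_score` | 2 | Final.Score threshold; 2 is the attainable floor and a no-op, 3 removes all unreplicated interactions |
| `method_table` | bundled | `MI:nnnn` → category conversion; authoritative and must be unambiguous (conflicting duplicates are a load error) |
| `providers` | the seven defaults | any subset/superset via a YAML config; a failing provider is logged, never fatal |

The default filter mode is lenient because the scored table is easiest to
tighten after the fact (`score_threshold`, or re-running stringent) and
impossible to loosen.

The bundled conversion table groups the common PSI-MI detection-method
codes at the assay-family level (affinity purification, two-hybrid,
complementation, resonance energy transfer, imaging, structure,
biophysical, cross-linking, enzymatic, array), with the three two-hybrid
variants guaranteed to share one category. Category labels other than the
two-hybrid grouping are this package's own naming; the table is a data
file precisely so a lab's preferred grouping can drop in via
`--method-table`.

## What the synthetic generator emulates — and what it does not

`generate_fixtures()` emulates the *curation landscape*: seven providers
serving overlapping evidence in different MITAB dialects (15- vs
17-column, quoted vs bare ontology terms, present vs absent alternative
identifiers, optional header comments), randomly flipped interactor
orientation, and a controlled rate of completeness defects — missing
PMIDs, multiple PMIDs, missing methods, foreign or absent taxids, and
accessions that map to two Entrez IDs. Defect draws are mutually
exclusive per record, so each defective record has exactly one injected
discard reason and the log can be checked reason-by-reason.

Alongside the files it writes a ground-truth manifest: each record's
intended fate under both regimes and each pair's true (MS, PS, FS),
computed by the generator's own bookkeeping rather than by the pipeline.
Manifest–pipeline agreement is the repository's principal integration
test.

Defaults are six seeds, five hundred records, a 5% rate for each defect
class and a 30% cross-provider overlap — a corpus in which every discard
reason, both regimes and the deduplication logic are all exercised while
staying desk-sized. The generator makes no attempt at biological realism:
no degree distribution, no real gene names, no correlation between method
and publication. Passing tests therefore demonstrate that the plumbing,
accounting and arithmetic are correct on data shaped like real curation
output — they say nothing about the biological quality of any given
provider snapshot, and live-mode results will legitimately drift as
providers update.

## Numerical and representational choices

- All string sorting and pair canonicalisation use bytewise (C-locale)
  comparison, so output files are identical across locales and runs;
  determinism of offline runs is asserted byte-for-byte in the tests.
- The canonical undirected-pair key orders the two triples by Swiss-Prot
  accession; the seed side is restored as interactor A at output time.
  A pair whose both members are seeds is emitted once, oriented to the
  lexicographically earlier gene name.
- `Method` and `PMIDS` entries are sorted lexicographically and joined
  with `;`; rows are ordered by `NameA`, then `NameB`.
- Malformed MITAB lines (fewer than 15 columns) are counted and reported
  but never fatal; an empty input yields an empty, still well-formed
  output table.
- Multi-valued detection-method columns yield one evidence unit per code,
  each converted independently; duplicate evidence across providers
  collapses at aggregation because scores count *distinct* categories and
  publications.

## Problem sizes used by the test suite

The bundled tests run generated corpora of 40–1000 records (about 3,000
records generated in total), an exhaustive 3 × 3 evidence-set
enumeration, and 100-pair brute-force cross-checks of the aggregation
arithmetic; the full suite completes in under a minute on a laptop-class
single core. These sizes were chosen to exercise every code path and
reason token several times over while keeping the suite quick enough to
run on every change.

## Known limitations

- Live PSICQUIC mode is implemented but deliberately untested
  automatically; provider availability and content drift over time, which
  is the very reason the offline mode and fixture generator exist.
- The mapping snapshot is a point-in-time file; identifier churn (symbol
  renames, accession merges) between snapshot and provider data will
  surface as `unmapped`/`ambiguous` discards, visible in the log.
- Interaction-type and tissue filtering are out of scope by design: the
  quality axis here is curation completeness, not assay semantics.
- The worm mode trusts its dump's identifier discipline (WBGene IDs);
  non-WBGene interactors in a dump are discarded as unmapped rather than
  ortholog-mapped.
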