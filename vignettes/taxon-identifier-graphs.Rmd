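---
title: "Linking taxon graphs by their external identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking taxon graphs by their external identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxograph)
```

## The problem

Biodiversity databases each mint their own taxon identifiers, and the
traditional way to connect them — matching taxonomic name strings, with
fuzzy matching and synonym lists — is slow, error-prone, and needs
curatorial authority. But most large resources already annotate each of
their taxa with identifiers *into other databases*: an NCBI taxid, an ITIS
TSN, a GBIF key, an EOL page ID, an Index Fungorum ID, a FishBase ID, a
WoRMS AphiaID. Each resource's taxon graph can therefore be flattened into
a **lookup table** of (local taxon ID, external identifier) pairs, and two
resources can be linked wherever their taxa point at the *same* external
identifier — a join, not a string comparison.

`taxograph` implements that method end to end: readers that turn three
heterogeneous archives (a Wikidata JSON entity dump, the Open Tree of Life
reference taxonomy, the GloBI taxon-graph TSV) into lookup tables, the
identifier join itself, and an audit layer that measures how much linked
resources overlap and where they contradict each other.

## The identifier model

Every identifier is a CURIE, `SCHEME:value` — `ITIS:183803`, `WD:Q140`.
Parsing splits on the **first** colon only, because GloBI's synthesized
local IDs embed free text after the prefix
(`GLOBI:null@Procladius sp1 M_PL_014`); splitting greedily would destroy
them. Schemes are case-insensitive and normalized through a total registry
(unknown prefixes pass through uppercased and flagged rather than
erroring, so a novel scheme in a huge input cannot abort an ingest);
values are opaque and case-sensitive, since no authority states otherwise
and case-folding numeric or `Q`-prefixed values is at best a no-op and at
worst lossy.

Two scheme sets matter:

* **join schemes** (`NCBI, ITIS, GBIF, EOL, IF, FISHBASE, WORMS`) — used
  when linking two resources;
* **audit schemes** (`NCBI, GBIF, IF, WORMS`) — the subset all three
  supported resources maintain, used for the overlap, Venn, and
  consistency metrics so the comparison is apples-to-apples.

Both are registry fields, not constants, and every metric takes a
`schemes` argument.

## Readers

Each reader produces the same shape — a `lookup_table` with columns
`taxonId`, `taxonName`, `externalId` — plus ingest counters obeying a
conservation law: every scanned record/claim is either emitted, skipped
for a named reason, or deduplicated, and the counts add up exactly. The
tests assert this on every dialect.

* **Wikidata** (`extract_wikidata_taxa()`): a single streaming pass over
  the entity-per-line JSON dump. An item is a taxon when an instance-of
  claim (`P31`) targets the taxon class (`Q16521`); deprecated-rank claims
  are dropped, preferred and normal kept, which is the standard dump
  consumer convention. The property→scheme map is configuration
  (`wikidata_property_map()`), so a drifted dump or an extra scheme —
  e.g. adding iNaturalist's property — needs no code change. Malformed
  lines are counted and skipped. The links-per-taxon histogram is computed
  in the same pass.
* **OTT** (`read_ott_taxonomy()`): the `taxonomy.tsv` dialect separates
  fields with the literal three-character `tab|tab`; we split on the full
  delimiter, never on single tabs. Each comma-separated `sourceinfo` CURIE
  becomes a row; schemes outside the join set (`silva`, `irmng`) are
  counted but excluded by default (`include_all_schemes = TRUE` keeps
  them).
* **GloBI** (`read_globi_taxon_graph()`): GloBI mints no taxon IDs, so the
  provided-side identifier is used as the local key, and when it is
  null/empty a stable joinable key `GLOBI:null@<name>` is synthesized.
  This is the one resource whose local IDs legitimately carry foreign
  prefixes, and the `lookup_table` validity rule is relaxed accordingly.

Duplicate (taxonId, externalId) pairs are dropped at ingest with the
first-seen name winning: every downstream metric is set-based, and row
multiplicity would silently double-count.

## The join

`join_graphs(a, b, schemes)` is a hash equi-join keyed on the serialized
external-ID CURIE, grouped per (taxonA, taxonB) pair so the complete
shared identifier set travels with each cross-link. Design points that
were genuinely open:

* **Many-to-many pairs are all retained.** If several taxa in one
  resource share an identifier (a synonym ring), each pairs with each
  matching taxon on the other side. Collapsing them would require an
  authority decision this method deliberately avoids.
* **No transitive closure.** A call links exactly one pair of resources;
  inferring A–C from A–B and B–C changes the semantics (and propagates
  errors), so it is simply not done.
* **Hash join, not pairwise comparison.** The all-pairs alternative is
  quadratic in taxa; the equi-join is linear in rows. The quadratic
  version exists anyway — in the test suite, as the independent oracle the
  join must agree with exactly (200 randomized instances up to 100 taxa,
  mixed conflict rates).

`merge_links()` folds accepted cross-links back into a base table, one row
per (base taxon, foreign taxon) pair, idempotently — merging twice appends
nothing. We append per taxon pair rather than per shared identifier
because the foreign taxon ID is the new fact being recorded; the shared
identifiers are already rows of the base table.

## The audits

* `consistency_audit()` — a taxon ID linking to ≥2 distinct identifiers
  in one scheme is inconsistent (synonymy, outdated names, or resolver
  bugs). Name-string disagreement is *reported* on the record but never
  triggers a flag by itself; the definition is about identifiers.
* `pairwise_consistency()` — the same rule applied to the pooled
  identifiers of a linked taxon pair. It needs the two source tables in
  addition to the links, because a cross-link carries only the shared
  subset.
* `overlap_metrics()`, `venn_partition()`, `scheme_counts()` — all count
  **distinct** external IDs, never rows. The seven Venn regions are
  asserted to sum to the union cardinality on every call, and
  `overlap(a,b)$shared` equals the `ab + abc` regions by construction
  (cross-checked in tests). `scheme_counts()` percentages use the
  reference resource's per-scheme totals as denominators — they are
  relative size estimates, not intersections, and a zero-count reference
  scheme yields `NA` rather than a fabricated 100%.

## The synthetic generator

`synthetic_spec()` / `generate_taxon_graphs()` emulate exactly the
statistical structure the method assumes: `n_taxa` true taxa, each holding
one canonical ID per scheme; resources covering taxa with probability
`coverage` and carrying each scheme link with probability `link_prob`;
planted conflicts at rate `conflict_rate`. Two constructions keep the
ground truth *exact* rather than probable:

* canonical values live in disjoint 10^7-wide integer blocks per scheme,
  so cross-scheme collisions cannot occur;
* planted wrong values come from a reserved upper half-block keyed by
  resource, so a conflict can never accidentally equal a canonical ID or
  another resource's wrong value — a planted conflict cannot create a
  spurious true link.

Defaults (three resources `WD`/`OTT`/`GLOBI`, coverage 0.8, four audit
schemes, link probability 0.7, conflict rate 0 unless planted on purpose)
mirror a world where most taxa are shared but no resource is complete,
which is the observed regime for these databases. The generator is
deterministic given the spec and seed and leaves the caller's RNG stream
untouched.

What it deliberately does **not** emulate: taxonomic hierarchy, realistic
name strings, or scheme-specific value syntax. The method under test is
identifier-set algebra, and none of those features enter it — so passing
tests certify the algebra, not the readers' robustness to every real-world
archive quirk (that is what the dialect-specific reader tests and the
malformed-input tests are for).

## Numerical and procedural choices

* All sorting is byte-order (`method = "radix"`), making outputs
  locale-independent and byte-stable across runs; the pipeline's only
  varying output field is a provenance timestamp.
* Empty inputs flow through every stage and produce empty outputs with a
  warning, not an error.
* Problem sizes in the shipped tests: ground-truth recovery runs 20 seeds
  at 500 taxa × 3 resources; oracle equivalence runs 200 instances at up
  to 100 taxa; the convergence check for the planted-conflict rate uses
  4000 taxa. These sizes give exact (not asymptotic) checks for the
  set-algebra properties while keeping the default suite fast.

## Limitations

* Full-scale inputs (the 20 GB Wikidata dump, OTT 3.0, GloBI v0.4.2) are
  not shipped; the readers stream and the join is linear in rows, but the
  published full-scale counts can only be reproduced against the pinned
  archives, which must be downloaded separately.
* The Wikidata reader is single-threaded R; at full dump scale it is
  IO/JSON-bound and slow compared to a cluster run, though memory-safe.
* Identifier-based linking inherits the quality of the identifier
  annotations themselves: it cannot link taxa no resource has annotated,
  and it faithfully propagates upstream mis-mappings (which is precisely
  what the consistency audit is for detecting).
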