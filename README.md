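# taxograph

Linking biodiversity databases by joining their taxon **identifier graphs**
instead of matching taxonomic name strings.

## The problem

Biodiversity resources — Wikidata, the Open Tree of Life reference taxonomy
(OTT), the Global Biotic Interactions database (GloBI) — each use their own
taxon identifiers, and cross-database linking is usually done by comparing
name strings: slow, fuzzy, and dependent on nomenclatural authorities. But
these resources already annotate their taxa with identifiers *into other
databases* (NCBI taxids, ITIS TSNs, GBIF keys, EOL page IDs, Index Fungorum
IDs, FishBase IDs, WoRMS AphiaIDs). Flattening each resource's taxon graph
into a lookup table of

```
taxonId        taxonName      externalId
WD:Q140        Panthera leo   ITIS:183803
```

rows turns cross-database linking into an equi-join: taxa in two resources
are the same concept wherever they share an external identifier. For taxa
*t₁* in resource *A* and *t₂* in resource *B* with external-ID sets
*E(t₁)*, *E(t₂)* restricted to a scheme set *S*:

* **link**: *t₁ ~ t₂* ⇔ *E(t₁) ∩ E(t₂) ≠ ∅* (the shared set is kept as
  evidence; many-to-many matches, e.g. synonym rings, are all retained);
* **overlap** of two graphs: |distinct external IDs in both| / |distinct
  external IDs in each|;
* **inconsistency**: a taxon ID linking to ≥ 2 distinct identifiers in the
  *same* scheme — the signature of synonymy, outdated names, or resolver
  bugs.

`taxograph` implements the whole method: streaming readers for the Wikidata
JSON entity dump, the OTT `taxonomy.tsv`, and the GloBI taxon-graph TSV; the
hash join; merge-back of inferred links; overlap/Venn/per-scheme-count/
consistency audits; and a synthetic taxon-graph generator with exact planted
ground truth for validating all of it.

## Worked example

Three miniature taxon graphs ship with the package — a Wikidata table with
the lion (`WD:Q140` → `ITIS:183803`) and a marine taxon carrying three
identifiers, the matching OTT record, and a GloBI table with two known
problem names:

```r
library(taxograph)
fx <- example_taxon_graphs()

join_graphs(fx$wd, fx$ott)
#> # Cross-links: WD ↔ OTT on NCBI,ITIS,GBIF,EOL,IF,FISHBASE,WORMS
#> # 1 linked taxon pairs
#> # A tibble: 1 × 3
#>   taxonIdA    taxonIdB    sharedIds
#>   <chr>       <chr>       <list>
#> 1 WD:Q7247420 OTT:1087695 <chr [3]>
```

`WD:Q7247420` and `OTT:1087695` both point to `NCBI:191633`,
`WORMS:156905` and `GBIF:1449280`, so they are linked on a shared set of
three identifiers — and `pairwise_consistency()` confirms the pair is
consistent (no scheme holds two different values across the pooled IDs).

```r
consistency_audit(fx$globi)[, c("taxonId", "scheme", "nValues")]
#> # A tibble: 2 × 3
#>   taxonId                            scheme nValues
#>   <chr>                              <chr>    <int>
#> 1 GLOBI:null@Procladius sp1 M_PL_014 NCBI         6
#> 2 GLOBI:null@Senecio pectinatus      GBIF         2
```

Both GloBI names are flagged inconsistent: the *Procladius* morphospecies
resolved to six provisional NCBI taxa, and *Senecio pectinatus* — an
outdated name — maps to two GBIF keys.

```r
overlap_metrics(fx$wd, fx$ott)
#> <overlap_report> WD vs OTT on NCBI,GBIF,IF,WORMS
#>   WD: 3 distinct external IDs
#>   OTT: 3 distinct external IDs
#>   shared: 3 (100.0% of WD, 100.0% of OTT)
```

The same operations scale to the real archives via `run_pipeline()`
(extract → join → merge → audits, with a JSON metrics report) or the
command-line front end:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/taxograph.R", package = "taxograph"))') \
  run dump.json.gz ott/taxonomy.tsv globi.tsv -o out/
```

Raw-format micro-inputs for all three readers are under
`inst/extdata/`.

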