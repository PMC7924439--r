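# --- Wikidata entity-dump extraction -------------------------------------

test_that("Wikidata extraction emits one row per external-identifier claim", {
  dump <- write_wd_dump(c(
    wd_entity("Q140", name = "Panthera leo", ext = c(P815 = "183803")),
    wd_entity("Q7247420", ext = c(P850 = "156905", P846 = "1449280",
                                  P685 = "191633")),
    wd_entity("Q42", name = "Douglas Adams", taxon = FALSE,
              ext = c(P685 = "999"))
  ))
  res <- extract_wikidata_taxa(dump)
  lt <- res$table
  st <- res$stats

  expect_equal(st$entities_scanned, 3)
  expect_equal(st$taxa_extracted, 2) # the person is filtered out
  expect_equal(nrow(lt), 4)
  expect_equal(resource(lt), "WD")

  q140 <- tibble::as_tibble(lt)[lt$taxonId == "WD:Q140", ]
  expect_equal(q140$taxonName, "Panthera leo")
  expect_equal(q140$externalId, "ITIS:183803")

  q724 <- tibble::as_tibble(lt)[lt$taxonId == "WD:Q7247420", ]
  expect_setequal(q724$externalId,
                  c("WORMS:156905", "GBIF:1449280", "NCBI:191633"))
})

test_that("extraction stats: histogram sums to taxa, weighted sum to rows", {
  dump <- write_wd_dump(c(
    wd_entity("Q1", ext = c(P685 = "1")),
    wd_entity("Q2", ext = c(P685 = "2", P846 = "3")),
    wd_entity("Q3"), # a taxon with zero links: histogram 0-bin, no rows
    wd_entity("Q4", ext = c(P685 = "4", P846 = "5", P850 = "6"))
  ))
  st <- extract_wikidata_taxa(dump)$stats
  h <- st$links_per_taxon
  expect_equal(sum(h), st$taxa_extracted)
  expect_equal(sum(as.integer(names(h)) * h), st$rows_emitted)
  expect_equal(unname(h[c("0", "1", "2", "3")]), rep(1L, 4))
  expect_equal(st$per_scheme_link_counts[["NCBI"]], 3)
})

test_that("malformed dump lines are counted and skipped, never fatal", {
  dump <- tempfile(fileext = ".json")
  writeLines(c(
    "[",
    paste0(wd_entity("Q1", ext = c(P685 = "1")), ","),
    "{this is not json},",
    paste0(wd_entity("Q2", ext = c(P846 = "2")), ""),
    "]"
  ), dump)
  res <- extract_wikidata_taxa(dump)
  expect_equal(res$stats$malformed_lines, 1)
  expect_equal(res$stats$entities_scanned, 3)
  expect_equal(res$stats$entities_parsed +
                 res$stats$malformed_lines, res$stats$entities_scanned)
  expect_equal(res$stats$taxa_extracted, 2)
})

test_that("deprecated-rank claims are skipped, preferred/normal kept", {
  dump <- write_wd_dump(
    wd_entity("Q5", ext = c(P685 = "10"), deprecated = c(P846 = "99"))
  )
  lt <- extract_wikidata_taxa(dump)$table
  expect_equal(lt$externalId, "NCBI:10")
})

test_that("extraction streams from a connection, not only from files", {
  lines <- c("[", paste0(wd_entity("Q6", ext = c(P850 = "7")), ""), "]")
  con <- textConnection(lines)
  on.exit(close(con))
  res <- extract_wikidata_taxa(con, chunk_size = 1L)
  expect_equal(res$table$externalId, "WORMS:7")
})

test_that("gzip-compressed dumps are decompressed transparently", {
  dump <- tempfile(fileext = ".json.gz")
  con <- gzfile(dump, "wt")
  writeLines(c("[", as.character(wd_entity("Q7", ext = c(P685 = "8"))), "]"),
             con)
  close(con)
  res <- extract_wikidata_taxa(dump)
  expect_equal(res$table$externalId, "NCBI:8")
})

test_that("the property map is configuration: a remapped dump needs no code", {
  dump <- write_wd_dump(
    wd_entity("Q8", ext = c(P9999 = "77"))
  )
  props <- wikidata_property_map(external_ids = c(P9999 = "GBIF"))
  res <- extract_wikidata_taxa(dump, properties = props)
  expect_equal(res$table$externalId, "GBIF:77")

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(external_ids = list(P9999 = "WORMS")), f,
                       auto_unbox = TRUE)
  props2 <- wikidata_property_map(file = f)
  expect_equal(extract_wikidata_taxa(dump, properties = props2)$table$externalId,
               "WORMS:77")
  jsonlite::write_json(list(bogus_key = 1), f, auto_unbox = TRUE)
  expect_error(wikidata_property_map(file = f), "bogus_key")
})

# --- OTT taxonomy ---------------------------------------------------------

test_that("OTT records expand to one row per join-scheme sourceinfo entry", {
  f <- write_ott_fixture(list(
    list(uid = "1087695", name = "Procladius",
         sourceinfo = "ncbi:191633,worms:156905,gbif:1449280"),
    list(uid = "2", name = "No links", sourceinfo = ""),
    list(uid = "3", name = "Silva only", sourceinfo = "silva:AB123")
  ))
  lt <- read_ott_taxonomy(f)
  expect_equal(resource(lt), "OTT")
  expect_equal(nrow(lt), 3)
  expect_true(all(lt$taxonId == "OTT:1087695"))
  expect_setequal(lt$externalId,
                  c("NCBI:191633", "WORMS:156905", "GBIF:1449280"))
  expect_equal(lt$taxonName, rep("Procladius", 3))

  st <- table_stats(lt)
  expect_equal(st$records_scanned, 3)
  expect_equal(st$entries_scanned, 4)
  expect_equal(st$skipped_non_target, 1) # the silva entry
  expect_equal(st$emitted + st$skipped_non_target + st$skipped_unparsable,
               st$entries_scanned)

  # non-target schemes still counted in the per-scheme tally
  expect_equal(unname(st$per_scheme_entry_counts[["SILVA"]]), 1)

  # and can be included on request
  all_rows <- read_ott_taxonomy(f, include_all_schemes = TRUE)
  expect_equal(nrow(all_rows), 4)
  expect_true("SILVA:AB123" %in% all_rows$externalId)
})

test_that("OTT reader rejects files without the tab-pipe-tab dialect", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("uid\tname\tsourceinfo", "1\tx\tncbi:2"), f)
  expect_error(read_ott_taxonomy(f), "taxonomy.tsv")
})

test_that("unparsable sourceinfo entries are skipped and counted", {
  f <- write_ott_fixture(list(
    list(uid = "10", name = "Messy",
         sourceinfo = "ncbi:1,garbage,worms:2,:3")
  ))
  lt <- read_ott_taxonomy(f)
  expect_equal(nrow(lt), 2)
  expect_equal(table_stats(lt)$skipped_unparsable, 2)
})

test_that("OTT reader accepts a directory containing taxonomy.tsv", {
  d <- tempfile()
  dir.create(d)
  write_ott_fixture(list(list(uid = "5", name = "X", sourceinfo = "gbif:9")),
                    path = file.path(d, "taxonomy.tsv"))
  lt <- read_ott_taxonomy(d)
  expect_equal(lt$externalId, "GBIF:9")
})

# --- GloBI taxon graph ----------------------------------------------------

test_that("GloBI provided IDs are kept; null IDs get a synthesized key", {
  f <- write_globi_fixture(tibble::tibble(
    providedTaxonId = c(NA, "ITIS:552644"),
    providedTaxonName = c("Procladius sp1 M_PL_014", "Pluvialis obscura"),
    resolvedTaxonId = c("NCBI:1981571", "NCBI:176230"),
    resolvedTaxonName = c("Procladius", "Pluvialis obscura")
  ))
  lt <- read_globi_taxon_graph(f)
  expect_equal(resource(lt), "GLOBI")
  expect_setequal(lt$taxonId,
                  c("GLOBI:null@Procladius sp1 M_PL_014", "ITIS:552644"))
  expect_setequal(lt$externalId, c("NCBI:1981571", "NCBI:176230"))
})

test_that("GloBI reader skips and counts unparsable resolved IDs", {
  # 10 records, 3 with unparsable resolved IDs -> 7 rows + skip count 3
  df <- tibble::tibble(
    providedTaxonId = paste0("ITIS:", 1:10),
    providedTaxonName = paste("Taxon", 1:10),
    resolvedTaxonId = c("NCBI:1", "no-colon", "NCBI:2", ":novalue", "GBIF:3",
                        "NCBI:4", "", "WORMS:5", "EOL:6", "IF:7"),
    resolvedTaxonName = paste("Resolved", 1:10)
  )
  lt <- read_globi_taxon_graph(write_globi_fixture(df))
  st <- table_stats(lt)
  expect_equal(nrow(lt), 7)
  expect_equal(st$skipped_unparsable, 3)
  expect_equal(st$records_scanned, 10)
  expect_equal(st$emitted + st$skipped_unparsable + st$skipped_self_scheme +
                 st$skipped_no_key + st$deduplicated, st$records_scanned)
})

test_that("a header-only GloBI file yields an empty table", {
  f <- write_globi_fixture(tibble::tibble(
    providedTaxonId = character(), providedTaxonName = character(),
    resolvedTaxonId = character(), resolvedTaxonName = character()
  ))
  lt <- read_globi_taxon_graph(f)
  expect_equal(nrow(lt), 0)
})

test_that("missing required GloBI columns are reported by name", {
  f <- write_globi_fixture(tibble::tibble(
    providedTaxonId = "x", providedTaxonName = "y"
  ))
  expect_error(read_globi_taxon_graph(f), "resolvedTaxonId")
})
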