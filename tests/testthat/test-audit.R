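aud4 <- c("NCBI", "GBIF", "IF", "WORMS")

test_that("same-scheme multiplicity is flagged; one record per (taxon, scheme)", {
  fx <- example_taxon_graphs()
  rep_ <- consistency_audit(fx$globi)
  expect_equal(nrow(rep_), 2)
  procladius <- rep_[rep_$scheme == "NCBI", ]
  expect_equal(procladius$taxonId, "GLOBI:null@Procladius sp1 M_PL_014")
  expect_equal(procladius$nValues, 6L)
  senecio <- rep_[rep_$scheme == "GBIF", ]
  expect_equal(senecio$taxonId, "GLOBI:null@Senecio pectinatus")
  expect_setequal(senecio$values[[1]], c("GBIF:8317096", "GBIF:8414746"))

  # one ID per scheme per taxon -> consistent
  expect_equal(nrow(consistency_audit(fx$wd)), 0)
  expect_equal(nrow(consistency_audit(fx$ott)), 0)
})

test_that("consistency output is invariant under row permutation", {
  set.seed(61)
  rows <- tibble::tibble(
    taxonId = paste0("OTT:", sample(1:8, 40, replace = TRUE)),
    taxonName = NA_character_,
    externalId = paste0(sample(aud4, 40, replace = TRUE), ":",
                        sample(1:6, 40, replace = TRUE))
  )
  a <- consistency_audit(lookup_table(rows, "OTT"), aud4)
  b <- consistency_audit(lookup_table(rows[sample(nrow(rows)), ], "OTT"),
                         aud4)
  expect_equal(a, b)
})

test_that("names are collected on conflict records but never trigger one", {
  lt <- lookup_table(tibble::tibble(
    taxonId = c("OTT:1", "OTT:1"),
    taxonName = c("Name one", "Name two"), # two names, one ID: consistent
    externalId = c("NCBI:1", "GBIF:1")
  ), "OTT")
  expect_equal(nrow(consistency_audit(lt, aud4)), 0)

  lt2 <- lookup_table(tibble::tibble(
    taxonId = c("OTT:1", "OTT:1"),
    taxonName = c("Name one", "Name two"),
    externalId = c("NCBI:1", "NCBI:2")
  ), "OTT")
  rep_ <- consistency_audit(lt2, aud4)
  expect_equal(rep_$names[[1]], c("Name one", "Name two"))
})

test_that("pairwise consistency pools both taxa's identifiers", {
  fx <- example_taxon_graphs()
  links <- join_graphs(fx$wd, fx$ott)
  # identical triple of IDs on both sides: overlapping and consistent
  expect_equal(nrow(pairwise_consistency(links, fx$wd, fx$ott)), 0)

  a <- lookup_table(tibble::tibble(
    taxonId = c("WD:Q1", "WD:Q1"),
    externalId = c("GBIF:77", "NCBI:1")
  ), "WD")
  b <- lookup_table(tibble::tibble(
    taxonId = c("OTT:9", "OTT:9"),
    externalId = c("GBIF:77", "NCBI:2")
  ), "OTT")
  links2 <- join_graphs(a, b)
  rep_ <- pairwise_consistency(links2, a, b)
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$scheme, "NCBI")
  expect_setequal(rep_$values[[1]], c("NCBI:1", "NCBI:2"))
})

test_that("pairwise consistency recovers exactly the planted conflicts", {
  spec <- synthetic_spec(120, resources = c("WD", "OTT"), coverage = 1,
                         link_prob = 1, conflict_rate = 0.15, seed = 9)
  g <- generate_taxon_graphs(spec)
  links <- join_graphs(g$tables$WD, g$tables$OTT, schemes = spec$schemes)
  rep_ <- pairwise_consistency(links, g$tables$WD, g$tables$OTT,
                               schemes = spec$schemes)
  planted <- dplyr::bind_rows(
    g$truth$conflicts$WD[c("taxonId", "scheme")],
    g$truth$conflicts$OTT[c("taxonId", "scheme")]
  )
  # with full coverage each taxon pairs only with its counterpart, so the
  # flagged (pair, scheme) set maps 1:1 onto the planted (taxon, scheme) set
  got <- unique(rbind(
    data.frame(taxonId = rep_$taxonIdA, scheme = rep_$scheme),
    data.frame(taxonId = rep_$taxonIdB, scheme = rep_$scheme)
  ))
  flagged_sides <- paste(got$taxonId, got$scheme)
  planted_keys <- paste(planted$taxonId, planted$scheme)
  expect_true(all(planted_keys %in% flagged_sides))
})

test_that("overlap counts distinct identifiers and both coverage fractions", {
  a <- lookup_table(tibble::tibble(
    taxonId = paste0("WD:Q", 1:4),
    externalId = c("NCBI:1", "NCBI:2", "GBIF:3", "WORMS:4")
  ), "WD")
  b <- lookup_table(tibble::tibble(
    taxonId = paste0("OTT:", 1:2),
    externalId = c("NCBI:1", "GBIF:3")
  ), "OTT")
  ov <- overlap_metrics(a, b, aud4)
  expect_equal(ov$n_a, 4)
  expect_equal(ov$n_b, 2)
  expect_equal(ov$shared, 2)
  expect_equal(ov$fraction_a_covered, 0.5)
  expect_equal(ov$fraction_b_covered, 1.0)

  same <- overlap_metrics(a, a, aud4)
  expect_equal(same$shared, same$n_a)
  expect_equal(same$fraction_a_covered, 1.0)
})

test_that("Venn regions partition the union, degenerate cases included", {
  fx <- example_taxon_graphs()
  v <- venn_partition(fx$wd, fx$ott, fx$globi)
  expect_equal(sum(v$regions), v$union_size)
  expect_equal(unname(v$regions[["abc"]]), 0)
  expect_equal(unname(v$regions[["ab"]]), 3) # the consistent WD/OTT triple

  # disjoint tables: no pairwise or triple region
  a <- lookup_table(tibble::tibble(taxonId = "WD:Q1",
                                   externalId = "NCBI:1"), "WD")
  b <- lookup_table(tibble::tibble(taxonId = "OTT:1",
                                   externalId = "NCBI:2"), "OTT")
  d <- lookup_table(tibble::tibble(taxonId = "ITIS:1",
                                   externalId = "NCBI:3"),
                    "GLOBI")
  v2 <- venn_partition(a, b, d)
  expect_equal(unname(v2$regions[c("ab", "ac", "bc", "abc")]), rep(0L, 4))
  expect_equal(sum(v2$regions), 3)

  # identical ID sets: only the triple region
  b_same <- lookup_table(tibble::tibble(taxonId = "OTT:1",
                                        externalId = "NCBI:1"), "OTT")
  d_same <- lookup_table(tibble::tibble(taxonId = "ITIS:9",
                                        externalId = "NCBI:1"), "GLOBI")
  v3 <- venn_partition(a, b_same, d_same)
  expect_equal(unname(v3$regions[["abc"]]), 1)
  expect_equal(sum(v3$regions), 1)
  expect_equal(v3$abc_by_scheme[["NCBI"]], 1)

  expect_error(venn_partition(a, a, b), "distinct")
})

test_that("overlap shared equals the AB + ABC Venn regions", {
  set.seed(71)
  for (i in 1:5) {
    a <- random_lookup_table("WD", 12, aud4, id_pool = 18)
    b <- random_lookup_table("OTT", 12, aud4, id_pool = 18)
    d <- random_lookup_table("GLOBI", 12, aud4, id_pool = 18)
    ov <- overlap_metrics(a, b, aud4)
    v <- venn_partition(a, b, d, aud4)
    expect_equal(ov$shared,
                 unname(v$regions[["ab"]] + v$regions[["abc"]]))
  }
})

test_that("scheme counts report distinct IDs with reference percentages", {
  ref <- lookup_table(tibble::tibble(
    taxonId = paste0("OTT:", 1:5),
    externalId = c("NCBI:1", "NCBI:2", "GBIF:3", "WORMS:4", "IF:5")
  ), "OTT")
  other <- lookup_table(tibble::tibble(
    taxonId = paste0("WD:Q", 1:2),
    externalId = c("NCBI:1", "GBIF:9")
  ), "WD")
  counts <- scheme_counts(list(ref, other), reference = "OTT", schemes = aud4)

  ref_rows <- counts[counts$resource == "OTT", ]
  expect_true(all(ref_rows$pct == 100))
  expect_equal(ref_rows$count[ref_rows$scheme == "Combined"], 5L)

  wd_rows <- counts[counts$resource == "WD", ]
  expect_equal(wd_rows$count[wd_rows$scheme == "NCBI"], 1L)
  expect_equal(wd_rows$pct[wd_rows$scheme == "NCBI"], 50L) # 1 of 2
  expect_equal(wd_rows$pct[wd_rows$scheme == "GBIF"], 100L) # 1 of 1
  expect_equal(wd_rows$pct[wd_rows$scheme == "Combined"], 40L) # 2 of 5

  expect_error(scheme_counts(list(ref), reference = "OTT",
                             schemes = character()), "non-empty")
  expect_error(scheme_counts(list(ref), reference = "WD"), "not among")
})

test_that("flagged fraction converges to the planted conflict rate", {
  p <- 0.2
  spec <- synthetic_spec(4000, resources = "OTT", coverage = 1,
                         link_prob = 1, conflict_rate = p, seed = 12)
  g <- generate_taxon_graphs(spec)
  flagged <- nrow(consistency_audit(g$tables$OTT, schemes = spec$schemes))
  expect_lt(abs(flagged / spec$n_taxa - p), 0.02)
})
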