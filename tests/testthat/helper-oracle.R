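# brute-force all-pairs join oracle: compares every taxon pair's external-ID
# sets directly, no hashing/joining machinery shared with join_graphs()
brute_force_join <- function(a, b, schemes) {
  sets_of <- function(x) {
    rows <- tibble::as_tibble(x)
    rows <- rows[sub(":.*$", "", rows$externalId) %in% schemes, ]
    split(rows$externalId, rows$taxonId)
  }
  sets_a <- sets_of(a)
  sets_b <- sets_of(b)
  out <- list()
  k <- 0L
  for (ta in names(sets_a)) {
    for (tb in names(sets_b)) {
      shared <- intersect(sets_a[[ta]], sets_b[[tb]])
      if (length(shared)) {
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          taxonIdA = ta, taxonIdB = tb,
          sharedIds = list(sort(unique(shared), method = "radix"))
        )
      }
    }
  }
  if (!k) {
    return(tibble::tibble(taxonIdA = character(), taxonIdB = character(),
                          sharedIds = list()))
  }
  res <- dplyr::bind_rows(out)
  res[order(res$taxonIdA, res$taxonIdB, method = "radix"), ]
}

# strip class/metadata so link sets can be compared structurally
canon_links <- function(links) {
  out <- tibble::tibble(
    taxonIdA = links$taxonIdA,
    taxonIdB = links$taxonIdB,
    sharedIds = vapply(links$sharedIds, paste, "", collapse = "|")
  )
  out[order(out$taxonIdA, out$taxonIdB, method = "radix"), ]
}

expect_same_links <- function(got, want) {
  expect_equal(canon_links(got), canon_links(want))
}
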