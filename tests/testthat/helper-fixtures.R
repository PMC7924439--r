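# in-code fixture builders for the three raw input dialects

`%||%` <- function(x, y) if (is.null(x)) y else x

wd_entity <- function(id, name = NULL, taxon = TRUE, ext = character(),
                      deprecated = character()) {
  claim <- function(value, rank = "normal", is_item = FALSE) {
    dv <- if (is_item) list(value = list(id = value)) else list(value = value)
    list(mainsnak = list(snaktype = "value", datavalue = dv), rank = rank)
  }
  claims <- list()
  if (taxon) claims$P31 <- list(claim("Q16521", is_item = TRUE))
  if (!is.null(name)) claims$P225 <- list(claim(name))
  for (p in names(ext)) {
    claims[[p]] <- c(claims[[p]], list(claim(ext[[p]])))
  }
  for (p in names(deprecated)) {
    claims[[p]] <- c(claims[[p]],
                     list(claim(deprecated[[p]], rank = "deprecated")))
  }
  jsonlite::toJSON(list(id = id, type = "item", claims = claims),
                   auto_unbox = TRUE)
}

write_wd_dump <- function(entities, path = tempfile(fileext = ".json")) {
  body <- paste0(entities, c(rep(",", max(length(entities) - 1L, 0L)), ""))
  writeLines(c("[", body, "]"), path)
  path
}

write_ott_fixture <- function(records, path = tempfile(fileext = ".tsv")) {
  # records: list of c(uid=, name=, sourceinfo=)
  d <- "\t|\t"
  header <- paste("uid", "parent_uid", "name", "rank", "sourceinfo",
                  "uniqname", "flags", sep = d)
  lines <- vapply(records, function(r) {
    g <- function(k, default = "") if (k %in% names(r)) r[[k]] else default
    paste(g("uid"), g("parent_uid"), g("name"), g("rank", "species"),
          g("sourceinfo"), "", "", sep = d)
  }, "")
  writeLines(c(header, lines), path)
  path
}

write_globi_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, na = "", progress = FALSE)
  path
}

# random lookup tables for property tests (independent of synthgen)
random_lookup_table <- function(res, n_taxa, schemes, link_prob = 0.6,
                                id_pool = 40L) {
  rows <- list()
  k <- 0L
  for (t in seq_len(n_taxa)) {
    for (s in schemes) {
      if (stats::runif(1) < link_prob) {
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          taxonId = paste0(res, ":", t),
          taxonName = paste("Taxon", t),
          externalId = paste0(s, ":", sample.int(id_pool, 1L))
        )
      }
    }
  }
  lookup_table(dplyr::bind_rows(rows), resource = res)
}
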