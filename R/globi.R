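#' Read a GloBI taxon-graph lookup table
#'
#' GloBI mints no taxon identifiers of its own: its taxon graph records how
#' provided names/IDs from source datasets were resolved against external
#' taxonomies. The archive dialect read here is a TSV with (at least) the
#' columns `providedTaxonId`, `providedTaxonName`, `resolvedTaxonId`,
#' `resolvedTaxonName`. Each record becomes one row: the provided side is
#' the local taxon ID — when `providedTaxonId` is empty or `null`, a stable
#' joinable key `GLOBI:null@<providedTaxonName>` is synthesized — and the
#' resolved side, parsed as a CURIE, is the external identifier. Records
#' whose resolved side fails CURIE parsing are counted and skipped.
#'
#' @param path path to the taxon-graph TSV (gz read transparently).
#' @param registry a [scheme_registry()].
#' @param provenance free-text provenance recorded on the table.
#' @return a [lookup_table()] for resource `GLOBI`. Ingest counters in
#'   [table_stats()]: `records_scanned`, `emitted`, `skipped_unparsable`,
#'   `skipped_self_scheme`, `skipped_no_key`.
#' @export
read_globi_taxon_graph <- function(path, registry = scheme_registry(),
                                   provenance = "globi-taxon-graph") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = "", progress = FALSE, quote = "")
  need <- c("providedTaxonId", "providedTaxonName",
            "resolvedTaxonId", "resolvedTaxonName")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("not a GloBI taxon-graph TSV: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  provided_missing <- is.na(df$providedTaxonId) |
    tolower(trimws(df$providedTaxonId)) %in% c("null", "")
  has_name <- !is.na(df$providedTaxonName) & nzchar(df$providedTaxonName)
  no_key <- provided_missing & !has_name
  taxon_id <- ifelse(provided_missing,
                     paste0("GLOBI:null@", df$providedTaxonName),
                     trimws(df$providedTaxonId))

  res <- trimws(ifelse(is.na(df$resolvedTaxonId), "", df$resolvedTaxonId))
  pos <- regexpr(":", res, fixed = TRUE)
  ok <- pos > 1L & pos < nchar(res) & !no_key
  scheme <- character(n)
  scheme[ok] <- as.character(
    normalize_scheme(substr(res[ok], 1L, pos[ok] - 1L), registry)
  )
  self <- ok & scheme == "GLOBI"
  keep <- ok & !self
  rows <- tibble::tibble(
    taxonId = taxon_id[keep],
    taxonName = df$providedTaxonName[keep],
    externalId = paste0(scheme[keep], ":",
                        substr(res[keep], pos[keep] + 1L, nchar(res[keep])))
  )
  stats <- list(
    records_scanned = n,
    skipped_unparsable = sum(!ok & !no_key),
    skipped_self_scheme = sum(self),
    skipped_no_key = sum(no_key)
  )
  out <- lookup_table(rows, resource = "GLOBI", provenance = provenance,
                      registry = registry, stats = stats)
  st <- table_stats(out)
  st$emitted <- nrow(out) # post-dedup, so scanned == emitted + all skips
  attr(out, "stats") <- st
  out
}
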