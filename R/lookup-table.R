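#' Identifier lookup tables
#'
#' A lookup table is a taxon graph flattened to one row per
#' (local taxon ID, external identifier) link — the unit of exchange between
#' all operations in this package. Columns:
#'
#' * `taxonId` — the owning resource's local taxon identifier as a CURIE
#'   (`WD:Q140`, `OTT:1087695`, `GLOBI:null@Procladius sp1 M_PL_014`).
#' * `taxonName` — optional name string attached to the taxon (`NA` allowed).
#' * `externalId` — a CURIE in another resource's scheme (`ITIS:183803`).
#'
#' Invariants enforced at construction: every `taxonId` uses the owning
#' resource's scheme (relaxed for GLOBI, which mints no identifiers of its
#' own — its provided-side IDs keep their original prefixes, with
#' `GLOBI:null@name` synthesized when none exists); no `externalId` uses the
#' owning scheme; exact duplicate (taxonId, externalId) pairs are dropped,
#' first-seen name winning, since all downstream metrics are set-based.
#'
#' @param rows a data frame with columns `taxonId`, `externalId` and
#'   optionally `taxonName` (CURIE strings).
#' @param resource canonical scheme token of the owning resource (raw tokens
#'   are normalized).
#' @param provenance free-text version/DOI string carried along to reports.
#' @param registry a [scheme_registry()].
#' @param stats optional named list of ingest counters (see
#'   [table_stats()]); the constructor adds/updates `deduplicated`.
#' @return a `lookup_table`: a tibble with attributes `resource`,
#'   `provenance` and `stats`.
#' @examples
#' lt <- lookup_table(
#'   data.frame(taxonId = "WD:Q140", taxonName = "Panthera leo",
#'              externalId = "ITIS:183803"),
#'   resource = "WD"
#' )
#' resource(lt)
#' @export
lookup_table <- function(rows, resource, provenance = NA_character_,
                         registry = scheme_registry(), stats = list()) {
  rows <- tibble::as_tibble(rows)
  if (!"taxonName" %in% names(rows)) rows$taxonName <- NA_character_
  need <- c("taxonId", "taxonName", "externalId")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("lookup table rows lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[need]
  rows$taxonId <- as.character(rows$taxonId)
  rows$taxonName <- as.character(rows$taxonName)
  rows$externalId <- as.character(rows$externalId)
  resource <- as.character(normalize_scheme(resource, registry))[1L]
  if (nrow(rows)) {
    ts <- curie_scheme(rows$taxonId)
    if (resource != "GLOBI" && any(ts != resource)) {
      stop("taxon IDs must use the owning resource's scheme (", resource,
           "); offending: ",
           paste(utils::head(unique(rows$taxonId[ts != resource]), 3L),
                 collapse = ", "), call. = FALSE)
    }
    es <- curie_scheme(rows$externalId)
    if (any(es == resource)) {
      stop("external IDs may not use the owning resource's scheme (",
           resource, "); offending: ",
           paste(utils::head(unique(rows$externalId[es == resource]), 3L),
                 collapse = ", "), call. = FALSE)
    }
  }
  dup <- duplicated(rows[c("taxonId", "externalId")])
  stats$deduplicated <- (stats$deduplicated %||% 0L) + sum(dup)
  rows <- rows[!dup, , drop = FALSE]
  structure(
    rows,
    class = c("lookup_table", class(tibble::tibble())),
    resource = resource,
    provenance = provenance,
    stats = stats
  )
}

#' Lookup-table accessors
#'
#' @param x a [lookup_table()] (or, for `table_stats()`, any object carrying
#'   ingest counters).
#' @return `resource()` the owning resource token; `provenance()` the
#'   free-text provenance string; `table_stats()` the named list of ingest
#'   counters; `n_taxa()` the number of distinct local taxon IDs.
#' @export
resource <- function(x) attr(x, "resource", exact = TRUE)

#' @rdname resource
#' @export
provenance <- function(x) attr(x, "provenance", exact = TRUE)

#' @rdname resource
#' @export
table_stats <- function(x) attr(x, "stats", exact = TRUE)

#' @rdname resource
#' @export
n_taxa <- function(x) length(unique(x$taxonId))

#' @export
print.lookup_table <- function(x, ...) {
  cat("# Taxon identifier lookup table: ", resource(x), sep = "")
  if (!is.na(provenance(x))) cat(" (", provenance(x), ")", sep = "")
  cat("\n# ", n_taxa(x), " taxa, ", nrow(x), " external identifier links\n",
      sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Distinct external identifiers of a lookup table
#'
#' The counting unit for every overlap/Venn/coverage metric: the set of
#' distinct `(scheme, value)` external identifiers, optionally restricted to
#' a scheme set. Row multiplicity never double-counts.
#'
#' @param x a [lookup_table()].
#' @param schemes optional character vector of canonical scheme tokens.
#' @return character vector of distinct external-ID CURIEs (byte-sorted).
#' @export
distinct_external_ids <- function(x, schemes = NULL) {
  ids <- unique(x$externalId)
  if (!is.null(schemes)) ids <- ids[curie_scheme(ids) %in% schemes]
  ids[radix_order(ids)]
}

# rows restricted to a scheme set, as a plain tibble
restrict_schemes <- function(x, schemes) {
  rows <- tibble::as_tibble(x)
  rows[curie_scheme(rows$externalId) %in% schemes, , drop = FALSE]
}

#' Write and read lookup tables as TSV
#'
#' The on-disk interchange format is a three-column TSV with header
#' `taxonId`, `taxonName`, `externalId`. Rows are byte-sorted by
#' `(taxonId, externalId)` before writing so repeated runs produce
#' byte-identical files; `write` then `read` is the identity on valid
#' tables.
#'
#' @param x a [lookup_table()].
#' @param path file path to write to / read from.
#' @return `write_lookup_table()` returns the number of rows written,
#'   invisibly; `read_lookup_table()` returns a [lookup_table()].
#' @export
write_lookup_table <- function(x, path) {
  rows <- tibble::as_tibble(x)
  rows <- rows[radix_order(rows$taxonId, rows$externalId), , drop = FALSE]
  readr::write_tsv(rows, path, na = "", progress = FALSE)
  invisible(nrow(rows))
}

#' @rdname write_lookup_table
#' @inheritParams lookup_table
#' @export
read_lookup_table <- function(path, resource, provenance = NA_character_,
                              registry = scheme_registry()) {
  rows <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          na = "", progress = FALSE)
  need <- c("taxonId", "taxonName", "externalId")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("not a lookup-table TSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lookup_table(rows, resource = resource, provenance = provenance,
               registry = registry)
}
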