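#' Wikidata property map
#'
#' Which Wikidata properties carry the taxon signal. Defaults: an item is a
#' taxon when it has an instance-of (`P31`) claim targeting the taxon class
#' (`Q16521`); its name comes from the taxon-name property (`P225`); its
#' external links from the seven identifier properties `P685` (NCBI), `P815`
#' (ITIS), `P846` (GBIF), `P830` (EOL), `P1391` (Index Fungorum), `P938`
#' (FishBase) and `P850` (WoRMS). All of it is data, not code, so a drifted
#' dump or an added scheme needs only a new map (or a JSON file with the
#' same keys).
#'
#' @param instance_of property holding the class membership claim.
#' @param taxon_class entity ID of the taxon class.
#' @param taxon_name property holding the scientific name string.
#' @param external_ids named character vector mapping property IDs to
#'   canonical scheme tokens.
#' @param file optional path to a JSON file with any of the four keys above;
#'   values in the file override the arguments.
#' @return a named list of class `wikidata_property_map`.
#' @export
wikidata_property_map <- function(instance_of = "P31", taxon_class = "Q16521",
                                  taxon_name = "P225",
                                  external_ids = c(
                                    P685 = "NCBI", P815 = "ITIS",
                                    P846 = "GBIF", P830 = "EOL",
                                    P1391 = "IF", P938 = "FISHBASE",
                                    P850 = "WORMS"
                                  ),
                                  file = NULL) {
  map <- list(instance_of = instance_of, taxon_class = taxon_class,
              taxon_name = taxon_name, external_ids = external_ids)
  if (!is.null(file)) {
    cfg <- jsonlite::fromJSON(file)
    bad <- setdiff(names(cfg), names(map))
    if (length(bad)) {
      stop("unknown property-map key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (k in names(cfg)) map[[k]] <- unlist(cfg[[k]])
  }
  structure(map, class = "wikidata_property_map")
}

# claim values for one property, honouring statement ranks: preferred and
# normal are kept, deprecated dropped (standard consumer convention)
wd_claim_values <- function(entity, prop) {
  claims <- entity$claims[[prop]]
  if (is.null(claims)) return(character())
  vals <- character()
  for (st in claims) {
    if (identical(st$rank, "deprecated")) next
    dv <- st$mainsnak$datavalue$value
    if (is.null(dv)) next # novalue / somevalue snaks carry no identifier
    v <- if (is.list(dv)) dv$id else dv
    if (!is.null(v)) vals <- c(vals, as.character(v))
  }
  vals
}

open_text_source <- function(source) {
  if (inherits(source, "connection")) {
    if (!isOpen(source)) open(source, "rt")
    return(source)
  }
  con <- if (grepl("\\.bz2$", source)) {
    bzfile(source)
  } else {
    gzfile(source) # reads plain text and gzip transparently
  }
  open(con, "rt")
  con
}

#' Extract the taxon graph from a Wikidata JSON entity dump
#'
#' Streams a Wikidata dump — one JSON entity per line, wrapped in a JSON
#' array (`[` / `]` lines and trailing commas are tolerated) — and emits one
#' lookup-table row per (taxon item, external-identifier claim). An item
#' counts as a taxon when it carries an instance-of claim targeting the
#' taxon class; its taxon-name claim becomes the row's `taxonName`. Items
#' with zero external links emit no rows but are counted in the zero bin of
#' the links-per-taxon histogram. The pass is single and memory use is
#' bounded by the output, not the dump, so the 20 GB public archive streams
#' through without being loaded.
#'
#' Malformed JSON lines are counted and skipped, never fatal: one bad line
#' in a multi-gigabyte dump must not abort the run.
#'
#' @param source path to the dump (`.gz`/`.bz2` decompressed transparently)
#'   or an open text connection.
#' @param registry a [scheme_registry()].
#' @param properties a [wikidata_property_map()].
#' @param provenance free-text provenance recorded on the table.
#' @param chunk_size lines per read; tunes IO, not results.
#' @return a list with elements `table` (a [lookup_table()] for resource
#'   `WD`) and `stats` (an `extraction_stats` object: `entities_scanned`,
#'   `taxa_extracted`, `malformed_lines`, `rows_emitted`,
#'   `links_per_taxon` histogram, `per_scheme_link_counts`).
#' @export
extract_wikidata_taxa <- function(source, registry = scheme_registry(),
                                  properties = wikidata_property_map(),
                                  provenance = "wikidata-json-dump",
                                  chunk_size = 2000L) {
  con <- open_text_source(source)
  close_here <- !inherits(source, "connection")
  if (close_here) on.exit(close(con), add = TRUE)

  ext_props <- properties$external_ids
  taxon_acc <- list(); name_acc <- list(); ext_acc <- list(); n_acc <- 0L
  entities_scanned <- 0L; malformed <- 0L; taxa_extracted <- 0L
  hist_counts <- integer(0) # index k+1 holds the number of taxa with k links
  scheme_counts <- stats::setNames(integer(length(ext_props)),
                                   unname(ext_props))

  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (!length(lines)) break
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "" || ln == "[" || ln == "]") next
      ln <- sub(",$", "", ln)
      entities_scanned <- entities_scanned + 1L
      entity <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                         error = function(e) NULL)
      if (is.null(entity) || !is.list(entity) || is.null(entity$id)) {
        malformed <- malformed + 1L
        next
      }
      classes <- wd_claim_values(entity, properties$instance_of)
      if (!properties$taxon_class %in% classes) next
      taxa_extracted <- taxa_extracted + 1L
      nm <- wd_claim_values(entity, properties$taxon_name)
      nm <- if (length(nm)) nm[[1L]] else NA_character_
      k <- 0L
      for (prop in names(ext_props)) {
        vals <- unique(wd_claim_values(entity, prop))
        if (!length(vals)) next
        sch <- ext_props[[prop]]
        k <- k + length(vals)
        scheme_counts[[sch]] <- scheme_counts[[sch]] + length(vals)
        n_acc <- n_acc + 1L
        taxon_acc[[n_acc]] <- rep(paste0("WD:", entity$id), length(vals))
        name_acc[[n_acc]] <- rep(nm, length(vals))
        ext_acc[[n_acc]] <- paste0(sch, ":", vals)
      }
      if (length(hist_counts) < k + 1L) {
        hist_counts <- c(hist_counts,
                         integer(k + 1L - length(hist_counts)))
      }
      hist_counts[[k + 1L]] <- hist_counts[[k + 1L]] + 1L
    }
  }

  rows <- tibble::tibble(
    taxonId = unlist(taxon_acc) %||% character(),
    taxonName = unlist(name_acc) %||% character(),
    externalId = unlist(ext_acc) %||% character()
  )
  stats <- structure(
    list(
      entities_scanned = entities_scanned,
      entities_parsed = entities_scanned - malformed,
      malformed_lines = malformed,
      taxa_extracted = taxa_extracted,
      rows_emitted = nrow(rows),
      links_per_taxon = stats::setNames(hist_counts,
                                        seq_along(hist_counts) - 1L),
      per_scheme_link_counts = scheme_counts
    ),
    class = "extraction_stats"
  )
  table <- lookup_table(rows, resource = "WD", provenance = provenance,
                        registry = registry,
                        stats = c(stats, list()))
  list(table = table, stats = stats)
}

#' @export
print.extraction_stats <- function(x, ...) {
  cat("<extraction_stats>\n")
  cat("  entities scanned :", x$entities_scanned,
      "(", x$malformed_lines, "malformed )\n")
  cat("  taxa extracted   :", x$taxa_extracted, "\n")
  cat("  rows emitted     :", x$rows_emitted, "\n")
  cat("  links per taxon  :",
      paste0(names(x$links_per_taxon), "x", x$links_per_taxon,
             collapse = "  "), "\n")
  invisible(x)
}
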