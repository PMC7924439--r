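#' Read the Open Tree of Life reference taxonomy
#'
#' Parses the OTT `taxonomy.tsv` dialect: a header row and fields separated
#' by the literal three-character delimiter tab-pipe-tab (`\t|\t`). Splitting
#' on the full delimiter, not on tabs, keeps name strings containing pipes
#' intact. Each record's `sourceinfo` field holds comma-separated lowercase
#' CURIEs (`ncbi:191633,worms:156905,gbif:1449280`); one lookup-table row is
#' emitted per entry whose scheme normalizes into the registry's join-scheme
#' set. Entries in other schemes (`silva`, `irmng`, ...) are counted in the
#' ingest stats but excluded from rows unless `include_all_schemes = TRUE`.
#'
#' @param path path to `taxonomy.tsv`, or to a directory containing it.
#' @param registry a [scheme_registry()].
#' @param include_all_schemes emit rows for every parsable sourceinfo entry,
#'   whatever its scheme.
#' @param provenance free-text provenance recorded on the table.
#' @return a [lookup_table()] for resource `OTT`. Ingest counters in
#'   [table_stats()]: `records_scanned` (taxonomy records),
#'   `entries_scanned` (sourceinfo entries), `emitted`,
#'   `skipped_unparsable`, `skipped_non_target`, `per_scheme_entry_counts`.
#' @export
read_ott_taxonomy <- function(path, registry = scheme_registry(),
                              include_all_schemes = FALSE,
                              provenance = "ott-taxonomy") {
  if (dir.exists(path)) path <- file.path(path, "taxonomy.tsv")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty taxonomy file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t|\t", fixed = TRUE)
  header <- parts[[1L]]
  need <- c("uid", "name", "sourceinfo")
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop("not an OTT taxonomy.tsv (tab-pipe-tab dialect): missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(need, header)
  body <- parts[-1L]
  field <- function(k) {
    vapply(body, function(p) if (length(p) >= k) p[[k]] else "", "",
           USE.NAMES = FALSE)
  }
  uid <- field(idx[[1L]])
  nm <- field(idx[[2L]])
  src <- field(idx[[3L]])

  entries <- strsplit(src, ",", fixed = TRUE)
  n_entries <- lengths(entries)
  uid_rep <- rep(uid, n_entries)
  name_rep <- rep(nm, n_entries)
  e <- trimws(unlist(entries) %||% character())
  nonblank <- nzchar(e)
  e <- e[nonblank]; uid_rep <- uid_rep[nonblank]; name_rep <- name_rep[nonblank]

  pos <- regexpr(":", e, fixed = TRUE)
  ok <- pos > 1L & pos < nchar(e)
  scheme <- character(length(e))
  scheme[ok] <- as.character(
    normalize_scheme(substr(e[ok], 1L, pos[ok] - 1L), registry)
  )
  value <- substr(e, pos + 1L, nchar(e))

  targets <- registry$join_schemes
  keep <- ok & (include_all_schemes | scheme %in% targets)
  rows <- tibble::tibble(
    taxonId = paste0("OTT:", uid_rep[keep]),
    taxonName = ifelse(nzchar(name_rep[keep]), name_rep[keep], NA_character_),
    externalId = paste0(scheme[keep], ":", value[keep])
  )
  stats <- list(
    records_scanned = length(body),
    entries_scanned = length(e),
    skipped_unparsable = sum(!ok),
    skipped_non_target = sum(ok & !keep),
    per_scheme_entry_counts = table(scheme[ok])
  )
  out <- lookup_table(rows, resource = "OTT", provenance = provenance,
                      registry = registry, stats = stats)
  st <- table_stats(out)
  st$emitted <- nrow(out) # post-dedup, so entries == emitted + all skips
  attr(out, "stats") <- st
  out
}
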