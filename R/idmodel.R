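#' Canonical identifier scheme registry
#'
#' Biodiversity resources refer to external databases with a zoo of raw
#' tokens: OTT `sourceinfo` uses lowercase prefixes (`ncbi:`, `worms:`),
#' Wikidata uses property identifiers, GloBI uses mixed-case CURIE prefixes.
#' A `scheme_registry` maps every raw token onto one canonical scheme token
#' and carries the two scheme sets the method works with:
#'
#' * **join schemes** — NCBI, ITIS, GBIF, EOL, IF, FISHBASE, WORMS: the
#'   identifiers used to equi-join two taxon graphs.
#' * **audit schemes** — NCBI, GBIF, IF, WORMS: the identifiers used for the
#'   overlap, Venn, and consistency metrics.
#'
#' Lookup is total: a token the registry does not know is passed through
#' uppercased and flagged, never rejected, so a new identifier scheme in an
#' input file cannot abort a multi-hour ingest.
#'
#' @param aliases named character vector of extra raw-token -> canonical
#'   mappings (names are raw tokens, matched case-insensitively).
#' @param join_schemes,audit_schemes canonical scheme tokens overriding the
#'   defaults. Audit schemes must be a subset of join schemes.
#' @return an object of class `scheme_registry`.
#' @examples
#' reg <- scheme_registry()
#' normalize_scheme("worms", reg)
#' join_schemes(reg)
#' @export
scheme_registry <- function(aliases = character(), join_schemes = NULL,
                            audit_schemes = NULL) {
  al <- c(
    ncbi = "NCBI", itis = "ITIS", gbif = "GBIF", eol = "EOL",
    "if" = "IF", indexfungorum = "IF", fishbase = "FISHBASE",
    worms = "WORMS", wd = "WD", wikidata = "WD", ott = "OTT",
    globi = "GLOBI", irmng = "IRMNG", silva = "SILVA",
    inat = "INAT", inaturalist = "INAT"
  )
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases)))) {
      stop("`aliases` must be a named character vector", call. = FALSE)
    }
    extra <- toupper(unname(aliases))
    names(extra) <- tolower(names(aliases))
    al[names(extra)] <- extra
  }
  js <- toupper(join_schemes %||% c("NCBI", "ITIS", "GBIF", "EOL", "IF",
                                    "FISHBASE", "WORMS"))
  as_ <- toupper(audit_schemes %||% c("NCBI", "GBIF", "IF", "WORMS"))
  if (!all(as_ %in% js)) {
    stop("audit schemes must be a subset of join schemes; offending: ",
         paste(setdiff(as_, js), collapse = ", "), call. = FALSE)
  }
  canonical <- unique(c(unname(al), js, as_))
  lookup <- c(al, stats::setNames(canonical, tolower(canonical)))
  lookup <- lookup[!duplicated(names(lookup))]
  structure(
    list(lookup = lookup, join_schemes = js, audit_schemes = as_,
         canonical = canonical),
    class = "scheme_registry"
  )
}

#' @rdname scheme_registry
#' @param x a `scheme_registry`.
#' @export
join_schemes <- function(x) x$join_schemes

#' @rdname scheme_registry
#' @export
audit_schemes <- function(x) x$audit_schemes

#' @export
print.scheme_registry <- function(x, ...) {
  cat("<scheme_registry>\n")
  cat("  join schemes : ", paste(x$join_schemes, collapse = ", "), "\n", sep = "")
  cat("  audit schemes: ", paste(x$audit_schemes, collapse = ", "), "\n", sep = "")
  cat("  aliases      : ", length(x$lookup), " raw tokens\n", sep = "")
  invisible(x)
}

#' Normalize a raw scheme token
#'
#' Case-insensitive lookup of a raw source token (e.g. `"worms"`, `"Fishbase"`)
#' against the registry's alias table. Unknown tokens are passed through
#' uppercased; the returned vector carries a logical `"unknown"` attribute
#' marking them. Normalization is idempotent.
#'
#' @param raw character vector of raw tokens; elements must be non-empty after
#'   trimming.
#' @param registry a [scheme_registry()].
#' @return character vector of canonical scheme tokens with attribute
#'   `"unknown"` (logical, same length).
#' @examples
#' normalize_scheme(c("ncbi", "Fishbase", "frobnitz"))
#' @export
normalize_scheme <- function(raw, registry = scheme_registry()) {
  if (!is.character(raw)) stop("`raw` must be character", call. = FALSE)
  raw <- trimws(raw)
  if (length(raw) && any(is.na(raw) | !nzchar(raw))) {
    stop("scheme tokens must be non-empty", call. = FALSE)
  }
  hit <- registry$lookup[tolower(raw)]
  unknown <- is.na(hit)
  out <- ifelse(unknown, toupper(raw), unname(hit))
  attr(out, "unknown") <- unname(unknown)
  out
}

#' Parse and serialize compact identifiers (CURIEs)
#'
#' The on-disk identifier dialect everywhere in this package is the compact
#' form `SCHEME:value`, e.g. `ITIS:183803`. `parse_curie()` splits on the
#' *first* colon only, so local identifiers that embed free text — GloBI's
#' `GLOBI:null@Procladius sp1 M_PL_014` — survive losslessly. The prefix is
#' normalized through the registry; the value is kept verbatim apart from
#' trimming leading/trailing whitespace. Values are case-sensitive; schemes
#' are not.
#'
#' @param text character vector of `SCHEME:value` strings.
#' @param registry a [scheme_registry()].
#' @return a tibble with columns `scheme`, `value`, `known` (was the scheme
#'   prefix recognized?), and `curie` (the canonical serialization).
#' @examples
#' parse_curie(c("ITIS:183803", "GLOBI:null@Procladius sp1 M_PL_014"))
#' curie("worms", "156905")
#' @export
parse_curie <- function(text, registry = scheme_registry()) {
  if (!is.character(text)) stop("`text` must be character", call. = FALSE)
  text <- trimws(text)
  pos <- regexpr(":", text, fixed = TRUE)
  prefix <- trimws(substr(text, 1L, pmax(pos - 1L, 0L)))
  value <- trimws(substr(text, pos + 1L, nchar(text)))
  bad <- is.na(text) | pos < 1L | !nzchar(prefix) | !nzchar(value)
  if (any(bad)) {
    stop("not a SCHEME:value identifier: ",
         paste(sQuote(text[bad]), collapse = ", "), call. = FALSE)
  }
  scheme <- normalize_scheme(prefix, registry)
  known <- !attr(scheme, "unknown")
  scheme <- as.character(scheme)
  tibble::tibble(
    scheme = scheme,
    value = value,
    known = known,
    curie = paste0(scheme, ":", value)
  )
}

#' @rdname parse_curie
#' @param scheme,value components to serialize; `scheme` is normalized first.
#' @export
curie <- function(scheme, value, registry = scheme_registry()) {
  value <- trimws(as.character(value))
  if (any(is.na(value) | !nzchar(value))) {
    stop("identifier values must be non-empty", call. = FALSE)
  }
  paste0(as.character(normalize_scheme(scheme, registry)), ":", value)
}

#' @rdname parse_curie
#' @param x character vector of serialized CURIEs.
#' @export
curie_scheme <- function(x) sub(":.*$", "", x)

#' @rdname parse_curie
#' @export
curie_value <- function(x) sub("^[^:]*:", "", x)
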