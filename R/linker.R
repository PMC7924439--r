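#' Link two taxon graphs by joining on shared external identifiers
#'
#' The core operation: instead of comparing name strings, two resources are
#' linked wherever a taxon in each carries the *same* external identifier.
#' Implemented as a hash equi-join keyed on the serialized external-ID CURIE
#' (restricted to `schemes`), then grouped per taxon pair, so one cross-link
#' is produced per (taxonA, taxonB) pair sharing at least one identifier,
#' with the complete shared set attached. Many-to-many matches are all
#' retained: if `WD:Q140` points to `ITIS:183803`, every taxon in the other
#' resource that also points to `ITIS:183803` — including synonyms — gets a
#' cross-link. No transitive closure is applied; a call links exactly one
#' pair of resources.
#'
#' @param a,b [lookup_table()]s of two distinct resources.
#' @param schemes scheme tokens to join on; defaults to the registry's seven
#'   join schemes.
#' @param registry a [scheme_registry()].
#' @param allow_same_resource permit `resource(a) == resource(b)`; only
#'   meaningful for self-join diagnostics, off by default.
#' @return a `cross_links` tibble with columns `taxonIdA`, `taxonIdB`,
#'   `sharedIds` (list of CURIE character vectors), byte-sorted by
#'   `(taxonIdA, taxonIdB)`; attributes `resource_a`, `resource_b`,
#'   `schemes`.
#' @examples
#' wd <- lookup_table(
#'   data.frame(taxonId = "WD:Q140", taxonName = "Panthera leo",
#'              externalId = "ITIS:183803"), "WD")
#' gl <- lookup_table(
#'   data.frame(taxonId = "GLOBI:null@Panthera leo",
#'              externalId = "ITIS:183803"), "GLOBI")
#' join_graphs(wd, gl)
#' @export
join_graphs <- function(a, b, schemes = NULL, registry = scheme_registry(),
                        allow_same_resource = FALSE) {
  schemes <- schemes %||% registry$join_schemes
  if (identical(resource(a), resource(b)) && !allow_same_resource) {
    stop("both tables belong to resource ", resource(a),
         "; use consistency_audit() for within-resource checks",
         call. = FALSE)
  }
  ra <- restrict_schemes(a, schemes)[c("taxonId", "externalId")]
  rb <- restrict_schemes(b, schemes)[c("taxonId", "externalId")]
  j <- dplyr::inner_join(ra, rb, by = "externalId",
                         suffix = c("A", "B"),
                         relationship = "many-to-many")
  links <- j |>
    dplyr::group_by(.data$taxonIdA, .data$taxonIdB) |>
    dplyr::summarise(
      sharedIds = list(sort(unique(.data$externalId), method = "radix")),
      .groups = "drop"
    )
  links <- links[radix_order(links$taxonIdA, links$taxonIdB), , drop = FALSE]
  new_cross_links(links, resource(a), resource(b), schemes)
}

new_cross_links <- function(links, resource_a, resource_b, schemes) {
  structure(
    tibble::as_tibble(links),
    class = c("cross_links", class(tibble::tibble())),
    resource_a = resource_a,
    resource_b = resource_b,
    schemes = schemes
  )
}

#' @export
print.cross_links <- function(x, ...) {
  cat("# Cross-links: ", attr(x, "resource_a"), " <-> ",
      attr(x, "resource_b"), " on ",
      paste(attr(x, "schemes"), collapse = ","), "\n", sep = "")
  cat("# ", nrow(x), " linked taxon pairs\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Write / read cross-links as TSV
#'
#' Columns `taxonIdA`, `taxonIdB`, `sharedIds` with the shared set
#' pipe-separated; rows byte-sorted for stable output.
#'
#' @param links a `cross_links` object (see [join_graphs()]).
#' @param path file path.
#' @return `write_cross_links()` the number of links written, invisibly;
#'   `read_cross_links()` a `cross_links` object.
#' @export
write_cross_links <- function(links, path) {
  flat <- tibble::tibble(
    taxonIdA = links$taxonIdA,
    taxonIdB = links$taxonIdB,
    sharedIds = vapply(links$sharedIds, paste, "", collapse = "|")
  )
  readr::write_tsv(flat, path, na = "", progress = FALSE)
  invisible(nrow(flat))
}

#' @rdname write_cross_links
#' @param resource_a,resource_b resource tokens of the two link ends (stored
#'   as metadata; inferred from the taxon-ID prefixes when `NULL`).
#' @param schemes scheme tokens the links were joined on (metadata).
#' @export
read_cross_links <- function(path, resource_a = NULL, resource_b = NULL,
                             schemes = NULL) {
  flat <- readr::read_tsv(path, col_types = "ccc", na = "", progress = FALSE)
  need <- c("taxonIdA", "taxonIdB", "sharedIds")
  miss <- setdiff(need, names(flat))
  if (length(miss)) {
    stop("not a cross-links TSV: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  links <- tibble::tibble(
    taxonIdA = flat$taxonIdA,
    taxonIdB = flat$taxonIdB,
    sharedIds = strsplit(flat$sharedIds, "|", fixed = TRUE)
  )
  new_cross_links(
    links,
    resource_a %||% (if (nrow(links)) curie_scheme(links$taxonIdA[[1L]]) else NA_character_),
    resource_b %||% (if (nrow(links)) curie_scheme(links$taxonIdB[[1L]]) else NA_character_),
    schemes
  )
}

#' Append inferred cross-links to a base taxon graph
#'
#' Writes the linkage back into a resource's lookup table: for every
#' cross-link whose base-side taxon is in `base`, one new row
#' `(base taxon, foreign taxon ID)` is appended — the foreign resource's
#' taxon ID becomes an external identifier of the base taxon, exactly how
#' the Wikidata links were folded into the GloBI taxon graph. The operation
#' is idempotent: rows already present are deduplicated away, so merging
#' the same links twice appends nothing.
#'
#' @param base a [lookup_table()].
#' @param links a `cross_links` object from [join_graphs()].
#' @param source_side `"a"` or `"b"`: which end of the cross-links is the
#'   base table.
#' @return the augmented [lookup_table()]; the number of rows actually
#'   appended is in `attr(, "appended")` and in
#'   `table_stats()$links_appended`.
#' @export
merge_links <- function(base, links, source_side = c("a", "b")) {
  source_side <- match.arg(source_side)
  base_col <- if (source_side == "a") "taxonIdA" else "taxonIdB"
  foreign_col <- if (source_side == "a") "taxonIdB" else "taxonIdA"
  absent <- setdiff(unique(links[[base_col]]), base$taxonId)
  if (length(absent)) {
    stop("cross-link base-side taxa absent from base table: ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) ", ..." else "", call. = FALSE)
  }
  new_rows <- unique(tibble::tibble(
    taxonId = links[[base_col]],
    externalId = links[[foreign_col]]
  ))
  # first-seen name of the base taxon carries over to its new rows
  first_name <- tibble::as_tibble(base)[c("taxonId", "taxonName")]
  first_name <- first_name[!duplicated(first_name$taxonId), , drop = FALSE]
  new_rows <- dplyr::left_join(new_rows, first_name, by = "taxonId")
  combined <- dplyr::bind_rows(
    tibble::as_tibble(base),
    new_rows[c("taxonId", "taxonName", "externalId")]
  )
  stats <- table_stats(base) %||% list()
  out <- lookup_table(combined, resource = resource(base),
                      provenance = provenance(base), stats = stats)
  appended <- nrow(out) - nrow(base)
  st <- table_stats(out)
  st$links_appended <- appended
  attr(out, "stats") <- st
  attr(out, "appended") <- appended
  out
}
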