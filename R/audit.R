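#' Same-scheme identifier conflicts within one taxon graph
#'
#' A taxon graph is *inconsistent* when one of its taxon IDs links to two or
#' more distinct external identifiers in the same scheme — the signature of
#' synonymy, an outdated name, or a name-resolution bug. One record is
#' returned per (taxonId, scheme) with at least two distinct values,
#' byte-sorted by taxon ID then scheme, so the output is invariant under row
#' order of the input. Name strings attached to the offending rows are
#' collected for inspection but never themselves trigger a flag; only
#' same-scheme ID multiplicity does.
#'
#' @param x a [lookup_table()].
#' @param schemes scheme tokens to audit; defaults to the registry's four
#'   audit schemes (NCBI, GBIF, IF, WORMS).
#' @param registry a [scheme_registry()].
#' @return a tibble with columns `taxonId`, `scheme`, `nValues`,
#'   `values` (list of CURIEs), `names` (list of distinct name strings).
#' @examples
#' gl <- lookup_table(data.frame(
#'   taxonId = "GLOBI:null@Senecio pectinatus",
#'   taxonName = "Senecio pectinatus",
#'   externalId = c("GBIF:8317096", "GBIF:8414746")), "GLOBI")
#' consistency_audit(gl)
#' @export
consistency_audit <- function(x, schemes = NULL,
                              registry = scheme_registry()) {
  schemes <- schemes %||% registry$audit_schemes
  rows <- restrict_schemes(x, schemes)
  rows$scheme <- curie_scheme(rows$externalId)
  out <- rows |>
    dplyr::group_by(.data$taxonId, .data$scheme) |>
    dplyr::summarise(
      nValues = dplyr::n_distinct(.data$externalId),
      values = list(sort(unique(.data$externalId), method = "radix")),
      names = list(sort(unique(.data$taxonName[!is.na(.data$taxonName)]),
                        method = "radix")),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$nValues >= 2L)
  out[radix_order(out$taxonId, out$scheme), , drop = FALSE]
}

#' Same-scheme conflicts across linked taxon pairs
#'
#' Two overlapping taxon IDs are inconsistent when their pooled external
#' identifiers contain two or more distinct values in one scheme — e.g. one
#' resource says `NCBI:1` where the other says `NCBI:2` for the same linked
#' taxon. For every cross-link, both taxa's external IDs (restricted to the
#' audit schemes) are pooled and each scheme with multiplicity is reported.
#'
#' @param links a `cross_links` object from [join_graphs()].
#' @param a,b the two [lookup_table()]s the links were derived from.
#' @inheritParams consistency_audit
#' @return a tibble with columns `taxonIdA`, `taxonIdB`, `scheme`,
#'   `nValues`, `values` (list of CURIEs), byte-sorted.
#' @export
pairwise_consistency <- function(links, a, b, schemes = NULL,
                                 registry = scheme_registry()) {
  schemes <- schemes %||% registry$audit_schemes
  if (!nrow(links)) {
    return(tibble::tibble(taxonIdA = character(), taxonIdB = character(),
                          scheme = character(), nValues = integer(),
                          values = list()))
  }
  pairs <- tibble::tibble(.pair = seq_len(nrow(links)),
                          taxonIdA = links$taxonIdA,
                          taxonIdB = links$taxonIdB)
  ra <- restrict_schemes(a, schemes)[c("taxonId", "externalId")]
  rb <- restrict_schemes(b, schemes)[c("taxonId", "externalId")]
  pooled <- dplyr::bind_rows(
    dplyr::inner_join(pairs, ra, by = c(taxonIdA = "taxonId"),
                      relationship = "many-to-many"),
    dplyr::inner_join(pairs, rb, by = c(taxonIdB = "taxonId"),
                      relationship = "many-to-many")
  )
  pooled$scheme <- curie_scheme(pooled$externalId)
  out <- pooled |>
    dplyr::group_by(.data$.pair, .data$taxonIdA, .data$taxonIdB,
                    .data$scheme) |>
    dplyr::summarise(
      nValues = dplyr::n_distinct(.data$externalId),
      values = list(sort(unique(.data$externalId), method = "radix")),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$nValues >= 2L)
  out <- out[radix_order(out$taxonIdA, out$taxonIdB, out$scheme), , drop = FALSE]
  out$.pair <- NULL
  out
}

#' Overlap between two taxon graphs' external-identifier sets
#'
#' Counts distinct external identifiers (restricted to `schemes`) in each
#' table and in their intersection, with coverage fractions in both
#' directions. Overlap is the similarity measure between two taxon graphs;
#' the counting unit is the distinct (scheme, value) pair, never rows.
#'
#' @param a,b [lookup_table()]s.
#' @inheritParams consistency_audit
#' @return an `overlap_report`: list with `resource_a`, `resource_b`,
#'   `n_a`, `n_b`, `shared`, `fraction_a_covered`, `fraction_b_covered`,
#'   `schemes`.
#' @export
overlap_metrics <- function(a, b, schemes = NULL,
                            registry = scheme_registry()) {
  schemes <- schemes %||% registry$audit_schemes
  sa <- distinct_external_ids(a, schemes)
  sb <- distinct_external_ids(b, schemes)
  shared <- length(intersect(sa, sb))
  structure(
    list(
      resource_a = resource(a), resource_b = resource(b),
      n_a = length(sa), n_b = length(sb), shared = shared,
      fraction_a_covered = if (length(sa)) shared / length(sa) else NA_real_,
      fraction_b_covered = if (length(sb)) shared / length(sb) else NA_real_,
      schemes = schemes
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> ", x$resource_a, " vs ", x$resource_b,
      " on ", paste(x$schemes, collapse = ","), "\n", sep = "")
  cat(sprintf("  %s: %d distinct external IDs\n", x$resource_a, x$n_a))
  cat(sprintf("  %s: %d distinct external IDs\n", x$resource_b, x$n_b))
  cat(sprintf("  shared: %d (%.1f%% of %s, %.1f%% of %s)\n", x$shared,
              100 * x$fraction_a_covered, x$resource_a,
              100 * x$fraction_b_covered, x$resource_b))
  invisible(x)
}

#' Seven-region Venn decomposition of three taxon graphs
#'
#' Splits the union of three resources' distinct external-identifier sets
#' into the seven exclusive Venn regions, with a per-scheme breakdown of the
#' triple intersection. The region counts are asserted to sum to the union
#' cardinality on every call.
#'
#' @param a,b,c [lookup_table()]s of three distinct resources.
#' @inheritParams consistency_audit
#' @return a `venn_partition`: list with `resources`, `schemes`, `regions`
#'   (named counts `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`),
#'   `union_size`, `abc_by_scheme`.
#' @export
venn_partition <- function(a, b, c, schemes = NULL,
                           registry = scheme_registry()) {
  schemes <- schemes %||% registry$audit_schemes
  res <- c(resource(a), resource(b), resource(c))
  if (anyDuplicated(res)) {
    stop("venn_partition() needs three distinct resources, got: ",
         paste(res, collapse = ", "), call. = FALSE)
  }
  sa <- distinct_external_ids(a, schemes)
  sb <- distinct_external_ids(b, schemes)
  sc <- distinct_external_ids(c, schemes)
  u <- unique(c(sa, sb, sc))
  ina <- u %in% sa; inb <- u %in% sb; inc <- u %in% sc
  regions <- c(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc)
  )
  stopifnot(sum(regions) == length(u))
  abc_ids <- u[ina & inb & inc]
  abc_by_scheme <- table(factor(curie_scheme(abc_ids), levels = schemes))
  structure(
    list(resources = res, schemes = schemes, regions = regions,
         union_size = length(u),
         abc_by_scheme = stats::setNames(as.integer(abc_by_scheme),
                                         names(abc_by_scheme))),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  r <- x$resources
  lab <- c(
    a_only = r[1], b_only = r[2], c_only = r[3],
    ab = paste(r[1], r[2], sep = "&"), ac = paste(r[1], r[3], sep = "&"),
    bc = paste(r[2], r[3], sep = "&"),
    abc = paste(r, collapse = "&")
  )
  cat("<venn_partition> ", paste(r, collapse = " / "),
      " on ", paste(x$schemes, collapse = ","), "\n", sep = "")
  for (k in names(x$regions)) {
    cat(sprintf("  %-12s %d\n", lab[[k]], x$regions[[k]]))
  }
  cat("  triple-intersection by scheme: ",
      paste0(names(x$abc_by_scheme), "=", x$abc_by_scheme, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Per-scheme link counts relative to a reference resource
#'
#' For each table and scheme, the number of distinct external identifiers,
#' plus a `Combined` row summing over schemes, with percentages of the
#' reference resource's counts (reference vs itself is 100% by
#' construction). The percentages are relative size estimates, not set
#' intersections.
#'
#' @param tables a list of [lookup_table()]s.
#' @param reference a [lookup_table()] or the resource token of one of
#'   `tables`.
#' @inheritParams consistency_audit
#' @return a tibble with columns `resource`, `scheme`, `count`, `pct`
#'   (integer percentage of the reference's count for that scheme).
#' @export
scheme_counts <- function(tables, reference, schemes = NULL,
                          registry = scheme_registry()) {
  schemes <- schemes %||% registry$audit_schemes
  if (!length(schemes)) stop("`schemes` must be non-empty", call. = FALSE)
  if (is.character(reference)) {
    tok <- as.character(normalize_scheme(reference, registry))
    hit <- which(vapply(tables, resource, "") == tok)
    if (!length(hit)) {
      stop("reference resource ", tok, " not among the tables",
           call. = FALSE)
    }
    reference <- tables[[hit[[1L]]]]
  }
  count_one <- function(t) {
    per <- vapply(schemes,
                  function(s) length(distinct_external_ids(t, s)), 0L)
    c(per, Combined = sum(per))
  }
  ref_counts <- count_one(reference)
  out <- lapply(tables, function(t) {
    cnt <- count_one(t)
    tibble::tibble(
      resource = resource(t),
      scheme = names(cnt),
      count = as.integer(unname(cnt)),
      pct = unname(ifelse(ref_counts > 0L,
                          as.integer(round(100 * cnt / ref_counts)),
                          NA_integer_))
    )
  })
  dplyr::bind_rows(out)
}
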