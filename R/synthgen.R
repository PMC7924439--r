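#' Specify a synthetic multi-resource taxon graph
#'
#' The generator emulates the statistical structure the linker and the
#' audits assume: a pool of true underlying taxa, each holding one canonical
#' external identifier per scheme; several resources that each cover a
#' random subset of the taxa and carry a random subset of their scheme
#' links; and, optionally, planted same-scheme conflicts. Canonical
#' identifier values are drawn from disjoint integer ranges per scheme, and
#' every planted "wrong" value comes from a reserved range never used as a
#' canonical ID, so ground truth is exact: a conflict can never silently
#' create a true link, and accidental cross-scheme collisions are
#' impossible.
#'
#' @param n_taxa number of true underlying taxa (>= 1).
#' @param resources resource tokens (>= 1); must be disjoint from `schemes`.
#' @param coverage probability a true taxon appears in a resource; scalar or
#'   one value per resource.
#' @param schemes external-identifier schemes the taxa carry IDs in.
#' @param link_prob probability a covered taxon carries its ID in a given
#'   scheme; scalar or one value per scheme.
#' @param conflict_rate probability a taxon-in-resource with at least one
#'   link receives a second, wrong same-scheme ID.
#' @param seed integer seed; the same spec and seed reproduce the tables
#'   byte-identically.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_taxa, resources = c("WD", "OTT", "GLOBI"),
                           coverage = 0.8,
                           schemes = c("NCBI", "GBIF", "IF", "WORMS"),
                           link_prob = 0.7, conflict_rate = 0, seed = 1L) {
  stopifnot(length(n_taxa) == 1L, n_taxa >= 1L)
  if (!length(resources)) stop("at least one resource required", call. = FALSE)
  resources <- toupper(resources)
  schemes <- toupper(schemes)
  if (anyDuplicated(resources)) stop("duplicate resources", call. = FALSE)
  if (length(intersect(resources, schemes))) {
    stop("resources must be disjoint from schemes: ",
         paste(intersect(resources, schemes), collapse = ", "),
         call. = FALSE)
  }
  coverage <- rep_len(coverage, length(resources))
  link_prob <- rep_len(link_prob, length(schemes))
  probs <- c(coverage, link_prob, conflict_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_taxa = as.integer(n_taxa), resources = resources,
         coverage = stats::setNames(coverage, resources),
         schemes = schemes,
         link_prob = stats::setNames(link_prob, schemes),
         conflict_rate = conflict_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# canonical ID value of taxon t in scheme i: disjoint 10^7-wide blocks;
# wrong values live in the block's upper half, keyed by resource so two
# resources can never share a planted-wrong value
synth_canonical_value <- function(scheme_idx, taxon) {
  scheme_idx * 10000000L + taxon
}

synth_wrong_value <- function(scheme_idx, resource_idx, taxon) {
  scheme_idx * 10000000L + 5000000L + resource_idx * 1000000L + taxon
}

synth_taxon_id <- function(res, taxa) {
  switch(res,
    WD = paste0("WD:Q9", taxa),
    GLOBI = paste0("GLOBI:null@Synthtaxon ", taxa),
    paste0(res, ":", taxa)
  )
}

#' Generate synthetic taxon graphs with planted ground truth
#'
#' Draws the tables a [synthetic_spec()] describes and returns them together
#' with the generator's own bookkeeping: every cross-link that must exist
#' between each pair of resources (taxa present in both that share at least
#' one scheme link, with the exact shared identifier set) and every planted
#' same-scheme conflict. Deterministic: the same spec yields identical
#' output on every call.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `tables` (named list of [lookup_table()]s, one per
#'   resource) and `truth`, itself a list with `cross_links` (named
#'   `"A|B"` per resource pair: tibbles `taxonIdA`, `taxonIdB`, `sharedIds`)
#'   and `conflicts` (named per resource: tibbles `taxonId`, `scheme`,
#'   `values`).
#' @examples
#' g <- generate_taxon_graphs(synthetic_spec(20, seed = 7))
#' names(g$tables)
#' nrow(g$truth$cross_links[["WD|OTT"]])
#' @export
generate_taxon_graphs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, synth_generate_impl(spec))
}

synth_generate_impl <- function(spec) {
  n <- spec$n_taxa
  S <- length(spec$schemes)
  R <- length(spec$resources)
  registry <- scheme_registry(
    join_schemes = unique(c(spec$schemes,
                            c("NCBI", "ITIS", "GBIF", "EOL", "IF",
                              "FISHBASE", "WORMS"))),
    audit_schemes = spec$schemes
  )

  # canonical CURIE of taxon t in scheme s: [t, s] matrix
  canon <- vapply(seq_len(S), function(i) {
    paste0(spec$schemes[[i]], ":", synth_canonical_value(i, seq_len(n)))
  }, character(n))
  canon <- matrix(canon, nrow = n)

  present <- matrix(FALSE, n, R)
  linked <- vector("list", R) # per resource: n x S logical
  tables <- vector("list", R)
  conflicts <- vector("list", R)
  names(tables) <- names(conflicts) <- spec$resources

  for (j in seq_len(R)) {
    res <- spec$resources[[j]]
    present[, j] <- stats::runif(n) < spec$coverage[[j]]
    has <- matrix(stats::runif(n * S) < rep(spec$link_prob, each = n), n, S)
    has[!present[, j], ] <- FALSE
    linked[[j]] <- has

    idx <- which(has, arr.ind = TRUE)
    rows <- tibble::tibble(
      taxonId = synth_taxon_id(res, idx[, 1L]),
      taxonName = paste("Taxon", idx[, 1L]),
      externalId = canon[idx]
    )

    # plant conflicts: eligible taxa (>=1 link) get a second, wrong value
    # in one of their linked schemes, chosen uniformly
    eligible <- which(rowSums(has) > 0L)
    hit <- eligible[stats::runif(length(eligible)) < spec$conflict_rate]
    conf <- tibble::tibble(taxonId = character(), scheme = character(),
                           values = list())
    if (length(hit)) {
      pick <- vapply(hit, function(t) {
        ss <- which(has[t, ])
        if (length(ss) == 1L) ss else sample(ss, 1L)
      }, 0L)
      wrong <- paste0(spec$schemes[pick], ":",
                      synth_wrong_value(pick, j, hit))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        taxonId = synth_taxon_id(res, hit),
        taxonName = paste("Taxon", hit),
        externalId = wrong
      ))
      conf <- tibble::tibble(
        taxonId = synth_taxon_id(res, hit),
        scheme = spec$schemes[pick],
        values = mapply(function(t, i, w) {
          sort(c(canon[t, i], w), method = "radix")
        }, hit, pick, wrong, SIMPLIFY = FALSE)
      )
      conf <- conf[radix_order(conf$taxonId, conf$scheme), , drop = FALSE]
    }
    conflicts[[j]] <- conf
    rows <- rows[radix_order(rows$taxonId, rows$externalId), , drop = FALSE]
    tables[[j]] <- lookup_table(rows, resource = res,
                                provenance = paste0("synthetic seed=",
                                                    spec$seed),
                                registry = registry)
  }

  cross_links <- list()
  if (R >= 2L) {
    for (j in seq_len(R - 1L)) {
      for (k in seq(j + 1L, R)) {
        both <- which(present[, j] & present[, k])
        shared_mask <- linked[[j]][both, , drop = FALSE] &
          linked[[k]][both, , drop = FALSE]
        nshared <- rowSums(shared_mask)
        keep <- both[nshared > 0L]
        mask <- shared_mask[nshared > 0L, , drop = FALSE]
        cl <- tibble::tibble(
          taxonIdA = synth_taxon_id(spec$resources[[j]], keep),
          taxonIdB = synth_taxon_id(spec$resources[[k]], keep),
          sharedIds = lapply(seq_along(keep), function(i) {
            sort(canon[keep[[i]], mask[i, ]], method = "radix")
          })
        )
        cl <- cl[radix_order(cl$taxonIdA, cl$taxonIdB), , drop = FALSE]
        cross_links[[paste(spec$resources[[j]], spec$resources[[k]],
                           sep = "|")]] <- cl
      }
    }
  }

  list(tables = tables,
       truth = list(cross_links = cross_links, conflicts = conflicts))
}

#' Worked micro-example taxon graphs
#'
#' Three hand-built miniature lookup tables exercising the canonical linking
#' and audit situations: the lion (`WD:Q140` pointing to `ITIS:183803`) that
#' links Wikidata into GloBI's synonym ring; a marine taxon whose Wikidata
#' item (`WD:Q7247420`) and OTT record (`OTT:1087695`) carry the same three
#' WoRMS/GBIF/NCBI identifiers — overlapping *and* consistent; the GloBI
#' name `Procladius sp1 M_PL_014` resolved to six different provisional NCBI
#' taxa, and `Senecio pectinatus` (an outdated name) resolved to two GBIF
#' keys — both inconsistent.
#'
#' @return a named list of [lookup_table()]s: `wd`, `ott`, `globi`.
#' @examples
#' fx <- example_taxon_graphs()
#' join_graphs(fx$wd, fx$ott)
#' consistency_audit(fx$globi)
#' @export
example_taxon_graphs <- function() {
  wd <- lookup_table(tibble::tibble(
    taxonId = c("WD:Q140", rep("WD:Q7247420", 3L)),
    taxonName = c("Panthera leo", NA, NA, NA),
    externalId = c("ITIS:183803", "WORMS:156905", "GBIF:1449280",
                   "NCBI:191633")
  ), resource = "WD", provenance = "worked example")
  ott <- lookup_table(tibble::tibble(
    taxonId = rep("OTT:1087695", 3L),
    taxonName = NA_character_,
    externalId = c("NCBI:191633", "WORMS:156905", "GBIF:1449280")
  ), resource = "OTT", provenance = "worked example")
  globi <- lookup_table(tibble::tibble(
    taxonId = c(rep("GLOBI:null@Procladius sp1 M_PL_014", 6L),
                rep("GLOBI:null@Senecio pectinatus", 2L)),
    taxonName = c(rep("Procladius sp1 M_PL_014", 6L),
                  rep("Senecio pectinatus", 2L)),
    externalId = c("NCBI:1981571", "NCBI:1981569", "NCBI:1981572",
                   "NCBI:1981573", "NCBI:1981574", "NCBI:1981570",
                   "GBIF:8317096", "GBIF:8414746")
  ), resource = "GLOBI", provenance = "worked example")
  list(wd = wd, ott = ott, globi = globi)
}
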