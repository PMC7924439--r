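#' Pipeline run configuration
#'
#' Bundles everything the end-to-end pipeline needs besides the input files:
#' the scheme registry (with any alias overrides), the Wikidata property
#' map, the output directory and the log level. `read_run_config()` loads
#' the same settings from a JSON file with keys `out_dir`, `log_level`,
#' `scheme_aliases`, `join_schemes`, `audit_schemes`,
#' `wikidata_properties`; any other key is rejected by name.
#'
#' @param out_dir directory the pipeline writes its outputs into.
#' @param registry a [scheme_registry()].
#' @param properties a [wikidata_property_map()].
#' @param log_level one of `"info"`, `"quiet"`, `"debug"`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = ".", registry = scheme_registry(),
                       properties = wikidata_property_map(),
                       log_level = c("info", "quiet", "debug")) {
  structure(
    list(out_dir = out_dir, registry = registry, properties = properties,
         log_level = match.arg(log_level)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path path to a JSON configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  allowed <- c("out_dir", "log_level", "scheme_aliases", "join_schemes",
               "audit_schemes", "wikidata_properties")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  registry <- scheme_registry(
    aliases = unlist(cfg$scheme_aliases) %||% character(),
    join_schemes = cfg$join_schemes,
    audit_schemes = cfg$audit_schemes
  )
  props <- wikidata_property_map()
  if (!is.null(cfg$wikidata_properties)) {
    wp <- cfg$wikidata_properties
    badp <- setdiff(names(wp), names(props))
    if (length(badp)) {
      stop("unknown config key(s): ",
           paste(paste0("wikidata_properties.", badp), collapse = ", "),
           call. = FALSE)
    }
    for (k in names(wp)) props[[k]] <- unlist(wp[[k]])
  }
  run_config(
    out_dir = cfg$out_dir %||% ".",
    registry = registry,
    properties = props,
    log_level = cfg$log_level %||% "info"
  )
}

#' Run the full linking-and-audit pipeline
#'
#' Wires the whole method end to end: extract the Wikidata taxon graph from
#' a JSON entity dump, read the OTT taxonomy and the GloBI taxon graph,
#' join Wikidata to GloBI on the seven join schemes, fold the inferred
#' Wikidata links back into the GloBI table, then compute the audit suite
#' on the four audit schemes — pairwise overlaps, the three-way Venn
#' partition, per-scheme counts against OTT, and per-resource consistency
#' audits. Outputs (all byte-stable: every table is sorted before writing)
#' land in `config$out_dir`:
#'
#' * `wd.tsv`, `ott.tsv`, `globi.tsv` — the three lookup tables;
#' * `links-wd-globi.tsv` — the inferred cross-links;
#' * `globi-merged.tsv` — GloBI with the Wikidata links appended;
#' * `inconsistent-<resource>.tsv` — per-resource audit reports;
#' * `metrics.json` — the metrics report (the only field that varies
#'   between identical runs is the provenance timestamp).
#'
#' Empty inputs produce empty outputs and a warning, not an error.
#'
#' @param config a [run_config()].
#' @param wd_dump path to the Wikidata JSON entity dump.
#' @param ott_path path to the OTT `taxonomy.tsv` (or its directory).
#' @param globi_tsv path to the GloBI taxon-graph TSV.
#' @return the metrics report, invisibly (the same structure written to
#'   `metrics.json`).
#' @export
run_pipeline <- function(config, wd_dump, ott_path, globi_tsv) {
  stopifnot(inherits(config, "run_config"))
  old <- options(taxograph.log_level = config$log_level)
  on.exit(options(old), add = TRUE)
  reg <- config$registry
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  tg_log("info", "extracting Wikidata taxon graph from ", wd_dump)
  wd_x <- extract_wikidata_taxa(wd_dump, registry = reg,
                                properties = config$properties,
                                provenance = basename(wd_dump))
  wd <- wd_x$table
  tg_log("info", "  ", wd_x$stats$taxa_extracted, " taxa, ",
         wd_x$stats$rows_emitted, " links (",
         wd_x$stats$malformed_lines, " malformed lines skipped)")

  tg_log("info", "reading OTT taxonomy from ", ott_path)
  ott <- read_ott_taxonomy(ott_path, registry = reg,
                           provenance = basename(ott_path))
  tg_log("info", "  ", table_stats(ott)$records_scanned, " records, ",
         nrow(ott), " links")

  tg_log("info", "reading GloBI taxon graph from ", globi_tsv)
  globi <- read_globi_taxon_graph(globi_tsv, registry = reg,
                                  provenance = basename(globi_tsv))
  tg_log("info", "  ", table_stats(globi)$records_scanned, " records, ",
         nrow(globi), " links")

  if (!nrow(wd) && !nrow(ott) && !nrow(globi)) {
    warning("all three inputs are empty; writing empty outputs",
            call. = FALSE)
  }

  write_lookup_table(wd, out("wd.tsv"))
  write_lookup_table(ott, out("ott.tsv"))
  write_lookup_table(globi, out("globi.tsv"))

  tg_log("info", "joining WD to GloBI on ",
         paste(join_schemes(reg), collapse = ","))
  links_wd_globi <- join_graphs(wd, globi, schemes = join_schemes(reg),
                                registry = reg)
  links_wd_ott <- join_graphs(wd, ott, schemes = join_schemes(reg),
                              registry = reg)
  write_cross_links(links_wd_globi, out("links-wd-globi.tsv"))

  merged <- merge_links(globi, links_wd_globi, source_side = "b")
  appended <- attr(merged, "appended")
  tg_log("info", "  ", nrow(links_wd_globi), " cross-links, ",
         appended, " rows appended to GloBI")
  write_lookup_table(merged, out("globi-merged.tsv"))

  aud <- audit_schemes(reg)
  tables <- list(wd = wd, ott = ott, globi = globi)
  inconsistent <- lapply(tables, consistency_audit, schemes = aud,
                         registry = reg)
  for (nm in names(inconsistent)) {
    rep_ <- inconsistent[[nm]]
    flat <- tibble::tibble(
      taxonId = rep_$taxonId,
      scheme = rep_$scheme,
      nValues = rep_$nValues,
      values = vapply(rep_$values, paste, "", collapse = "|"),
      names = vapply(rep_$names, paste, "", collapse = "|")
    )
    readr::write_tsv(flat, out(paste0("inconsistent-", nm, ".tsv")),
                     na = "", progress = FALSE)
  }

  ov <- list(
    wd_ott = overlap_metrics(wd, ott, aud, reg),
    globi_ott = overlap_metrics(globi, ott, aud, reg),
    globi_wd = overlap_metrics(globi, wd, aud, reg)
  )
  venn <- venn_partition(ott, wd, globi, aud, reg)
  counts <- scheme_counts(tables[c("ott", "wd", "globi")], reference = "OTT",
                          schemes = aud, registry = reg)

  report <- list(
    provenance = list(
      wikidata = provenance(wd), ott = provenance(ott),
      globi = provenance(globi),
      generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    extraction = list(
      entities_scanned = wd_x$stats$entities_scanned,
      malformed_lines = wd_x$stats$malformed_lines,
      taxa_extracted = wd_x$stats$taxa_extracted,
      links_per_taxon = as.list(wd_x$stats$links_per_taxon)
    ),
    links = list(
      wd_globi = nrow(links_wd_globi),
      wd_ott = nrow(links_wd_ott),
      appended_to_globi = appended
    ),
    overlap = lapply(ov, function(o) {
      list(resources = c(o$resource_a, o$resource_b),
           n_a = o$n_a, n_b = o$n_b, shared = o$shared,
           pct_a_covered = round(100 * o$fraction_a_covered, 1),
           pct_b_covered = round(100 * o$fraction_b_covered, 1))
    }),
    venn = list(resources = venn$resources,
                regions = as.list(venn$regions),
                abc_by_scheme = as.list(venn$abc_by_scheme)),
    scheme_counts = counts,
    inconsistencies = lapply(inconsistent, nrow)
  )
  jsonlite::write_json(report, out("metrics.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  tg_log("info", "metrics written to ", out("metrics.json"))
  invisible(report)
}
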