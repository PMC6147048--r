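with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full Mo-utilization pipeline
#'
#' Orchestrates every analysis stage over a community (generated by
#' [generate_community()] or read from disk with [read_community()]):
#' hit filtering, family assignment, presence profiles, trait calls,
#' orphan cross-tabulation, occurrence summaries, transporter overlaps,
#' molybdoproteome sizes, family occurrence, domain-fusion detection,
#' tungstoprotein prediction, trait-by-environment tables, and — when the
#' community carries an alignment set — gene trees and HGT scoring. The run
#' is deterministic given the inputs; any stage error propagates with the
#' stage name attached.
#'
#' @param community An `mo_community` (or a directory path to read one from).
#' @param config An [mo_config()].
#' @param outdir Optional directory: when given, all primary result tables
#'   are serialized as tab-delimited text.
#' @return An object of class `mo_bundle` with one element per stage result.
#' @export
run_pipeline <- function(community, config = mo_config(), outdir = NULL) {
  if (is.character(community)) community <- read_community(community)
  metadata <- with_stage("metadata",
                         validate_metadata(community$metadata))
  registry <- seed_registry()
  filtered <- with_stage("filter_hits", filter_hits(
    community$hits, evalue_max = config$evalue_max,
    coverage_min = config$coverage_min))
  assignments <- with_stage("assign_families",
                            assign_families(filtered, registry))
  profiles <- with_stage("build_profiles",
                         build_profiles(assignments, metadata))
  trait_calls <- with_stage("call_mo_utilization",
                            call_mo_utilization(profiles, metadata, config))
  orphans <- with_stage("classify_orphans", classify_orphans(trait_calls))
  occurrence <- with_stage("occurrence_summary", occurrence_summary(
    trait_calls, .data$kingdom, .data$mo_utilizing,
    decimals = config$percent_decimals))
  overlaps <- with_stage("transporter_overlap", {
    ks <- intersect(kingdom_levels(), unique(metadata$kingdom))
    stats::setNames(lapply(ks, function(k) {
      transporter_overlap(trait_calls, kingdom = k)
    }), ks)
  })
  proteomes <- with_stage("proteome_sizes", proteome_sizes(
    assignments, metadata, rich_threshold = config$rich_threshold))
  families <- with_stage("family_occurrence",
                         family_occurrence(trait_calls,
                                           config$percent_decimals))
  fusions <- with_stage("fusion", {
    if (nrow(community$domains) > 0) {
      arch <- tile_architectures(community$domains,
                                 evalue_max = config$evalue_max,
                                 overlap_tolerance = config$overlap_tolerance)
      ev <- detect_fusions(arch)
      list(architectures = arch, events = ev,
           partners = cross_family_partners(ev))
    } else {
      list(architectures = NULL, events = NULL, partners = NULL)
    }
  })
  tungsto <- with_stage("predict_tungstoproteins",
                        predict_tungstoproteins(assignments, metadata))
  env <- with_stage("trait_by_factor", {
    ks <- unique(metadata$kingdom)
    if ("bacteria" %in% ks) {
      list(habitat = trait_by_factor(trait_calls, metadata, "habitat",
                                     decimals = config$env_decimals),
           oxygen = trait_by_factor(trait_calls, metadata, "oxygen_req",
                                    decimals = config$env_decimals))
    } else NULL
  })
  hgt <- NULL
  if (!is.null(community$hgt)) {
    hgt <- with_stage("hgt_score", {
      trees <- lapply(community$hgt$alignments, gene_tree)
      focal <- community$hgt$focal %||% {
        # default: score the taxon whose id marks it as the recipient
        grep("recipient", community$hgt$taxonomy$taxon_id, value = TRUE)[1]
      }
      list(trees = trees,
           report = hgt_score(trees, community$hgt$taxonomy, focal,
                              config$hgt_min_trees))
    })
  }
  bundle <- structure(
    list(config = config, metadata = metadata, assignments = assignments,
         profiles = profiles, trait_calls = trait_calls, orphans = orphans,
         occurrence = occurrence, overlaps = overlaps, proteomes = proteomes,
         families = families, fusions = fusions, tungsto = tungsto,
         env = env, hgt = hgt,
         log = c(n_hits = nrow(community$hits), n_filtered = nrow(filtered),
                 n_assigned = nrow(assignments),
                 n_organisms = nrow(metadata))),
    class = "mo_bundle"
  )
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Serialize a result bundle as tab-delimited tables
#'
#' @param bundle An `mo_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    utils::write.table(as.data.frame(x), file.path(outdir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(bundle$trait_calls, "trait_calls.tsv")
  wt(bundle$orphans, "orphans.tsv")
  wt(bundle$occurrence, "summary.tsv")
  for (k in names(bundle$overlaps)) {
    wt(bundle$overlaps[[k]], sprintf("venn_%s.tsv", k))
  }
  wt(bundle$proteomes, "proteomes.tsv")
  wt(bundle$families, "families.tsv")
  wt(bundle$fusions$events, "fusions.tsv")
  wt(bundle$fusions$partners, "partners.tsv")
  wt(bundle$tungsto, "tungstoproteins.tsv")
  if (!is.null(bundle$env)) {
    wt(bundle$env$habitat, "env_habitat_mo_trait.tsv")
    wt(bundle$env$oxygen, "env_oxygen_req_mo_trait.tsv")
  }
  if (!is.null(bundle$hgt)) {
    wt(bundle$hgt$report$per_gene, "hgt_report.tsv")
    for (g in names(bundle$hgt$trees)) {
      ape::write.tree(bundle$hgt$trees[[g]],
                      file.path(outdir, sprintf("tree_%s.nwk", g)))
    }
  }
  invisible(outdir)
}

#' @export
print.mo_bundle <- function(x, ...) {
  cat("<mo_bundle>\n")
  cat(sprintf("  organisms: %d | hits: %d -> filtered: %d -> assigned: %d\n",
              x$log["n_organisms"], x$log["n_hits"], x$log["n_filtered"],
              x$log["n_assigned"]))
  print(x$occurrence)
  if (!is.null(x$hgt)) print(x$hgt$report)
  invisible(x)
}

#' @rdname tidy
#' @param x An `mo_bundle`.
#' @param ... Unused.
#' @export
tidy.mo_bundle <- function(x, ...) {
  as_tibble(x$trait_calls)
}

#' @rdname glance
#' @param x An `mo_bundle`.
#' @param ... Unused.
#' @export
glance.mo_bundle <- function(x, ...) {
  tc <- x$trait_calls
  tibble(
    n_organisms = nrow(tc),
    n_mo_utilizing = sum(tc$mo_utilizing),
    pct_mo_utilizing = percent_of(sum(tc$mo_utilizing), nrow(tc),
                                  x$config$percent_decimals),
    n_rich = sum(tc$rich),
    n_fusion_events = if (is.null(x$fusions$events)) 0L
                      else nrow(x$fusions$events),
    hgt_flagged = if (is.null(x$hgt)) NA else x$hgt$report$flagged
  )
}

#' @rdname tidy
#' @export
tidy.mo_hgt <- function(x, ...) {
  x$per_gene
}

#' @rdname glance
#' @export
glance.mo_hgt <- function(x, ...) {
  tibble(focal = x$focal, focal_class = x$focal_class,
         n_supporting = x$n_supporting,
         n_trees_with_focal = x$n_trees_with_focal,
         flagged = x$flagged)
}

#' @rdname tidy
#' @export
tidy.mo_factor_table <- function(x, ...) {
  out <- as_tibble(x)
  out$factor <- attr(x, "factor")
  out$feature <- attr(x, "feature")
  out
}
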