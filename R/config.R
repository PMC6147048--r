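#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults follow the
#' standard screen for Mo/W utilization genes: homology hits kept at
#' e-value <= 0.01 with at least 20% query (seed) coverage; the Moco
#' biosynthetic pathway requires a strict majority (>= 4) of the 7 key genes
#' with every one of the three biosynthetic steps represented; an organism is
#' "molybdoprotein-rich" when it encodes strictly more than 20 molybdoprotein
#' genes; a horizontal-transfer flag needs concordant foreign placement in at
#' least 3 gene trees.
#'
#' @param evalue_max Maximum e-value for a homology hit to be retained.
#' @param coverage_min Minimum fraction of the query (seed) covered by the
#'   alignment, in `[0, 1]`.
#' @param rich_threshold Molybdoproteome size above which (strictly) an
#'   organism counts as molybdoprotein-rich.
#' @param pathway_majority Minimum number of the 7 key Moco genes that must be
#'   present (on top of the per-step rule) for a pathway call.
#' @param hgt_min_trees Minimum number of gene trees with concordant foreign
#'   sister placement for an HGT flag.
#' @param overlap_tolerance Residues by which accepted domain hits may overlap
#'   when tiling a protein's domain architecture.
#' @param percent_decimals Decimal places for occurrence percentages.
#' @param env_decimals Decimal places for environment-association tables.
#' @param rng_seed Integer seed used by the synthetic generators.
#' @return An object of class `mo_config` (a validated named list).
#' @examples
#' mo_config()
#' mo_config(rich_threshold = 25)
#' @export
mo_config <- function(evalue_max = 0.01,
                      coverage_min = 0.20,
                      rich_threshold = 20L,
                      pathway_majority = 4L,
                      hgt_min_trees = 3L,
                      overlap_tolerance = 10L,
                      percent_decimals = 1L,
                      env_decimals = 2L,
                      rng_seed = 1L) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    abort("`evalue_max` must be > 0")
  }
  if (!is.numeric(coverage_min) || coverage_min < 0 || coverage_min > 1) {
    abort("`coverage_min` must lie in [0, 1]")
  }
  if (rich_threshold < 0) abort("`rich_threshold` must be >= 0")
  if (pathway_majority < 0 || pathway_majority > 7) {
    abort("`pathway_majority` must lie in 0..7")
  }
  structure(
    list(
      evalue_max = as.numeric(evalue_max),
      coverage_min = as.numeric(coverage_min),
      rich_threshold = as.integer(rich_threshold),
      pathway_majority = as.integer(pathway_majority),
      hgt_min_trees = as.integer(hgt_min_trees),
      overlap_tolerance = as.integer(overlap_tolerance),
      percent_decimals = as.integer(percent_decimals),
      env_decimals = as.integer(env_decimals),
      rng_seed = as.integer(rng_seed)
    ),
    class = "mo_config"
  )
}

#' @export
print.mo_config <- function(x, ...) {
  cat("<mo_config>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
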