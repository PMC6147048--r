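#' Tile a protein's domain architecture
#'
#' Greedy selection of domain hits for one protein: hits above the e-value
#' cutoff are visited in order of descending score (ties: lower e-value,
#' then smaller start) and accepted iff they overlap every previously
#' accepted hit by at most `overlap_tolerance` residues (default 10,
#' absorbing the boundary jitter of real domain annotations). The accepted
#' set is returned sorted by start, so tiling is deterministic and invariant
#' to input row order.
#'
#' @param domain_hits Domain hits of a single protein (`protein_id`,
#'   `domain_id`, `start`, `end`, `score`, `evalue`).
#' @param evalue_max E-value cutoff for considering a hit.
#' @param overlap_tolerance Maximum allowed residue overlap between accepted
#'   hits.
#' @return The accepted hits, sorted by `start`.
#' @export
tile_architecture <- function(domain_hits, evalue_max = 0.01,
                              overlap_tolerance = 10) {
  hits <- as_tibble(domain_hits)
  if (length(unique(hits$protein_id)) > 1) {
    abort("tile_architecture expects hits of a single protein")
  }
  hits <- hits |>
    filter(.data$evalue <= evalue_max) |>
    arrange(desc(.data$score), .data$evalue, .data$start)
  keep <- greedy_tile(hits$start, hits$end, overlap_tolerance)
  arrange(hits[keep, ], .data$start)
}

# greedy acceptance over score-ordered intervals; returns logical keep vector
greedy_tile <- function(start, end, overlap_tolerance) {
  n <- length(start)
  keep <- logical(n)
  acc_s <- integer(0)
  acc_e <- integer(0)
  for (i in seq_len(n)) {
    ov <- pmin(end[i], acc_e) - pmax(start[i], acc_s) + 1
    if (all(ov <= overlap_tolerance)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, start[i])
      acc_e <- c(acc_e, end[i])
    }
  }
  keep
}

#' Tile architectures for many proteins
#'
#' @param domains Domain-hit tibble covering any number of proteins.
#' @inheritParams tile_architecture
#' @return Accepted hits for all proteins, sorted by protein then start.
#' @export
tile_architectures <- function(domains, evalue_max = 0.01,
                               overlap_tolerance = 10) {
  dm <- as_tibble(domains) |>
    filter(.data$evalue <= evalue_max) |>
    arrange(.data$protein_id, desc(.data$score), .data$evalue, .data$start)
  if (nrow(dm) == 0) return(dm)
  idx_by_protein <- split(seq_len(nrow(dm)), dm$protein_id)
  keep <- logical(nrow(dm))
  for (idx in idx_by_protein) {
    if (length(idx) == 1) {
      keep[idx] <- TRUE
    } else {
      keep[idx] <- greedy_tile(dm$start[idx], dm$end[idx], overlap_tolerance)
    }
  }
  dm[keep, ] |> arrange(.data$protein_id, .data$start)
}

#' Detect domain fusions on molybdoproteins
#'
#' A fusion event is recorded per (protein, partner domain) where the tiled
#' architecture contains at least one catalytic domain of exactly one
#' molybdoenzyme family plus at least one non-catalytic partner domain.
#' Proteins whose architecture carries catalytic domains of two or more
#' families are reported in the `multi_family` attribute and emit no events.
#'
#' @param architectures Tiled domain hits ([tile_architectures()]).
#' @param catalytic Catalytic-domain registry ([catalytic_domains()]).
#' @param partner_annotations Partner annotation table
#'   ([fusion_partner_annotations()]); used to mark partners already known to
#'   be functionally linked to molybdoproteins.
#' @return A tibble of fusion events (`protein_id`, `organism_id`,
#'   `family_id`, `partner_domain`, `known_partner`) with attribute
#'   `multi_family` listing skipped protein ids.
#' @export
detect_fusions <- function(architectures, catalytic = catalytic_domains(),
                           partner_annotations = fusion_partner_annotations()) {
  arch <- as_tibble(architectures) |>
    left_join(rename(catalytic, cat_family = "family_id"), by = "domain_id")
  per_protein <- arch |>
    group_by(.data$protein_id) |>
    summarise(
      n_fam = dplyr::n_distinct(.data$cat_family, na.rm = TRUE),
      .groups = "drop"
    )
  multi <- per_protein$protein_id[per_protein$n_fam >= 2]
  single <- per_protein$protein_id[per_protein$n_fam == 1]
  events <- arch |>
    filter(.data$protein_id %in% single) |>
    group_by(.data$protein_id) |>
    mutate(family_id = .data$cat_family[!is.na(.data$cat_family)][1]) |>
    ungroup() |>
    filter(is.na(.data$cat_family)) |>
    distinct(.data$protein_id, .data$family_id,
             partner_domain = .data$domain_id) |>
    mutate(organism_id = organism_from_protein(.data$protein_id)) |>
    left_join(select(partner_annotations, partner_domain = "domain_id",
                     known_partner = "known"),
              by = "partner_domain") |>
    mutate(known_partner = dplyr::coalesce(.data$known_partner, FALSE)) |>
    select("protein_id", "organism_id", "family_id", "partner_domain",
           "known_partner") |>
    arrange(.data$protein_id, .data$partner_domain)
  attr(events, "multi_family") <- sort(multi)
  events
}

#' Partner domains across molybdoenzyme families
#'
#' Summarises fusion events per partner domain: the set of molybdoenzyme
#' families it fuses with and whether it spans multiple families (the
#' signature of a partner tied to Moco utilization generally rather than to
#' one enzyme).
#'
#' @param events Fusion events from [detect_fusions()].
#' @return A tibble `partner_domain`, `families` (sorted, `,`-joined),
#'   `n_families`, `multi_family`, `n_proteins`.
#' @export
cross_family_partners <- function(events) {
  ev <- as_tibble(events)
  if (nrow(ev) == 0) {
    return(tibble(partner_domain = character(), families = character(),
                  n_families = integer(), multi_family = logical(),
                  n_proteins = integer()))
  }
  ev |>
    group_by(.data$partner_domain) |>
    summarise(
      families = paste(sort(unique(.data$family_id)), collapse = ","),
      n_families = dplyr::n_distinct(.data$family_id),
      n_proteins = dplyr::n_distinct(.data$protein_id),
      .groups = "drop"
    ) |>
    mutate(multi_family = .data$n_families >= 2) |>
    select("partner_domain", "families", "n_families", "multi_family",
           "n_proteins")
}
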