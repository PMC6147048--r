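#' Filter homology hits by e-value and query coverage
#'
#' Keeps a hit iff `evalue <= evalue_max` and the aligned fraction of the
#' query, `(qend - qstart + 1) / query_length`, is at least `coverage_min`.
#' Coverage is computed on the query (seed) side: seeds are full-length
#' curated proteins while target genomes may be fragmentary. Input order is
#' preserved and the operation is idempotent.
#'
#' @param hits A hit tibble (see [read_hit_table()]).
#' @param query_lengths A data frame mapping `query_id` to `query_length`
#'   (residues). Defaults to the seed registry's seed lengths.
#' @param evalue_max,coverage_min Thresholds; defaults 0.01 and 0.20.
#' @return The retained hits, with a `coverage` column appended.
#' @examples
#' hits <- tibble::tibble(
#'   query_id = "MOAA_ECOLI", subject_id = "org|p1", pident = 45,
#'   aln_length = 300, mismatches = 150, gap_opens = 2, qstart = 1,
#'   qend = 300, sstart = 10, send = 309, evalue = 1e-40, bitscore = 250
#' )
#' filter_hits(hits)
#' @export
filter_hits <- function(hits, query_lengths = NULL,
                        evalue_max = 0.01, coverage_min = 0.20) {
  if (is.null(query_lengths)) {
    query_lengths <- seed_registry() |>
      distinct(.data$seed_id, .data$seed_length) |>
      rename(query_id = "seed_id", query_length = "seed_length")
  }
  query_lengths <- distinct(as_tibble(query_lengths),
                            .data$query_id, .data$query_length)
  out <- left_join(as_tibble(hits), query_lengths, by = "query_id")
  missing <- unique(out$query_id[is.na(out$query_length)])
  if (length(missing) > 0) {
    abort(sprintf("query_length unknown for: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- out |>
    mutate(coverage = (.data$qend - .data$qstart + 1) / .data$query_length) |>
    filter(.data$evalue <= evalue_max, .data$coverage >= coverage_min) |>
    select(-"query_length")
  out
}

# per-query best subject under the tie-broken ordering:
# max bitscore, then min evalue, then lexicographically smallest subject_id
best_hits_by_query <- function(hits) {
  as_tibble(hits) |>
    arrange(.data$query_id, desc(.data$bitscore), .data$evalue,
            .data$subject_id) |>
    group_by(.data$query_id) |>
    slice(1) |>
    ungroup() |>
    select("query_id", "subject_id", "bitscore", "evalue")
}

#' Best hit of one query
#'
#' The subject with maximal bit score among the (already filtered) hits of
#' `query_id`; ties are broken by lower e-value, then by lexicographically
#' smaller subject id.
#'
#' @param hits Filtered hit tibble.
#' @param query_id Query identifier.
#' @return The best subject id, or `NA_character_` if the query has no hits.
#' @export
best_hit <- function(hits, query_id) {
  sub <- filter(as_tibble(hits), .data$query_id == !!query_id)
  if (nrow(sub) == 0) return(NA_character_)
  best_hits_by_query(sub)$subject_id[1]
}

#' Bidirectional best hits
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best hit in the A-vs-B table
#' and `a` is `b`'s best hit in the B-vs-A table. Both tables are assumed
#' pre-filtered by [filter_hits()]. The result is a partial matching: no
#' identifier appears twice.
#'
#' @param hits_ab Hits of A-side queries against B-side subjects.
#' @param hits_ba Hits of B-side queries against A-side subjects.
#' @return A tibble with columns `a_id`, `b_id`.
#' @export
bidirectional_best_hits <- function(hits_ab, hits_ba) {
  fwd <- best_hits_by_query(hits_ab) |>
    select(a_id = "query_id", b_id = "subject_id")
  rev <- best_hits_by_query(hits_ba) |>
    select(b_id = "query_id", a_id = "subject_id")
  out <- dplyr::inner_join(fwd, rev, by = c("a_id", "b_id")) |>
    arrange(.data$a_id)
  out
}

#' Assign proteins to seed families
#'
#' Hits are seed-vs-proteome: `query_id` is a registry seed, `subject_id` a
#' protein. For each protein the top seed is selected (max bit score, then
#' min e-value, then smaller seed id). A protein is assigned to family F only
#' if its top seed is an F member; if the top seed is an exclusion seed
#' (NuoG, NifE) the protein is discarded. Proteins whose top bit score is
#' shared by seeds of two different families are left unassigned and reported
#' in the `ambiguous` attribute rather than guessed.
#'
#' Bifunctional seeds spanning two registry rows (e.g. Cnx1 = moeA + mogA)
#' yield one assignment per row.
#'
#' @param hits Filtered seed-vs-proteome hits.
#' @param registry Seed registry (default [seed_registry()]).
#' @param protein_organism Optional named character vector mapping protein id
#'   to organism id; by default organism ids are recovered from protein ids of
#'   the form `"<organism>|<protein>"`.
#' @return A tibble of assignments (`organism_id`, `protein_id`, `family_id`,
#'   `gene_label`, `class`, `seed_id`, `bitscore`, `evalue`) with attribute
#'   `ambiguous` listing unassignable protein ids.
#' @export
assign_families <- function(hits, registry = seed_registry(),
                            protein_organism = NULL) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    out <- tibble(organism_id = character(), protein_id = character(),
                  family_id = character(), gene_label = character(),
                  class = character(), seed_id = character(),
                  bitscore = numeric(), evalue = numeric())
    attr(out, "ambiguous") <- character()
    return(out)
  }
  unknown <- setdiff(unique(hits$query_id), registry$seed_id)
  if (length(unknown) > 0) {
    abort(sprintf("hits reference seeds absent from the registry: %s",
                  paste(unknown, collapse = ", ")))
  }
  seed_family <- distinct(registry, .data$seed_id, .data$family_id,
                          .data$role)
  ranked <- hits |>
    left_join(seed_family, by = c(query_id = "seed_id"),
              relationship = "many-to-many") |>
    arrange(.data$subject_id, desc(.data$bitscore), .data$evalue,
            .data$query_id)
  top <- ranked |> group_by(.data$subject_id) |> slice(1) |> ungroup()
  # ambiguity: top bitscore shared by different seeds of different families
  # (one bifunctional seed spanning two registry rows is not ambiguous)
  amb <- ranked |>
    group_by(.data$subject_id) |>
    filter(.data$bitscore == max(.data$bitscore)) |>
    summarise(nseed = dplyr::n_distinct(.data$query_id),
              nfam = dplyr::n_distinct(.data$family_id), .groups = "drop") |>
    filter(.data$nseed > 1, .data$nfam > 1) |>
    pull("subject_id")
  top <- filter(top, !.data$subject_id %in% amb, .data$role == "member")
  out <- top |>
    select(protein_id = "subject_id", seed_id = "query_id",
           "bitscore", "evalue") |>
    left_join(filter(registry, .data$role == "member") |>
                select("seed_id", "family_id", "gene_label", "class"),
              by = "seed_id", relationship = "many-to-many")
  if (is.null(protein_organism)) {
    out$organism_id <- organism_from_protein(out$protein_id)
  } else {
    out$organism_id <- unname(protein_organism[out$protein_id])
  }
  out <- select(out, "organism_id", "protein_id", "family_id", "gene_label",
                "class", "seed_id", "bitscore", "evalue") |>
    distinct(.data$protein_id, .data$family_id, .data$gene_label,
             .keep_all = TRUE) |>
    arrange(.data$organism_id, .data$protein_id, .data$family_id)
  attr(out, "ambiguous") <- sort(amb)
  out
}
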