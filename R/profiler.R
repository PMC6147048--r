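#' Occurrence summary by group
#'
#' Counts positives per group and reports the percentage with round-half-up
#' at `decimals`, the rounding used throughout printed trait-occurrence
#' tables (e.g. 249/256 prints as 97.3). Empty groups are flagged with an
#' `NA` percent, never divided.
#'
#' @param data A data frame with one row per organism (or unit).
#' @param group Column (tidy-eval) to group by, e.g. `kingdom`.
#' @param feature Logical column (tidy-eval) marking positives.
#' @param decimals Decimal places for the percentage.
#' @return A `mo_occurrence` tibble: `group`, `n_total`, `n_positive`,
#'   `percent`.
#' @examples
#' df <- tibble::tibble(kingdom = rep("archaea", 256),
#'                      mo = rep(c(TRUE, FALSE), c(249, 7)))
#' occurrence_summary(df, kingdom, mo) # 97.3
#' @export
occurrence_summary <- function(data, group, feature, decimals = 1) {
  out <- as_tibble(data) |>
    group_by(group = {{ group }}) |>
    summarise(n_total = dplyr::n(),
              n_positive = sum({{ feature }}, na.rm = TRUE),
              .groups = "drop") |>
    mutate(percent = percent_of(.data$n_positive, .data$n_total, decimals))
  class(out) <- c("mo_occurrence", class(out))
  out
}

#' Transporter overlap (Venn) table
#'
#' Exact-region counts for the transporter systems of one kingdom, plus the
#' complement (organisms carrying none). The inclusion-exclusion identity is
#' verified before returning; a violation indicates an upstream bug and is
#' raised as an error.
#'
#' @param trait_calls Output of [call_mo_utilization()]; rows are restricted
#'   to Mo-utilizing organisms of `kingdom`.
#' @param kingdom Kingdom to profile (`NULL` = all rows as given).
#' @param systems Character vector of system columns; defaults to MOT1/MOT2
#'   for eukaryotes and the three ABC systems otherwise.
#' @return A `mo_overlap` tibble with one row per non-empty region (`region`
#'   is the `&`-joined set label, `degree` its size) plus a `none` row;
#'   attributes `total`, `none`, and `set_sizes`.
#' @export
transporter_overlap <- function(trait_calls, kingdom = NULL, systems = NULL) {
  tc <- as_tibble(trait_calls)
  if (!is.null(kingdom)) tc <- filter(tc, .data$kingdom == !!kingdom)
  tc <- filter(tc, .data$mo_utilizing)
  if (is.null(systems)) {
    systems <- if (identical(kingdom, "eukaryota")) c("MOT1", "MOT2")
               else c("ModABC", "WtpABC", "TupABC")
  }
  m <- as.matrix(tc[, systems, drop = FALSE])
  key <- apply(m, 1, function(r) paste(systems[r], collapse = "&"))
  key[key == ""] <- "none"
  all_regions <- unlist(lapply(seq_along(systems), function(k) {
    utils::combn(systems, k, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = c(all_regions, "none")))
  out <- tibble(
    region = c(all_regions, "none"),
    degree = c(lengths(strsplit(all_regions, "&", fixed = TRUE)), 0L),
    count = as.integer(counts)
  )
  # inclusion-exclusion: region counts must rebuild the marginal set sizes
  set_sizes <- vapply(systems, function(s) sum(m[, s]), integer(1))
  rebuilt <- vapply(systems, function(s) {
    sum(out$count[vapply(strsplit(out$region, "&", fixed = TRUE),
                         function(r) s %in% r, logical(1))])
  }, integer(1))
  if (!identical(unname(rebuilt), unname(set_sizes)) ||
      sum(out$count) != nrow(tc)) {
    abort("transporter_overlap: inclusion-exclusion identity violated")
  }
  attr(out, "total") <- nrow(tc)
  attr(out, "none") <- out$count[out$region == "none"]
  attr(out, "set_sizes") <- set_sizes
  attr(out, "systems") <- systems
  class(out) <- c("mo_overlap", class(out))
  out
}

#' Count organisms in the intersection of transporter sets
#'
#' Sums the exact-region counts of an [transporter_overlap()] table over all
#' regions containing every system in `sets` (i.e. the plain intersection
#' cardinality, e.g. the MOT1-and-MOT2 overlap).
#'
#' @param overlap A `mo_overlap` table.
#' @param sets Systems whose joint carriers to count.
#' @return Integer count.
#' @export
overlap_count <- function(overlap, sets) {
  in_region <- vapply(strsplit(overlap$region, "&", fixed = TRUE),
                      function(r) all(sets %in% r), logical(1))
  sum(overlap$count[in_region])
}

#' Molybdoproteome sizes
#'
#' Per-organism counts of assigned molybdoprotein genes (families SO, XO,
#' DMSOR, AOR, MOSC; nitrogenase excluded unless requested), with per-kingdom
#' largest-proteome organisms (ties reported together).
#'
#' @param assignments Output of [assign_families()].
#' @param metadata Organism metadata.
#' @param include_nitrogenase Count nitrogenase genes too (default `FALSE`).
#' @param rich_threshold Strict threshold for the `rich` flag.
#' @return A `mo_proteomes` tibble (`organism_id`, `kingdom`, `taxon_path`,
#'   `n_molybdoproteins`, `rich`) with attribute `largest`, a tibble of the
#'   argmax organisms per kingdom.
#' @export
proteome_sizes <- function(assignments, metadata,
                           include_nitrogenase = FALSE,
                           rich_threshold = 20) {
  keep <- enzyme_families()
  if (include_nitrogenase) keep <- c(keep, "Nitrogenase")
  counts <- as_tibble(assignments) |>
    filter(.data$family_id %in% keep) |>
    count(.data$organism_id, name = "n_molybdoproteins")
  out <- metadata |>
    select("organism_id", "kingdom", "taxon_path") |>
    left_join(counts, by = "organism_id") |>
    mutate(n_molybdoproteins =
             as.integer(dplyr::coalesce(.data$n_molybdoproteins, 0L)),
           rich = is_rich(.data$n_molybdoproteins, rich_threshold))
  largest <- out |>
    group_by(.data$kingdom) |>
    filter(.data$n_molybdoproteins == max(.data$n_molybdoproteins)) |>
    ungroup()
  attr(out, "largest") <- largest
  class(out) <- c("mo_proteomes", class(out))
  out
}

#' Molybdoenzyme family occurrence among Mo-utilizing organisms
#'
#' For each kingdom and molybdoenzyme family (plus nitrogenase), the
#' percentage of that kingdom's Mo-utilizing organisms carrying at least one
#' member.
#'
#' @param trait_calls Output of [call_mo_utilization()].
#' @param decimals Decimal places for percentages.
#' @return A `mo_occurrence`-style tibble: `kingdom`, `family`, `n_total`
#'   (Mo-utilizing organisms of the kingdom), `n_positive`, `percent`.
#' @export
family_occurrence <- function(trait_calls, decimals = 1) {
  fams <- c(enzyme_families(), "nitrogenase")
  mo <- filter(as_tibble(trait_calls), .data$mo_utilizing)
  out <- purrr::map_dfr(fams, function(f) {
    col <- if (f == "nitrogenase") mo$nitrogenase else mo[[f]]
    mo |>
      mutate(.pos = col) |>
      group_by(.data$kingdom) |>
      summarise(n_total = dplyr::n(), n_positive = sum(.data$.pos),
                .groups = "drop") |>
      mutate(family = f)
  }) |>
    mutate(percent = percent_of(.data$n_positive, .data$n_total, decimals)) |>
    select("kingdom", "family", "n_total", "n_positive", "percent")
  class(out) <- c("mo_occurrence", class(out))
  out
}
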