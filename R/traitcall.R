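#' Build gene-presence profiles from ortholog assignments
#'
#' Counts assigned proteins per organism and canonical gene label. Pathway
#' genes, transporter subunits and nitrogenase are keyed by gene label
#' (`moaA`, `modA`, ..., `nif`); molybdoenzyme assignments are keyed by family
#' (`SO`, `XO`, `DMSOR`, `AOR`, `MOSC`). Every organism in `metadata` gets a
#' row (all-zero when it has no assignments), and all 24 canonical labels are
#' always present as columns.
#'
#' @param assignments Output of [assign_families()].
#' @param metadata Organism metadata (defines the organism universe).
#' @return A wide tibble: `organism_id` plus one integer count column per
#'   canonical gene label.
#' @export
build_profiles <- function(assignments, metadata) {
  labels <- profile_gene_labels()
  asn <- as_tibble(assignments)
  if (nrow(asn) > 0) {
    asn <- asn |>
      mutate(label = dplyr::case_when(
        .data$class == "enzyme" ~ .data$family_id,
        .data$class == "nitrogenase" ~ "nif",
        TRUE ~ .data$gene_label
      )) |>
      filter(.data$label %in% labels) |>
      count(.data$organism_id, .data$label)
  } else {
    asn <- tibble(organism_id = character(), label = character(),
                  n = integer())
  }
  grid <- tidyr::expand_grid(organism_id = metadata$organism_id,
                             label = labels)
  grid |>
    left_join(asn, by = c("organism_id", "label")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n") |>
    select("organism_id", all_of(labels))
}

#' Call the Moco biosynthetic pathway
#'
#' The pathway is present iff each of the three biosynthetic steps is
#' represented (step 1: moaA or moaC; step 2: moaD, moaE or moeB; step 3:
#' moeA or mogA) and at least `pathway_majority` of the 7 key genes are
#' present ("most of the key genes"; default a strict majority of 4).
#'
#' @param profiles Wide profile tibble from [build_profiles()] (or any data
#'   frame with the 7 key-gene count columns and `organism_id`).
#' @param pathway_majority Minimum number of present key genes.
#' @return A tibble with `organism_id`, per-step booleans `step1..step3`,
#'   `n_key_genes` and the `moco_pathway` verdict.
#' @examples
#' prof <- tibble::tibble(
#'   organism_id = "x", moaA = 1, moaC = 1, moaD = 1, moaE = 0,
#'   moeB = 1, moeA = 1, mogA = 1
#' )
#' call_moco_pathway(prof)
#' @export
call_moco_pathway <- function(profiles, pathway_majority = 4) {
  need <- pathway_genes()
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("profiles lack key-gene columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  steps <- pathway_steps()
  present <- as.matrix(profiles[, need]) > 0
  step_has <- function(genes) rowSums(present[, genes, drop = FALSE]) > 0
  tibble(
    organism_id = profiles$organism_id,
    step1 = step_has(steps$step1),
    step2 = step_has(steps$step2),
    step3 = step_has(steps$step3),
    n_key_genes = as.integer(rowSums(present))
  ) |>
    mutate(moco_pathway = .data$step1 & .data$step2 & .data$step3 &
             .data$n_key_genes >= pathway_majority)
}

#' Call transporter systems from subunit presence
#'
#' An ABC system (ModABC, WtpABC, TupABC) is present iff its substrate-binding
#' A subunit is present together with at least one of the B/C subunits; the
#' single-gene eukaryotic carriers MOT1/MOT2 are present iff their gene is.
#' Prokaryotic profiles never yield MOT calls and eukaryotic profiles never
#' yield ABC calls.
#'
#' @param profiles Wide profile tibble.
#' @param metadata Organism metadata (for the kingdom gate).
#' @return A tibble with `organism_id` and logical columns `ModABC`, `WtpABC`,
#'   `TupABC`, `MOT1`, `MOT2`.
#' @export
call_transporters <- function(profiles, metadata) {
  km <- stats::setNames(metadata$kingdom, metadata$organism_id)
  kingdom <- unname(km[profiles$organism_id])
  is_euk <- kingdom == "eukaryota"
  abc <- function(a, b, c_) {
    profiles[[a]] > 0 & (profiles[[b]] > 0 | profiles[[c_]] > 0)
  }
  tibble(
    organism_id = profiles$organism_id,
    ModABC = abc("modA", "modB", "modC") & !is_euk,
    WtpABC = abc("wtpA", "wtpB", "wtpC") & !is_euk,
    TupABC = abc("tupA", "tupB", "tupC") & !is_euk,
    MOT1 = profiles$mot1 > 0 & is_euk,
    MOT2 = profiles$mot2 > 0 & is_euk
  )
}

#' Call Mo-utilization traits per organism
#'
#' Combines the pathway verdict, molybdoenzyme presence (any of SO, XO,
#' DMSOR, AOR, MOSC), and nitrogenase into the per-organism trait call.
#' The Moco utilization trait requires the complete biosynthetic pathway
#' plus at least one Moco-dependent molybdoenzyme; an organism is
#' Mo-utilizing if it has that trait or nitrogenase. Categories partition
#' organisms into `both`, `moco_only`, `nif_only`, `none`. Orphan classes
#' mark partial traits (pathway without enzyme, enzyme without pathway).
#' The molybdoproteome size counts molybdoenzyme genes (nitrogenase excluded
#' by default); `rich` is strict: size > `rich_threshold`.
#'
#' @param profiles Wide profile tibble from [build_profiles()].
#' @param metadata Organism metadata.
#' @param config An [mo_config()].
#' @param include_nif_in_proteome Count nitrogenase genes in the
#'   molybdoproteome size (default `FALSE`).
#' @return A `mo_traitcalls` tibble with one row per organism: verdict
#'   booleans, `category`, `orphan_class`, per-family presence, transporter
#'   calls, `n_molybdoproteins`, `rich` and `mo_utilizing`.
#' @export
call_mo_utilization <- function(profiles, metadata, config = mo_config(),
                                include_nif_in_proteome = FALSE) {
  pw <- call_moco_pathway(profiles, config$pathway_majority)
  tr <- call_transporters(profiles, metadata)
  fam <- enzyme_families()
  fam_present <- as_tibble(stats::setNames(
    lapply(fam, function(f) profiles[[f]] > 0), fam))
  n_moly <- rowSums(as.matrix(profiles[, fam]))
  if (include_nif_in_proteome) n_moly <- n_moly + profiles$nif
  out <- tibble(
    organism_id = profiles$organism_id,
    moco_enzyme = rowSums(as.matrix(profiles[, fam]) > 0) > 0,
    nitrogenase = profiles$nif > 0,
    n_molybdoproteins = as.integer(n_moly)
  ) |>
    left_join(pw, by = "organism_id") |>
    dplyr::bind_cols(fam_present) |>
    left_join(tr, by = "organism_id") |>
    left_join(select(metadata, "organism_id", "kingdom"),
              by = "organism_id") |>
    mutate(
      moco_trait = .data$moco_pathway & .data$moco_enzyme,
      category = dplyr::case_when(
        .data$moco_trait & .data$nitrogenase ~ "both",
        .data$moco_trait ~ "moco_only",
        .data$nitrogenase ~ "nif_only",
        TRUE ~ "none"
      ),
      orphan_class = dplyr::case_when(
        .data$moco_pathway & !.data$moco_enzyme ~ "pathway_no_enzyme",
        !.data$moco_pathway & .data$moco_enzyme ~ "enzyme_no_pathway",
        TRUE ~ "none"
      ),
      rich = is_rich(.data$n_molybdoproteins, config$rich_threshold),
      mo_utilizing = .data$category != "none"
    ) |>
    select("organism_id", "kingdom", "step1", "step2", "step3",
           "n_key_genes", "moco_pathway", "moco_enzyme", "nitrogenase",
           "moco_trait", "category", "orphan_class", all_of(fam),
           "ModABC", "WtpABC", "TupABC", "MOT1", "MOT2",
           "n_molybdoproteins", "rich", "mo_utilizing")
  class(out) <- c("mo_traitcalls", class(out))
  out
}

#' Molybdoprotein-rich predicate
#'
#' Strictly more than `rich_threshold` molybdoprotein genes.
#'
#' @param proteome_size Non-negative gene count(s).
#' @param rich_threshold Threshold (default 20; 20 itself is not rich).
#' @return Logical vector.
#' @examples
#' is_rich(c(20, 21, 73)) # FALSE TRUE TRUE
#' @export
is_rich <- function(proteome_size, rich_threshold = 20) {
  proteome_size > rich_threshold
}

#' Cross-tabulate orphan Moco traits
#'
#' Organisms carrying only part of the Moco utilization trait — a complete
#' pathway without any molybdoenzyme, or molybdoenzymes without a complete
#' pathway — are counted per kingdom, crossed with nitrogenase status.
#' Organisms with both components or neither contribute to no cell.
#'
#' @param trait_calls Output of [call_mo_utilization()].
#' @return A tibble with one row per kingdom and the four cell counts
#'   `pathway_no_enzyme_nif_pos`, `pathway_no_enzyme_nif_neg`,
#'   `enzyme_no_pathway_nif_pos`, `enzyme_no_pathway_nif_neg`.
#' @export
classify_orphans <- function(trait_calls) {
  cells <- tidyr::expand_grid(
    orphan_class = c("pathway_no_enzyme", "enzyme_no_pathway"),
    nitrogenase = c(TRUE, FALSE)
  )
  kingdoms <- sort(unique(trait_calls$kingdom))
  grid <- tidyr::expand_grid(kingdom = kingdoms, cells)
  counts <- trait_calls |>
    filter(.data$orphan_class != "none") |>
    count(.data$kingdom, .data$orphan_class, .data$nitrogenase)
  grid |>
    left_join(counts, by = c("kingdom", "orphan_class", "nitrogenase")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           cell = paste0(.data$orphan_class,
                         ifelse(.data$nitrogenase, "_nif_pos", "_nif_neg"))) |>
    select("kingdom", "cell", "n") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "n") |>
    select("kingdom",
           "pathway_no_enzyme_nif_pos", "pathway_no_enzyme_nif_neg",
           "enzyme_no_pathway_nif_pos", "enzyme_no_pathway_nif_neg")
}

#' Predict tungstoproteins
#'
#' Flags possible tungsten-dependent proteins among molybdoenzyme
#' assignments using three rules: (i) all members of the AOR family;
#' (ii) FDH and ACH orthologs (DMSOR subfamilies) in strictly anaerobic
#' bacteria; (iii) FWD (formylmethanofuran dehydrogenase) orthologs in
#' methanogenic archaea. "Strictly anaerobic" means `oxygen_req ==
#' "anaerobic"`; methanogens are recognised by a taxon-path rank starting
#' with "Methano".
#'
#' @param assignments Output of [assign_families()].
#' @param metadata Organism metadata.
#' @return A tibble of molybdoenzyme assignments with `rule_fired`
#'   (`AOR`, `FDH_ACH_anaerobe`, `FWD_methanogen` or `none`) and
#'   `predicted_w`.
#' @export
predict_tungstoproteins <- function(assignments, metadata) {
  md <- metadata |>
    mutate(methanogen = vapply(
      strsplit(.data$taxon_path, ";", fixed = TRUE),
      function(p) any(grepl("^Methano", trimws(p))), logical(1))) |>
    select("organism_id", "kingdom", "oxygen_req", "methanogen")
  as_tibble(assignments) |>
    filter(.data$class == "enzyme") |>
    left_join(md, by = "organism_id") |>
    mutate(
      rule_fired = dplyr::case_when(
        .data$family_id == "AOR" ~ "AOR",
        .data$gene_label %in% c("FDH", "ACH") &
          .data$kingdom == "bacteria" &
          .data$oxygen_req == "anaerobic" ~ "FDH_ACH_anaerobe",
        .data$gene_label == "FWD" & .data$kingdom == "archaea" &
          .data$methanogen ~ "FWD_methanogen",
        TRUE ~ "none"
      ),
      predicted_w = .data$rule_fired != "none"
    ) |>
    select("organism_id", "protein_id", "family_id", "gene_label",
           "rule_fired", "predicted_w")
}
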