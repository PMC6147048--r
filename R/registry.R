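#' Curated seed-family registry
#'
#' The registry maps seed protein sequences to gene families for ortholog
#' assignment. Each row is one seed: `family_id` groups seeds into the unit a
#' protein is assigned to (a pathway gene such as `MoaA`, a transporter system
#' such as `ModABC`, or a molybdoenzyme family such as `DMSOR`); `gene_label`
#' is the per-gene (or subfamily) label used in presence profiles and
#' tungstoprotein rules; `role` is `"member"` or `"exclusion"`. Exclusion
#' seeds represent Mo-independent homologs whose best-hit capture disqualifies
#' a protein: NuoG (NADH-quinone oxidoreductase chain G, a DMSOR look-alike)
#' and NifE (nitrogenase cofactor biosynthesis protein, a nitrogenase
#' look-alike).
#'
#' Bifunctional eukaryotic seeds occupy one row per activity: plant Cnx1
#' carries both the moeA and mogA activities, so a protein whose best seed is
#' Cnx1 satisfies both labels.
#'
#' @return A tibble with columns `family_id`, `gene_label`, `seed_id`,
#'   `seed_length`, `role`, `class` (pathway / transporter / enzyme /
#'   nitrogenase) and `kingdom_scope` (prokaryote / eukaryote / both).
#' @examples
#' seed_registry()
#' @export
seed_registry <- function() {
  reg <- function(family, label, seed, len, role, class, scope) {
    tibble(family_id = family, gene_label = label, seed_id = seed,
           seed_length = as.integer(len), role = role, class = class,
           kingdom_scope = scope)
  }
  bind_rows(
    # Moco biosynthetic pathway, prokaryotic seeds (E. coli moa-mog loci)
    reg("MoaA", "moaA", "MOAA_ECOLI", 329, "member", "pathway", "prokaryote"),
    reg("MoaC", "moaC", "MOAC_ECOLI", 161, "member", "pathway", "prokaryote"),
    reg("MoaD", "moaD", "MOAD_ECOLI", 81, "member", "pathway", "prokaryote"),
    reg("MoaE", "moaE", "MOAE_ECOLI", 150, "member", "pathway", "prokaryote"),
    reg("MoeB", "moeB", "MOEB_ECOLI", 249, "member", "pathway", "prokaryote"),
    reg("MoeA", "moeA", "MOEA_ECOLI", 411, "member", "pathway", "prokaryote"),
    reg("MogA", "mogA", "MOGA_ECOLI", 195, "member", "pathway", "prokaryote"),
    # eukaryotic Cnx seeds mapped onto the same 7 canonical labels
    reg("MoaA", "moaA", "CNX2_ARATH", 303, "member", "pathway", "eukaryote"),
    reg("MoaC", "moaC", "CNX3_ARATH", 231, "member", "pathway", "eukaryote"),
    reg("MoaD", "moaD", "CNX7_ARATH", 111, "member", "pathway", "eukaryote"),
    reg("MoaE", "moaE", "CNX6_ARATH", 195, "member", "pathway", "eukaryote"),
    reg("MoeB", "moeB", "CNX5_ARATH", 459, "member", "pathway", "eukaryote"),
    reg("MoeA", "moeA", "CNX1_ARATH", 670, "member", "pathway", "eukaryote"),
    reg("MogA", "mogA", "CNX1_ARATH", 670, "member", "pathway", "eukaryote"),
    # ABC transport systems (prokaryotes)
    reg("ModABC", "modA", "MODA_ECOLI", 257, "member", "transporter", "prokaryote"),
    reg("ModABC", "modB", "MODB_ECOLI", 229, "member", "transporter", "prokaryote"),
    reg("ModABC", "modC", "MODC_ECOLI", 352, "member", "transporter", "prokaryote"),
    reg("WtpABC", "wtpA", "WTPA_PYRFU", 273, "member", "transporter", "prokaryote"),
    reg("WtpABC", "wtpB", "WTPB_PYRFU", 283, "member", "transporter", "prokaryote"),
    reg("WtpABC", "wtpC", "WTPC_PYRFU", 335, "member", "transporter", "prokaryote"),
    reg("TupABC", "tupA", "TUPA_EUBAC", 276, "member", "transporter", "prokaryote"),
    reg("TupABC", "tupB", "TUPB_EUBAC", 232, "member", "transporter", "prokaryote"),
    reg("TupABC", "tupC", "TUPC_EUBAC", 261, "member", "transporter", "prokaryote"),
    # eukaryotic carriers
    reg("MOT1", "mot1", "MOT1_ARATH", 456, "member", "transporter", "eukaryote"),
    reg("MOT2", "mot2", "MOT2_CHLRE", 472, "member", "transporter", "eukaryote"),
    # molybdoenzyme families; gene_label carries the subfamily
    reg("SO", "SO", "SUOX_HUMAN", 545, "member", "enzyme", "both"),
    reg("SO", "NAS", "NIA1_ARATH", 917, "member", "enzyme", "both"),
    reg("XO", "XDH", "XDH_HUMAN", 1333, "member", "enzyme", "both"),
    reg("XO", "AO", "AOXA_HUMAN", 1338, "member", "enzyme", "both"),
    reg("DMSOR", "FDH", "FDHF_ECOLI", 715, "member", "enzyme", "prokaryote"),
    reg("DMSOR", "ACH", "ACHY_PELAE", 730, "member", "enzyme", "prokaryote"),
    reg("DMSOR", "NAR", "NARG_ECOLI", 1247, "member", "enzyme", "prokaryote"),
    reg("DMSOR", "DMS", "DMSA_ECOLI", 814, "member", "enzyme", "prokaryote"),
    reg("DMSOR", "FWD", "FWDB_METTH", 437, "member", "enzyme", "prokaryote"),
    reg("AOR", "AOR", "AOR_PYRFU", 605, "member", "enzyme", "prokaryote"),
    reg("MOSC", "MOSC", "YCBX_ECOLI", 369, "member", "enzyme", "prokaryote"),
    reg("MOSC", "MARC", "MARC1_HUMAN", 337, "member", "enzyme", "eukaryote"),
    reg("Nitrogenase", "nif", "NIFD_AZOVI", 492, "member", "nitrogenase", "prokaryote"),
    # Mo-independent look-alikes: capture and discard
    reg("DMSOR", "NuoG", "NUOG_ECOLI", 908, "exclusion", "enzyme", "prokaryote"),
    reg("Nitrogenase", "NifE", "NIFE_AZOVI", 478, "exclusion", "nitrogenase", "prokaryote")
  )
}

enzyme_families <- function() c("SO", "XO", "DMSOR", "AOR", "MOSC")
transporter_systems <- function() c("ModABC", "WtpABC", "TupABC", "MOT1", "MOT2")
pathway_genes <- function() {
  c("moaA", "moaC", "moaD", "moaE", "moeB", "moeA", "mogA")
}
pathway_steps <- function() {
  list(step1 = c("moaA", "moaC"),
       step2 = c("moaD", "moaE", "moeB"),
       step3 = c("moeA", "mogA"))
}

# labels a gene-presence profile always carries
profile_gene_labels <- function() {
  c(pathway_genes(),
    "modA", "modB", "modC", "wtpA", "wtpB", "wtpC", "tupA", "tupB", "tupC",
    "mot1", "mot2",
    enzyme_families(), "nif")
}

#' Catalytic-domain registry for molybdoenzyme families
#'
#' Maps each molybdoenzyme family to the Pfam accession of its
#' molybdopterin-binding (catalytic) domain; used to anchor fusion detection.
#'
#' @return A tibble with columns `family_id` and `domain_id`.
#' @export
catalytic_domains <- function() {
  tibble(
    family_id = c("SO", "XO", "DMSOR", "AOR", "MOSC"),
    domain_id = c("pfam00174", "pfam02738", "pfam00384", "pfam01314",
                  "pfam03473")
  )
}

#' Annotated fusion-partner domains
#'
#' Domains observed fused to molybdoproteins, split into partners with a known
#' functional link (e.g. the XDH FAD-binding subunit, nitrate reductase delta
#' subunit, cysteine desulfurase) and novel partners with no previously
#' reported Moco connection (cbb3-type cytochrome c oxidase subunit III,
#' high-molecular-weight glutenin, a retinal protein of unknown function, and
#' six single-family partners).
#'
#' @return A tibble with columns `domain_id`, `description`, `known`.
#' @export
fusion_partner_annotations <- function() {
  tibble(
    domain_id = c("pfam00941", "pfam02613", "pfam00266",
                  "pfam13442", "pfam03157", "pfam15449",
                  "COG0493", "COG4117", "COG1357", "COG0518",
                  "pfam05887", "COG2197"),
    description = c(
      "XDH FAD-binding subunit", "Nitrate reductase delta subunit",
      "Cysteine desulfurase",
      "Cytochrome C oxidase, cbb3-type, subunit III",
      "High molecular weight glutenin subunit",
      "Retinal protein (unknown function)",
      "NADPH-dependent glutamate synthase beta chain",
      "Thiosulfate reductase cytochrome b subunit",
      "Uncharacterized protein YjbI",
      "GMP synthase, glutamine amidotransferase domain",
      "Procyclic acidic repetitive protein (PARP)",
      "DNA-binding response regulator, NarL/FixJ family"),
    known = c(TRUE, TRUE, TRUE, rep(FALSE, 9))
  )
}
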