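amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

random_protein <- function(len) {
  paste(sample(amino_acids(), len, replace = TRUE), collapse = "")
}

# per-site substitution: each position mutates to a different residue with
# probability p; no indels, so alignments stay trivial and p-distances exact
mutate_sequence <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    aa <- amino_acids()
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(aa, ch), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a horizontal-transfer alignment scenario
#'
#' Simulates aligned protein sequences for the five key Moco biosynthesis
#' genes plus two molybdoproteins across two bacterial clades, with one
#' recipient taxon in the second clade whose sequences are drawn from the
#' donor clade's distribution for every gene (when `hgt = TRUE`) — the
#' signature of a recent transfer of the whole Mo utilization trait.
#' Sequences evolve by per-site substitution from clade ancestors; there are
#' no indels, so the emitted blocks are already aligned.
#'
#' @param n_taxa_per_clade Taxa per clade, at least 3.
#' @param genes Gene labels to simulate.
#' @param seq_length Alignment length in residues.
#' @param within_divergence Per-site substitution probability from clade
#'   ancestor to each taxon.
#' @param between_divergence Per-site substitution probability separating the
#'   two clade ancestors. Values yielding saturated distances (> 0.75) draw a
#'   warning, not an error.
#' @param hgt Transfer on/off.
#' @param donor_class,recipient_class Taxonomic class labels of the two
#'   clades.
#' @param seed Integer seed.
#' @return A list of class `mo_hgt_scenario`: `alignments` (named list of
#'   aligned blocks), `taxonomy` (tibble `taxon_id`, `class`), `focal` (the
#'   recipient taxon id) and `truth` (`hgt`, `n_genes`).
#' @export
generate_hgt_scenario <- function(n_taxa_per_clade = 4,
                                  genes = c("moaA", "moaC", "moeA", "moeB",
                                            "mogA", "MOSC", "AOR"),
                                  seq_length = 150,
                                  within_divergence = 0.05,
                                  between_divergence = 0.45,
                                  hgt = TRUE,
                                  donor_class = "Clostridia",
                                  recipient_class = "Erysipelotrichia",
                                  seed = 1L) {
  if (n_taxa_per_clade < 3) abort("need at least 3 taxa per clade")
  if (between_divergence > 0.75) {
    warn("between-clade divergence > 0.75: distances may be saturated")
  }
  set.seed(seed)
  donor_ids <- sprintf("CLO_%02d", seq_len(n_taxa_per_clade))
  resident_ids <- sprintf("ERY_%02d", seq_len(n_taxa_per_clade))
  focal <- "ERY_recipient"
  taxonomy <- tibble(
    taxon_id = c(donor_ids, resident_ids, focal),
    class = c(rep(donor_class, n_taxa_per_clade),
              rep(recipient_class, n_taxa_per_clade + 1))
  )
  alignments <- lapply(stats::setNames(genes, genes), function(g) {
    donor_anc <- random_protein(seq_length)
    resident_anc <- mutate_sequence(donor_anc, between_divergence)
    seqs <- c(
      vapply(donor_ids, function(i) {
        mutate_sequence(donor_anc, within_divergence)
      }, character(1)),
      vapply(resident_ids, function(i) {
        mutate_sequence(resident_anc, within_divergence)
      }, character(1))
    )
    seqs[focal] <- mutate_sequence(
      if (hgt) donor_anc else resident_anc, within_divergence)
    seqs
  })
  structure(
    list(alignments = alignments, taxonomy = taxonomy, focal = focal,
         truth = list(hgt = hgt, n_genes = length(genes))),
    class = "mo_hgt_scenario"
  )
}
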