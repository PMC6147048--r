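# in-code fixture builders shared across test files

make_hit <- function(query_id = "MOAA_ECOLI", subject_id = "org|p001",
                     pident = 50, aln_length = 200, mismatches = 100,
                     gap_opens = 1, qstart = 1, qend = 200, sstart = 1,
                     send = 600, evalue = 1e-20, bitscore = 150) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 pident = pident, aln_length = aln_length,
                 mismatches = mismatches, gap_opens = gap_opens,
                 qstart = qstart, qend = qend, sstart = sstart, send = send,
                 evalue = evalue, bitscore = bitscore)
}

# random hit table over a fixed query-length map
random_hits <- function(n, queries = paste0("q", 1:5), qlen = 300,
                        subjects = paste0("s", 1:8)) {
  tibble::tibble(
    query_id = sample(queries, n, replace = TRUE),
    subject_id = sample(subjects, n, replace = TRUE),
    pident = runif(n, 20, 95),
    aln_length = sample(30:300, n, replace = TRUE),
    mismatches = 0L, gap_opens = 0L,
    qstart = sample(1:100, n, replace = TRUE),
    sstart = 1L, send = 1L,
    evalue = 10^runif(n, -40, 1),
    bitscore = round(runif(n, 20, 300), 1)
  ) |>
    dplyr::mutate(qend = pmin(.data$qstart + .data$aln_length - 1L, qlen))
}

make_metadata <- function(organism_id, kingdom = "bacteria",
                          taxon_path = "Proteobacteria;Gammaproteobacteria",
                          habitat = "aquatic", oxygen_req = "aerobic") {
  tibble::tibble(organism_id = organism_id, kingdom = kingdom,
                 taxon_path = taxon_path, habitat = habitat,
                 oxygen_req = oxygen_req)
}

# wide all-zero profile for given organisms, with chosen labels set
make_profile <- function(organism_id, present = character(), counts = NULL) {
  labels <- molytrait:::profile_gene_labels()
  prof <- tibble::as_tibble(
    c(list(organism_id = organism_id),
      stats::setNames(rep(list(rep(0L, length(organism_id))), length(labels)),
                      labels)))
  if (is.null(counts)) counts <- rep(1L, length(present))
  for (i in seq_along(present)) prof[[present[i]]] <- counts[i]
  prof
}

# independent boolean oracle for the pathway rule, written from the verbal
# definition (not via the package's step tables)
oracle_pathway <- function(present, majority = 4) {
  s1 <- "moaA" %in% present || "moaC" %in% present
  s2 <- any(c("moaD", "moaE", "moeB") %in% present)
  s3 <- "moeA" %in% present || "mogA" %in% present
  s1 && s2 && s3 && length(intersect(
    present, c("moaA", "moaC", "moaD", "moaE", "moeB", "moeA", "mogA"))) >= majority
}

oracle_category <- function(pathway, enzyme, nif) {
  trait <- pathway && enzyme
  if (trait && nif) "both"
  else if (trait) "moco_only"
  else if (nif) "nif_only"
  else "none"
}

# exact binomial 99% acceptance interval for an observed count
binom99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p))
}

# transporter columns of a trait-call row collapsed to a sorted string
transporter_string <- function(trait_calls) {
  systems <- c("ModABC", "MOT1", "MOT2", "TupABC", "WtpABC")
  apply(as.matrix(trait_calls[, systems]), 1, function(r) {
    paste(sort(systems[r]), collapse = ",")
  })
}
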