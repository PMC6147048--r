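test_that("pathway calls follow the three-step-plus-majority rule", {
  # 6 of 7 genes, every step covered
  p6 <- make_profile("a", c("moaA", "moaC", "moaD", "moeB", "moeA", "mogA"))
  expect_true(call_moco_pathway(p6)$moco_pathway)
  # all steps covered but only 3 genes: majority (>= 4) fails
  p3 <- make_profile("a", c("moaA", "moaD", "moeA"))
  v3 <- call_moco_pathway(p3)
  expect_true(v3$step1 && v3$step2 && v3$step3)
  expect_false(v3$moco_pathway)
  # majority is configurable
  expect_true(call_moco_pathway(p3, pathway_majority = 3)$moco_pathway)
})

test_that("all 2^7 key-gene profiles match the exhaustive boolean oracle", {
  genes <- c("moaA", "moaC", "moaD", "moaE", "moeB", "moeA", "mogA")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(combos) <- genes
  prof <- make_profile(sprintf("g%03d", seq_len(nrow(combos))))
  for (g in genes) prof[[g]] <- as.integer(combos[[g]])
  got <- call_moco_pathway(prof)$moco_pathway
  want <- apply(combos, 1, function(row) oracle_pathway(genes[as.logical(row)]))
  expect_equal(got, unname(want))
})

test_that("utilization categories match the oracle on random full profiles", {
  set.seed(21)
  n <- 500
  labels <- molytrait:::profile_gene_labels()
  prof <- make_profile(sprintf("r%03d", 1:n))
  for (l in labels) prof[[l]] <- rbinom(n, 2, 0.3)
  md <- make_metadata(prof$organism_id)
  tc <- call_mo_utilization(prof, md)
  want <- vapply(seq_len(n), function(i) {
    present <- labels[as.numeric(prof[i, labels]) > 0]
    oracle_category(
      oracle_pathway(present),
      any(c("SO", "XO", "DMSOR", "AOR", "MOSC") %in% present),
      "nif" %in% present)
  }, character(1))
  expect_equal(tc$category, want)
  # the four categories partition the organisms
  expect_true(all(tc$category %in% c("both", "moco_only", "nif_only", "none")))
  expect_equal(sum(tc$category != "none"), sum(tc$mo_utilizing))

  # pathway + enzyme without nif is moco_only (worked example)
  p <- make_profile("w", c("moaA", "moaC", "moaD", "moeB", "moeA", "DMSOR"),
                    counts = c(1, 1, 1, 1, 1, 2))
  expect_equal(call_mo_utilization(p, make_metadata("w"))$category,
               "moco_only")
  # nitrogenase alone is nif_only
  p2 <- make_profile("x", "nif")
  expect_equal(call_mo_utilization(p2, make_metadata("x"))$category,
               "nif_only")
})

test_that("adding a gene never flips a positive verdict (monotonicity)", {
  set.seed(8)
  labels <- molytrait:::profile_gene_labels()
  for (rep in 1:25) {
    base_present <- sample(labels, sample(3:10, 1))
    prof <- make_profile("m", base_present)
    md <- make_metadata("m")
    before <- call_mo_utilization(prof, md)
    extra <- sample(setdiff(labels, base_present), 1)
    prof2 <- prof
    prof2[[extra]] <- 1L
    after <- call_mo_utilization(prof2, md)
    expect_true(after$moco_pathway >= before$moco_pathway)
    expect_true(after$moco_enzyme >= before$moco_enzyme)
    expect_true(after$mo_utilizing >= before$mo_utilizing)
  }
})

test_that("transporter calls enumerate the subunit rule and kingdom gates", {
  subunits <- c("modA", "modB", "modC")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  prof <- make_profile(sprintf("t%02d", seq_len(nrow(combos))))
  for (i in 1:3) prof[[subunits[i]]] <- as.integer(combos[[i]])
  md <- make_metadata(prof$organism_id)
  got <- call_transporters(prof, md)$ModABC
  want <- combos[[1]] & (combos[[2]] | combos[[3]])
  expect_equal(got, want)

  # {modA, modB} present; {modB, modC} absent (A subunit is required)
  expect_true(call_transporters(make_profile("y", c("modA", "modB")),
                                make_metadata("y"))$ModABC)
  expect_false(call_transporters(make_profile("y", c("modB", "modC")),
                                 make_metadata("y"))$ModABC)

  # a eukaryote with mot2 gets MOT2; a prokaryote with mot2 does not
  pm <- make_profile("e", "mot2")
  expect_true(call_transporters(pm, make_metadata("e", kingdom = "eukaryota"))$MOT2)
  expect_false(call_transporters(pm, make_metadata("e"))$MOT2)
  # and a eukaryote never gets an ABC call
  pa <- make_profile("e", c("modA", "modB"))
  expect_false(call_transporters(pa, make_metadata("e", kingdom = "eukaryota"))$ModABC)
})

test_that("orphan cross-tabulation fills the four cells and excludes full traits", {
  prof <- dplyr::bind_rows(
    make_profile("full", c("moaA", "moaC", "moaD", "moeB", "moeA", "SO")),
    make_profile("pne_nif", c("moaA", "moaC", "moaD", "moeB", "moeA", "nif")),
    make_profile("enp", "DMSOR"),
    make_profile("empty"))
  md <- make_metadata(prof$organism_id)
  tc <- call_mo_utilization(prof, md)
  orp <- classify_orphans(tc)
  expect_equal(orp$pathway_no_enzyme_nif_pos, 1)
  expect_equal(orp$pathway_no_enzyme_nif_neg, 0)
  expect_equal(orp$enzyme_no_pathway_nif_neg, 1)
  expect_equal(orp$enzyme_no_pathway_nif_pos, 0)
  # organisms with both components or neither contribute nowhere
  expect_equal(sum(as.matrix(orp[, -1])), 2)
})

test_that("the rich flag is a strict greater-than", {
  expect_true(is_rich(73))
  expect_false(is_rich(20))
  expect_true(is_rich(21))
})

test_that("tungstoprotein rules fire exactly as stated", {
  asn <- tibble::tibble(
    organism_id = c("anaer_bac", "aer_bac", "methano", "nonmeth", "any"),
    protein_id = paste0(organism_id, "|p1"),
    family_id = c("DMSOR", "DMSOR", "DMSOR", "DMSOR", "AOR"),
    gene_label = c("FDH", "FDH", "FWD", "FWD", "AOR"),
    class = "enzyme", seed_id = "x", bitscore = 100, evalue = 1e-20)
  md <- dplyr::bind_rows(
    make_metadata("anaer_bac", oxygen_req = "anaerobic"),
    make_metadata("aer_bac", oxygen_req = "aerobic"),
    make_metadata("methano", kingdom = "archaea",
                  taxon_path = "Euryarchaeota;Methanomicrobia"),
    make_metadata("nonmeth", kingdom = "archaea",
                  taxon_path = "Crenarchaeota;Thermoprotei"),
    make_metadata("any", oxygen_req = "aerobic"))
  got <- predict_tungstoproteins(asn, md)
  rules <- stats::setNames(got$rule_fired, got$organism_id)
  expect_equal(unname(rules["any"]), "AOR")             # rule (i)
  expect_equal(unname(rules["anaer_bac"]), "FDH_ACH_anaerobe") # rule (ii)
  expect_equal(unname(rules["aer_bac"]), "none")        # aerobe: no fire
  expect_equal(unname(rules["methano"]), "FWD_methanogen")     # rule (iii)
  expect_equal(unname(rules["nonmeth"]), "none")
  expect_equal(got$predicted_w, got$rule_fired != "none")
})
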