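test_that("occurrence percentages reproduce printed-table arithmetic", {
  flags <- tibble::tibble(
    kingdom = rep(c("archaea", "bacteria"), c(256, 3683)),
    pos = c(rep(c(TRUE, FALSE), c(249, 7)), rep(c(TRUE, FALSE), c(3269, 414))))
  got <- occurrence_summary(flags, kingdom, pos)
  expect_equal(got$percent[got$group == "archaea"], 97.3)
  expect_equal(got$percent[got$group == "bacteria"], 88.8)
  # all-negative group
  zero <- occurrence_summary(tibble::tibble(g = rep("x", 10), f = FALSE), g, f)
  expect_equal(zero$percent, 0)
  # empty group flagged as NA, never divided
  empty <- occurrence_summary(
    tibble::tibble(g = factor(character(), levels = "x"), f = logical()),
    g, f, decimals = 1)
  expect_equal(nrow(empty), 0)
})

test_that("rounding is half-up at the configured decimals", {
  expect_equal(round_half_up(97.25, 1), 97.3)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(percent_of(1, 3, 2), 33.33)
  expect_equal(percent_of(0, 0), NA_real_)
})

test_that("transporter overlap recovers the eukaryote MOT overlap from margins", {
  # membership layout consistent with the published margins:
  # |MOT1| = 57, |MOT2| = 135, 29 organisms with neither, 176 in total
  total <- 176; m1 <- 57; m2 <- 135; none <- 29
  both <- m1 + m2 - (total - none)
  tc <- tibble::tibble(
    organism_id = sprintf("e%03d", 1:total),
    kingdom = "eukaryota", mo_utilizing = TRUE,
    MOT1 = rep(c(TRUE, TRUE, FALSE, FALSE), c(both, m1 - both, m2 - both,
                                              total - m1 - m2 + both)),
    MOT2 = rep(c(TRUE, FALSE, TRUE, FALSE), c(both, m1 - both, m2 - both,
                                              total - m1 - m2 + both)))
  ov <- transporter_overlap(tc, kingdom = "eukaryota")
  expect_equal(overlap_count(ov, c("MOT1", "MOT2")), 45)
  expect_equal(attr(ov, "none"), 29)
  expect_equal(unname(attr(ov, "set_sizes")), c(57, 135))

  # disjoint sets: overlap 0
  dj <- tibble::tibble(organism_id = c("a", "b"), kingdom = "bacteria",
                       mo_utilizing = TRUE,
                       ModABC = c(TRUE, FALSE), WtpABC = c(FALSE, TRUE),
                       TupABC = FALSE)
  expect_equal(overlap_count(transporter_overlap(dj, "bacteria"),
                             c("ModABC", "WtpABC")), 0)
})

test_that("3-set region counts equal brute-force enumeration", {
  set.seed(9)
  n <- 100
  tc <- tibble::tibble(
    organism_id = sprintf("o%03d", 1:n), kingdom = "bacteria",
    mo_utilizing = TRUE,
    ModABC = runif(n) < 0.6, WtpABC = runif(n) < 0.3, TupABC = runif(n) < 0.4)
  ov <- transporter_overlap(tc, "bacteria")
  m <- as.matrix(tc[, c("ModABC", "WtpABC", "TupABC")])
  for (i in seq_len(nrow(ov))) {
    sets <- strsplit(ov$region[i], "&", fixed = TRUE)[[1]]
    if (ov$region[i] == "none") {
      want <- sum(rowSums(m) == 0)
    } else {
      inn <- m[, sets, drop = FALSE]
      out <- m[, setdiff(colnames(m), sets), drop = FALSE]
      want <- sum(rowSums(inn) == length(sets) & rowSums(out) == 0)
    }
    expect_equal(ov$count[i], want)
  }
  # inclusion-exclusion (k = 2): |A| + |B| - |A&B| + neither_of_AB = total
  expect_equal(sum(tc$ModABC) + sum(tc$WtpABC) -
                 overlap_count(ov, c("ModABC", "WtpABC")) +
                 sum(!tc$ModABC & !tc$WtpABC), n)
})

test_that("proteome sizes count molybdoprotein genes and find the argmax", {
  # 69 DMSOR members plus 4 other molybdoproteins: 73 genes
  asn <- tibble::tibble(
    organism_id = "gp",
    protein_id = sprintf("gp|p%03d", 1:74),
    family_id = c(rep("DMSOR", 69), "SO", "XO", "MOSC", "AOR", "Nitrogenase"),
    gene_label = "x", class = c(rep("enzyme", 73), "nitrogenase"),
    seed_id = "s", bitscore = 100, evalue = 1e-30)
  md <- dplyr::bind_rows(
    make_metadata("gp", taxon_path = "Actinobacteria;Coriobacteriia"),
    make_metadata("zero"))
  ps <- proteome_sizes(asn, md)
  expect_equal(ps$n_molybdoproteins[ps$organism_id == "gp"], 73)
  expect_true(ps$rich[ps$organism_id == "gp"])
  # nitrogenase excluded by default, included on request
  psn <- proteome_sizes(asn, md, include_nitrogenase = TRUE)
  expect_equal(psn$n_molybdoproteins[psn$organism_id == "gp"], 74)
  # organisms without assignments count zero
  expect_equal(ps$n_molybdoproteins[ps$organism_id == "zero"], 0)
  expect_equal(attr(ps, "largest")$organism_id, "gp")
})

test_that("family occurrence uses Mo-utilizing denominators", {
  comm <- generate_community(scenario_config(
    n_organisms = c(bacteria = 120), rng_seed = 17))
  b <- run_pipeline(comm)
  fo <- b$families
  occ <- b$occurrence
  expect_equal(unique(fo$n_total[fo$kingdom == "bacteria"]),
               occ$n_positive[occ$group == "bacteria"])
  # a kingdom where every Mo utilizer has DMSOR reports 100.0
  tc <- b$trait_calls
  tc$DMSOR[tc$mo_utilizing] <- TRUE
  fo2 <- family_occurrence(tc)
  expect_equal(fo2$percent[fo2$family == "DMSOR"], 100)
})

test_that("planted family inclusion probabilities are recovered at n = 1000", {
  probs <- c(SO = 0.9, XO = 0.7, DMSOR = 0.4, AOR = 0, MOSC = 0)
  sc <- scenario_config(
    n_organisms = c(bacteria = 1000),
    trait_category_weights = list(
      bacteria = c(both = 0, moco_only = 1, nif_only = 0, none = 0)),
    family_weights = list(bacteria = probs),
    fusion_rate = 0, rng_seed = 23)
  b <- run_pipeline(generate_community(sc))
  fo <- b$families
  for (f in c("XO", "DMSOR")) {
    ci <- binom99(1000, probs[[f]])
    expect_gte(fo$n_positive[fo$family == f], ci[1])
    expect_lte(fo$n_positive[fo$family == f], ci[2])
  }
  # SO also absorbs the at-least-one-family repair (P = 1.8%); allow it
  ci_so <- binom99(1000, probs[["SO"]] + 0.1 * 0.3 * 0.6)
  expect_gte(fo$n_positive[fo$family == "SO"], binom99(1000, 0.9)[1])
  expect_lte(fo$n_positive[fo$family == "SO"], ci_so[2])
})
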