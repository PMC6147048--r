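test_that("p-distance counts differing non-gap sites", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  # pairwise deletion of gap columns
  expect_equal(p_distance("AC-T", "ACGA"), 1 / 3)
  expect_error(p_distance("ACG", "ACGT"), "unequal")
  expect_warning(p_distance("--", "AA"), "no comparable")

  # random pairs vs a site-by-site counting oracle
  set.seed(5)
  aa <- c("A", "C", "D", "E", "-")
  for (i in 1:20) {
    a <- sample(aa, 60, replace = TRUE)
    b <- sample(aa, 60, replace = TRUE)
    cmp <- a != "-" & b != "-"
    want <- if (sum(cmp) == 0) 0 else sum(a[cmp] != b[cmp]) / sum(cmp)
    expect_equal(p_distance(paste(a, collapse = ""), paste(b, collapse = "")),
                 want)
    # symmetry
    expect_equal(p_distance(paste(a, collapse = ""), paste(b, collapse = "")),
                 p_distance(paste(b, collapse = ""), paste(a, collapse = "")))
  }
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
})

test_that("NJ recovers random additive trees exactly (topology and lengths)", {
  set.seed(14)
  for (ntaxa in c(5, 6, 7, 8)) {
    for (rep in 1:3) {
      true_tree <- ape::rtree(ntaxa)
      d <- ape::cophenetic.phylo(true_tree)
      got <- neighbor_joining(d)
      expect_equal(ape::dist.topo(ape::unroot(true_tree), got), 0,
                   ignore_attr = TRUE)
      back <- ape::cophenetic.phylo(got)[rownames(d), colnames(d)]
      expect_equal(back, d, tolerance = 1e-7)
      # independent implementation agrees on the topology
      ref <- ape::nj(d)
      expect_equal(ape::dist.topo(got, ref), 0, ignore_attr = TRUE)
    }
  }
})

test_that("NJ separates the two clades of the HGT generator", {
  sc <- generate_hgt_scenario(hgt = FALSE, seed = 2)
  tr <- gene_tree(sc$alignments$moaA)
  donor <- sc$taxonomy$taxon_id[sc$taxonomy$class == "Clostridia"]
  # the donor clade forms a bipartition: pruning it leaves a connected rest
  splits <- ape::prop.part(tr)
  labels <- attr(splits, "labels")
  has_donor_split <- any(vapply(splits, function(s) {
    setequal(labels[s], donor) || setequal(setdiff(labels, labels[s]), donor)
  }, logical(1)))
  expect_true(has_donor_split)
})

test_that("sister clades are read off the midpoint-rooted tree", {
  tax <- tibble::tibble(
    taxon_id = c("d1", "d2", "d3", "r1", "r2", "focal"),
    class = c("Donor", "Donor", "Donor", "Resident", "Resident", "Resident"))
  # focal nested inside the foreign (donor) clade
  tr <- ape::read.tree(
    text = "(((focal:0.02,d1:0.02):0.02,(d2:0.02,d3:0.02):0.02):0.3,(r1:0.05,r2:0.05):0.3);")
  expect_equal(sister_clade(tr, "focal", tax), "Donor")
  # focal sister to its own clade
  tr2 <- ape::read.tree(
    text = "(((focal:0.02,r1:0.02):0.02,r2:0.04):0.3,(d1:0.05,(d2:0.05,d3:0.05):0.02):0.3);")
  expect_equal(sister_clade(tr2, "focal", tax), "Resident")
  # 1/1 split sister group is ambiguous
  tr3 <- ape::read.tree(
    text = "((focal:0.1,(d1:0.1,r1:0.1):0.05):0.3,(d2:0.2,(d3:0.2,r2:0.2):0.1):0.3);")
  expect_equal(sister_clade(tr3, "focal", tax), "ambiguous")
  expect_error(sister_clade(tr, "absent", tax), "not in tree")
})

test_that("HGT scoring flags concordant foreign placement across gene trees", {
  sc <- generate_hgt_scenario(seed = 4)
  trees <- lapply(sc$alignments, gene_tree)
  rep <- hgt_score(trees, sc$taxonomy, sc$focal, hgt_min_trees = 3)
  expect_equal(rep$n_supporting, 7)
  expect_true(rep$flagged)
  expect_equal(rep$per_gene$sister_class,
               rep("Clostridia", 7))

  # no transfer: zero support
  sc0 <- generate_hgt_scenario(seed = 4, hgt = FALSE)
  rep0 <- hgt_score(lapply(sc0$alignments, gene_tree), sc0$taxonomy,
                    sc0$focal, hgt_min_trees = 3)
  expect_equal(rep0$n_supporting, 0)
  expect_false(rep0$flagged)

  # 2 supporting genes with a threshold of 3: not flagged; monotone in the
  # threshold; single-gene transfer flagged only when the threshold allows
  two <- hgt_score(trees[1:2], sc$taxonomy, sc$focal, hgt_min_trees = 3)
  expect_equal(two$n_supporting, 2)
  expect_false(two$flagged)
  one <- hgt_score(trees[1], sc$taxonomy, sc$focal, hgt_min_trees = 1)
  expect_true(one$flagged)
  flags <- vapply(1:8, function(k) {
    hgt_score(trees, sc$taxonomy, sc$focal, hgt_min_trees = k)$flagged
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("the HGT generator places the recipient by p-distance as declared", {
  sc <- generate_hgt_scenario(seed = 6)
  donors <- sc$taxonomy$taxon_id[sc$taxonomy$class == "Clostridia"]
  own <- setdiff(sc$taxonomy$taxon_id[sc$taxonomy$class == "Erysipelotrichia"],
                 sc$focal)
  for (g in names(sc$alignments)) {
    aln <- sc$alignments[[g]]
    d_donor <- vapply(donors, function(t) p_distance(aln[[sc$focal]], aln[[t]]),
                      numeric(1))
    d_own <- vapply(own, function(t) p_distance(aln[[sc$focal]], aln[[t]]),
                    numeric(1))
    expect_true(max(d_donor) < min(d_own))
  }
  # transfer off: nearest neighbour is within the declared clade
  sc0 <- generate_hgt_scenario(seed = 6, hgt = FALSE)
  for (g in names(sc0$alignments)) {
    aln <- sc0$alignments[[g]]
    d_all <- vapply(setdiff(names(aln), sc0$focal),
                    function(t) p_distance(aln[[sc0$focal]], aln[[t]]),
                    numeric(1))
    expect_true(names(which.min(d_all)) %in% own)
  }
  expect_warning(generate_hgt_scenario(between_divergence = 0.8, seed = 1),
                 "saturated")
})

test_that("bootstrap support is high for the true clade split", {
  sc <- generate_hgt_scenario(hgt = FALSE, seed = 12)
  tr <- bootstrap_support(sc$alignments$moaA, reps = 50, seed = 1)
  expect_true(!is.null(tr$node.label))
  expect_true(max(tr$node.label, na.rm = TRUE) >= 45)
})
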