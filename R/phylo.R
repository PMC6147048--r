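#' Pairwise p-distance
#'
#' Fraction of differing sites between two aligned sequences, with pairwise
#' deletion of positions where either sequence has a gap (`-` or `.`). If no
#' comparable sites remain the distance is 0 with a warning.
#'
#' @param seq_a,seq_b Aligned sequences (single strings) of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' p_distance("ACGT", "ACGA") # 0.25
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    abort(sprintf("unequal sequence lengths: %d vs %d", length(a), length(b)))
  }
  gap <- a %in% c("-", ".") | b %in% c("-", ".")
  a <- a[!gap]
  b <- b[!gap]
  if (length(a) == 0) {
    warn("no comparable (non-gap) sites; p-distance set to 0")
    return(0)
  }
  sum(a != b) / length(a)
}

#' p-distance matrix of an aligned block
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (at least 3).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = taxon
#'   ids.
#' @export
p_distance_matrix <- function(aln) {
  n <- length(aln)
  if (n < 3) abort("an aligned block needs at least 3 taxa")
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- p_distance(aln[[i]], aln[[j]])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration from a distance matrix: at each
#' step the pair minimising the Q criterion is joined; ties are broken by the
#' lexicographically smallest pair of taxon ids (each cluster represented by
#' its smallest original member). Negative branch-length estimates are
#' clamped at 0. On an additive matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param d Symmetric distance matrix with taxon ids as dimnames, `n >= 3`.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  # active nodes: newick fragment + smallest original taxon id (for ties)
  newick <- labels
  rep_id <- labels
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3) {
    r <- rowSums(d)
    best <- NULL
    best_q <- Inf
    best_key <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        key <- sort(c(rep_id[i], rep_id[j]))
        if (q < best_q - 1e-12 ||
            (abs(q - best_q) <= 1e-12 &&
             (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best_q <- q
          best <- c(i, j)
          best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li), newick[j], fmt(lj))
    merged_rep <- min(rep_id[i], rep_id[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    newick <- c(newick[keep], merged)
    rep_id <- c(rep_id[keep], merged_rep)
    n <- n - 1
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], fmt(la), newick[2], fmt(lb), newick[3], fmt(lc))
  ape::read.tree(text = txt)
}

#' Gene tree from an aligned block
#'
#' p-distance matrix plus neighbor joining.
#'
#' @param aln Named character vector of aligned sequences.
#' @return An `ape::phylo` tree.
#' @export
gene_tree <- function(aln) {
  neighbor_joining(p_distance_matrix(aln))
}

#' Bootstrap support for a gene tree
#'
#' Column-resampling bootstrap: alignment columns are resampled with
#' replacement, a neighbor-joining tree is built per replicate, and clade
#' frequencies are mapped onto the original tree's internal nodes.
#'
#' @param aln Named character vector of aligned sequences.
#' @param reps Number of replicates (default 100).
#' @param seed Optional integer seed.
#' @return The gene tree with `node.label` set to bootstrap counts.
#' @export
bootstrap_support <- function(aln, reps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- gene_tree(aln)
  len <- nchar(aln[[1]])
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  reps_trees <- lapply(seq_len(reps), function(i) {
    cols <- sample.int(len, len, replace = TRUE)
    resampled <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    gene_tree(resampled)
  })
  class(reps_trees) <- "multiPhylo"
  support <- ape::prop.clades(tree, reps_trees, rooted = FALSE)
  tree$node.label <- support
  tree
}

as_class_map <- function(taxonomy) {
  if (is.data.frame(taxonomy)) {
    stats::setNames(taxonomy$class, taxonomy$taxon_id)
  } else {
    taxonomy
  }
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Dominant taxonomic class of a leaf's sister group
#'
#' The tree is midpoint-rooted for orientation; the sister group is the set
#' of leaves under the focal leaf's sibling subtree(s). The dominant label is
#' the majority class among those leaves; ties yield `"ambiguous"`.
#'
#' @param tree An `ape::phylo` tree containing `focal`.
#' @param focal Focal taxon id (a tip label).
#' @param taxonomy Either a tibble with columns `taxon_id`, `class` or a
#'   named character vector mapping taxon id to class.
#' @return A single class label, or `"ambiguous"` on a tie.
#' @export
sister_clade <- function(tree, focal, taxonomy) {
  cls <- as_class_map(taxonomy)
  if (!focal %in% tree$tip.label) {
    abort(sprintf("focal taxon '%s' not in tree", focal))
  }
  rooted <- phangorn::midpoint(tree)
  tip <- which(rooted$tip.label == focal)
  parent <- rooted$edge[rooted$edge[, 2] == tip, 1]
  siblings <- setdiff(rooted$edge[rooted$edge[, 1] == parent, 2], tip)
  sister_tips <- unlist(lapply(siblings, tips_under, tree = rooted))
  sister_cls <- unname(cls[sister_tips])
  sister_cls <- sister_cls[!is.na(sister_cls)]
  if (length(sister_cls) == 0) return("ambiguous")
  tab <- sort(table(sister_cls), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("ambiguous")
  names(tab)[1]
}

#' Score a focal organism for horizontal transfer across gene trees
#'
#' A gene tree supports transfer when the focal leaf's sister group is
#' dominated by a taxonomic class different from the focal organism's own
#' declared class (ambiguous sisters never count). The organism is flagged
#' when at least `hgt_min_trees` gene trees concur — the incongruence
#' pattern of a recipient whose Moco genes all cluster inside a foreign
#' clade.
#'
#' @param trees Named list of `ape::phylo` gene trees.
#' @param taxonomy Taxon-to-class map (tibble or named vector), covering the
#'   focal organism.
#' @param focal Focal taxon id.
#' @param hgt_min_trees Minimum number of supporting gene trees for a flag.
#' @return An object of class `mo_hgt`: list with `focal`, `focal_class`,
#'   `per_gene` (tibble gene / sister_class / supports_hgt), `n_supporting`,
#'   `n_trees_with_focal` and `flagged`.
#' @export
hgt_score <- function(trees, taxonomy, focal, hgt_min_trees = 3) {
  cls <- as_class_map(taxonomy)
  if (!focal %in% names(cls)) {
    abort(sprintf("focal taxon '%s' missing from taxonomy", focal))
  }
  own <- unname(cls[focal])
  per_gene <- purrr::imap_dfr(trees, function(tr, gene) {
    if (!focal %in% tr$tip.label) {
      return(tibble(gene = gene, sister_class = NA_character_,
                    supports_hgt = NA))
    }
    sc <- sister_clade(tr, focal, cls)
    tibble(gene = gene, sister_class = sc,
           supports_hgt = sc != own & sc != "ambiguous")
  })
  n_sup <- sum(per_gene$supports_hgt, na.rm = TRUE)
  out <- list(
    focal = focal,
    focal_class = own,
    per_gene = per_gene,
    n_supporting = n_sup,
    n_trees_with_focal = sum(!is.na(per_gene$supports_hgt)),
    hgt_min_trees = hgt_min_trees,
    flagged = n_sup >= hgt_min_trees
  )
  class(out) <- "mo_hgt"
  out
}

#' @export
print.mo_hgt <- function(x, ...) {
  cat(sprintf("<mo_hgt> focal %s (%s): %d/%d gene trees support foreign placement; %s\n",
              x$focal, x$focal_class, x$n_supporting, x$n_trees_with_focal,
              if (x$flagged) "FLAGGED" else "not flagged"))
  print(x$per_gene)
  invisible(x)
}
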