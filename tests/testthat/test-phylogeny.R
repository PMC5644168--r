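test_that("NJ recovers additive trees and the 3-leaf closed form", {
  set.seed(41)
  ## known 5-leaf additive tree: NJ must recover the topology exactly
  for (i in 1:10) {
    tr <- ape::rtree(5)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    d <- ape::cophenetic.phylo(tr)
    nj <- nj_from_distances(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
                 ignore_attr = TRUE)
  }

  ## 3 leaves: branch lengths solve the three-point formulas
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj3 <- nj_from_distances(d)
  el <- setNames(nj3$edge.length, nj3$tip.label[nj3$edge[, 2]])
  expect_equal(el[["a"]], (3 + 4 - 5) / 2)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2)

  expect_error(nj_from_distances(d[1:2, 1:2]), "at least 3")
})

test_that("identical sequences get zero distance and trees have no negative branches", {
  set.seed(6)
  base <- rand_aln(1, 200)[1, ]
  aln <- rbind(s001 = base, s002 = base,           # identical pair
               s003 = mutate_row(base, 20), s004 = mutate_row(base, 40))
  w <- internal_window(0, 200)
  d <- ssucensus:::jc_distance_matrix(aln, w)
  expect_identical(d["s001", "s002"], 0)
  tr <- build_nj_tree(aln, w)
  expect_true(all(tr$edge.length >= 0))
  expect_error(build_nj_tree(aln[1:2, ], w), "at least 3")
})

test_that("saturated distances are capped with a warning", {
  set.seed(7)
  a <- rand_aln(1, 400, "a")[1, ]
  aln <- rbind(a = a, b = mutate_row(a, 5),
               far = sample(BASES4, 400, replace = TRUE))
  ## force near-maximal divergence for the third sequence
  aln["far", ] <- vapply(a, function(x) sample(setdiff(BASES4, x), 1), "")
  expect_warning(build_nj_tree(aln, internal_window(0, 400)), "saturated")
})

test_that("bootstrap replicates are deterministic under a fixed seed", {
  set.seed(3)
  base <- rand_aln(1, 150)[1, ]
  aln <- t(vapply(1:6, function(i) mutate_row(base, 15), character(150)))
  rownames(aln) <- sprintf("s%03d", 1:6)
  w <- internal_window(0, 150)
  expect_length(bootstrap_trees(aln, w, n = 0, seed = 1), 0)
  b1 <- bootstrap_trees(aln, w, n = 5, seed = 9)
  b2 <- bootstrap_trees(aln, w, n = 5, seed = 9)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
})

test_that("deep splits in clean data reach high bootstrap support", {
  ok <- 0
  for (seed in 1:5) {
    sim <- generate_dataset(sim_config(n_phyla = 3, otus_per_phylum = 3,
                                       seqs_per_otu = 1, chimera_fraction = 0,
                                       truncated_fraction = 0,
                                       gappy_fraction = 0, n_outgroup = 0,
                                       rng_seed = 300 + seed))
    w <- internal_window(0, 900)
    reps <- bootstrap_trees(sim$aln, w, n = 40, seed = seed)
    cons <- majority_consensus(reps)
    sup <- suppressWarnings(as.numeric(cons$node.label))
    ## phylum splits are deep and should be near-unanimous
    if (all(sup[!is.na(sup)] > 50) && sum(!is.na(sup)) >= 2) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("majority consensus keeps strict-majority splits with exact supports", {
  ## all trees identical: consensus equals them with 100% supports
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  cons <- majority_consensus(list(tr, tr, tr))
  expect_equal(ape::dist.topo(cons, ape::unroot(tr)), 0, ignore_attr = TRUE)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  ## 50/50 conflict collapses to a polytomy
  t1 <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,b:1,d:1);")
  cons2 <- majority_consensus(list(t1, t2))
  expect_equal(cons2$Nnode, 1)    # star: no retained split

  expect_error(majority_consensus(list(
    t1, ape::read.tree(text = "((a:1,b:1):1,c:1,e:1);"))), "mismatched")
})

test_that("consensus supports equal brute-force bipartition tallies", {
  set.seed(50)
  for (i in 1:5) {
    trees <- lapply(1:7, function(j) ape::rtree(5, tip.label = letters[1:5]))
    cons <- majority_consensus(trees)
    oracle <- brute_split_supports(trees)
    keys_kept <- names(oracle)[unlist(oracle) > 7 / 2]
    ## consensus keeps exactly the strict-majority splits
    sup <- suppressWarnings(as.numeric(cons$node.label))
    expect_equal(sum(!is.na(sup)), length(keys_kept))
    for (k in keys_kept) {
      side <- strsplit(k, ",")[[1]]
      expect_true(tree_has_split(cons, side))
    }
    ## mapped supports agree with the oracle counts
    if (length(keys_kept)) {
      mapped <- map_supports(cons, trees)
      msup <- suppressWarnings(as.numeric(mapped$node.label))
      expect_setequal(round(msup[!is.na(msup)], 6),
                      round(100 * unlist(oracle[keys_kept]) / 7, 6))
    }
  }
})

test_that("rogue removal finds planted rogues and raises consensus support", {
  ## stable replicates: no rogues, stops immediately
  tr <- ape::rtree(8)
  stable <- find_and_drop_rogues(rep(list(tr), 10))
  expect_equal(nrow(stable$rounds), 0)
  expect_length(stable$leaves, 8)

  skip_if_not_installed("phytools")
  found <- 0
  for (seed in 1:5) {
    set.seed(seed)
    base <- ape::rtree(12)
    rogue <- base$tip.label[1]
    reps <- lapply(1:30, function(i) regraft_leaf(base, rogue))
    res <- find_and_drop_rogues(reps)
    r1 <- res$rounds$rogue_id[res$rounds$round == 1]
    if (rogue %in% r1) found <- found + 1
    ## pruning the rogues of a round never lowers the consensus support score
    expect_true(all(diff(res$support_score) >= -1e-9))
  }
  expect_gte(found, 4)
})

test_that("outgroup rooting handles pendant, clade and degenerate cases", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):1):1,f:1);")
  r1 <- root_with_outgroup(tr, "f")
  expect_true(ape::is.rooted(r1))
  kids <- phangorn::Descendants(r1, length(r1$tip.label) + 1, "children")
  ## one side of the root is exactly the outgroup leaf
  expect_true(any(r1$tip.label[kids[kids <= 6]] == "f"))

  ## monophyletic multi-leaf outgroup roots on the clade stem
  tr8 <- ape::read.tree(
    text = "(((o1:1,o2:1):1,o3:1):1,((x1:1,x2:1):1,(x3:1,x4:1):1):1,x5:1);")
  r2 <- root_with_outgroup(tr8, c("o1", "o2", "o3"))
  expect_true(ape::is.rooted(r2))
  og_mrca <- ape::getMRCA(r2, c("o1", "o2", "o3"))
  tips_og <- r2$tip.label[phangorn::Descendants(r2, og_mrca, "tips")[[1]]]
  expect_setequal(tips_og, c("o1", "o2", "o3"))

  ## non-monophyletic outgroup warns but still roots
  expect_warning(r3 <- root_with_outgroup(tr8, c("o1", "x5")),
                 "not monophyletic")
  expect_true(ape::is.rooted(r3))

  expect_error(root_with_outgroup(tr, tr$tip.label), "all leaves")
  expect_error(root_with_outgroup(tr, "nope"), "absent")
})

test_that("long-branch flagging is exact and monotone in the multiplier", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_length(flag_long_branches(tr), 0)
  tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "d")] <- 20
  expect_identical(flag_long_branches(tr), "d")
  expect_length(flag_long_branches(tr, multiplier = Inf), 0)
})

test_that("phylum assignment requires pure, supported clades", {
  ## ((u,a)100,(b1,b2)100) rooted: u is sister to labeled a
  tr <- ape::read.tree(text = "((u:1,a:1)100:1,(b1:1,b2:1)100:1);")
  labels <- c(a = "PhA", b1 = "PhB", b2 = "PhB")
  res <- assign_phyla(tr, labels)
  expect_equal(res$phylum[res$leaf == "u"], "PhA")
  expect_equal(res$basis[res$leaf == "u"], "assigned")

  ## mixed labels in the smallest labeled clade: unassigned
  tr2 <- ape::read.tree(text = "((u:1,(a:1,b:1)90:1)80:1,(c1:1,c2:1)100:1);")
  res2 <- assign_phyla(tr2, c(a = "PhA", b = "PhB", c1 = "PhC", c2 = "PhC"))
  expect_true(is.na(res2$phylum[res2$leaf == "u"]))

  ## support below threshold: unassigned
  tr3 <- ape::read.tree(text = "((u:1,a:1)40:1,(b1:1,b2:1)100:1);")
  res3 <- assign_phyla(tr3, labels)
  expect_true(is.na(res3$phylum[res3$leaf == "u"]))

  expect_warning(res4 <- assign_phyla(tr, character(0)), "no labeled")
  expect_true(all(res4$basis == "unassigned"))
})

test_that("assignment recovers true phyla on synthetic data with partial labels", {
  good <- 0; tried <- 0
  for (seed in 1:5) {
    sim <- generate_dataset(sim_config(n_phyla = 3, otus_per_phylum = 4,
                                       seqs_per_otu = 1, chimera_fraction = 0,
                                       truncated_fraction = 0,
                                       gappy_fraction = 0, n_outgroup = 1,
                                       rng_seed = 400 + seed))
    w <- internal_window(0, 900)
    aln <- rbind(sim$aln, sim$outgroup)
    tree <- build_nj_tree(aln, w)
    tree <- root_with_outgroup(tree, rownames(sim$outgroup))
    tree <- map_supports(tree, bootstrap_trees(aln, w, n = 30, seed = seed))
    truth <- setNames(sim$truth$true_phylum, sim$truth$seq_id)
    ## label half of the leaves per phylum
    labels <- character(0)
    for (ph in unique(truth)) {
      ids <- names(truth)[truth == ph]
      labels <- c(labels, setNames(truth[ids[seq_len(2)]], ids[seq_len(2)]))
    }
    res <- assign_phyla(tree, labels)
    res <- res[res$basis == "assigned", ]
    tried <- tried + nrow(res)
    good <- good + sum(res$phylum == truth[res$leaf])
  }
  expect_gt(tried, 0)
  expect_gte(good / tried, 0.95)
})
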