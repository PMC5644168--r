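test_that("pairwise identity follows the dual-gap-excluded definition", {
  w10 <- internal_window(0, 10)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAC", w10), 100)
  ## 9 matching of 10 scored columns
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAG", w10), 90)
  ## dual-gap column excluded: 3 matches / 4 scored
  expect_equal(pairwise_identity("AC--T", "ACG-T", internal_window(0, 5)), 75)
  expect_error(pairwise_identity("-----", "ACGTA", internal_window(0, 5)),
               "all-gap")
})

test_that("greedy clustering applies the first-centroid scan rule", {
  w <- internal_window(0, 100)
  ## identical sequences collapse into one cluster
  aln <- aln_matrix(setNames(rep(paste(rep("ACGT", 25), collapse = ""), 5),
                             paste0("s", 1:5)))
  out <- greedy_cluster(aln, 97, w)
  expect_equal(length(unique(out$cluster)), 1)
  expect_equal(sum(out$is_centroid), 1)

  ## two sequences at exactly 96% window identity split at threshold 97
  set.seed(2)
  a <- rand_aln(1, 100, "a")[1, ]
  b <- mutate_row(a, 4)
  aln2 <- rbind(a = a, b = b)
  expect_equal(pairwise_identity(aln2["a", ], aln2["b", ], w), 96)
  out2 <- greedy_cluster(aln2, 97, w)
  expect_equal(length(unique(out2$cluster)), 2)
  out3 <- greedy_cluster(aln2, 96, w)
  expect_equal(length(unique(out3$cluster)), 1)

  expect_equal(nrow(greedy_cluster(aln2[0, , drop = FALSE], 97, w)), 0)
  expect_error(greedy_cluster(aln2, 0, w), "threshold")
})

test_that("greedy clustering matches the naive reference scan on random instances", {
  set.seed(99)
  w <- internal_window(0, 60)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    base <- rand_aln(1, 60)[1, ]
    aln <- t(vapply(seq_len(n), function(j) mutate_row(base, sample(0:25, 1)),
                    character(60)))
    rownames(aln) <- sprintf("s%03d", seq_len(n))
    ## random terminal gapping to vary ungapped lengths
    for (j in sample(n, ceiling(n / 3))) {
      k <- sample(1:10, 1)
      aln[j, seq_len(k)] <- "-"
    }
    thr <- sample(c(85, 92, 97), 1)
    mine <- greedy_cluster(aln, thr, w)
    ref <- naive_greedy(aln, thr, 0, 60)
    expect_identical(mine$cluster, ref$assign)
    expect_identical(mine$centroid_id, ref$centroid_id)
  }
})

test_that("members always reach threshold identity to their centroid", {
  set.seed(5)
  sim <- generate_dataset(sim_config(n_phyla = 2, otus_per_phylum = 4,
                                     seqs_per_otu = 4, chimera_fraction = 0,
                                     truncated_fraction = 0, gappy_fraction = 0,
                                     rng_seed = 5))
  w <- internal_window(0, 900)
  out <- greedy_cluster(sim$aln, 97, w)
  for (i in seq_len(nrow(out))) {
    expect_gte(pairwise_identity(sim$aln[out$seq_id[i], ],
                                 sim$aln[out$centroid_id[i], ], w), 97)
  }
})

test_that("two-level clustering links OTUs to clusters and removes singletons", {
  set.seed(12)
  sim <- generate_dataset(sim_config(n_phyla = 3, otus_per_phylum = 5,
                                     seqs_per_otu = 4, chimera_fraction = 0,
                                     truncated_fraction = 0, gappy_fraction = 0,
                                     rng_seed = 12))
  w <- internal_window(0, 900)
  ## add one lone unrelated sequence
  lone <- matrix(sample(BASES4, 1534, replace = TRUE), nrow = 1,
                 dimnames = list("loner", NULL))
  aln <- rbind(sim$aln, lone)
  tlc <- two_level_cluster(aln, w)

  ## partition property: every sequence in exactly one OTU
  expect_setequal(tlc$membership$seq_id, rownames(aln))
  expect_equal(anyDuplicated(tlc$membership$seq_id), 0)

  ## every OTU in exactly one 85% cluster or unplaced
  placed <- !is.na(tlc$otus$cluster_id)
  expect_true(all(tlc$otus$cluster_id[placed] %in% tlc$clusters85$cluster_id))
  expect_true(all(xor(placed, tlc$otus$unplaced)))

  ## the loner's singleton 85% cluster was removed
  lone_otu <- tlc$membership$otu_id[tlc$membership$seq_id == "loner"]
  expect_true(tlc$otus$unplaced[tlc$otus$otu_id == lone_otu])

  ## determinism
  tlc2 <- two_level_cluster(aln, w)
  expect_identical(tlc, tlc2)

  ## singleton rule by OTU instead of by sequence
  tlc3 <- two_level_cluster(aln, w, singleton_unit = "otu")
  expect_true(all(tlc3$clusters85$n_otus >= 2))
})

test_that("novelty categories follow the genome > reference > mg-only precedence", {
  set.seed(77)
  w <- internal_window(0, 120)
  base <- rand_aln(1, 120)[1, ]
  otu_a <- t(vapply(1:3, function(i) mutate_row(base, 1), character(120)))
  rownames(otu_a) <- c("a1", "a2", "a3")
  base_b <- mutate_row(base, 30)
  otu_b <- t(vapply(1:2, function(i) mutate_row(base_b, 1), character(120)))
  rownames(otu_b) <- c("b1", "b2")
  base_c <- mutate_row(mutate_row(base, 30), 30)
  otu_c <- matrix(base_c, nrow = 1, dimnames = list("c1", NULL))
  aln <- rbind(otu_a, otu_b, otu_c)

  ## references: one near otu_a (which also holds a genome member), one near
  ## otu_b, none near otu_c, plus one unrelated reference-only sequence
  refs <- rbind(ref_a = mutate_row(base, 1), ref_b = mutate_row(base_b, 1),
                ref_far = rand_aln(1, 120)[1, ])
  meta <- data.frame(seq_id = rownames(aln),
                     source = c("genome", "metagenome", "metagenome",
                                "metagenome", "metagenome", "metagenome"),
                     environment = "", phylum_label = "",
                     stringsAsFactors = FALSE)
  tlc <- two_level_cluster(aln, w)
  otus <- categorize_novelty(tlc, aln, refs, w, meta)
  otu_of <- setNames(tlc$membership$otu_id, tlc$membership$seq_id)
  ## genome membership takes precedence even though a reference co-clusters
  expect_equal(otus$novelty[otus$otu_id == otu_of[["a1"]]], "genome_backed")
  expect_equal(otus$novelty[otus$otu_id == otu_of[["b1"]]], "mg_and_silva")
  expect_equal(otus$novelty[otus$otu_id == otu_of[["c1"]]], "mg_only")
  expect_equal(attr(otus, "reference_only_clusters"), 1)
})
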