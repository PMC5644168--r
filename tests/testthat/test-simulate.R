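test_that("guide trees are deterministic, degenerate-safe, and scaled to the between-OTU divergence", {
  cfg <- sim_config(rng_seed = 42)
  t1 <- simulate_guide_trees(cfg)
  t2 <- simulate_guide_trees(cfg)
  expect_identical(lapply(t1, ape::write.tree), lapply(t2, ape::write.tree))

  cfg1 <- sim_config(otus_per_phylum = 1, rng_seed = 1)
  tt <- simulate_guide_trees(cfg1)
  expect_equal(nrow(tt[[1]]$edge), 0)
  expect_length(tt[[1]]$tip.label, 1)

  ## Monte-Carlo check of the scaling rule: mean pairwise path length should
  ## match twice the between-OTU divergence
  cfg8 <- sim_config(n_phyla = 200, otus_per_phylum = 8,
                     between_otu_divergence = 0.05,
                     between_phylum_divergence = 0.15, rng_seed = 9)
  trees <- simulate_guide_trees(cfg8)
  paths <- vapply(trees, function(tr) {
    d <- ape::cophenetic.phylo(tr)
    mean(d[upper.tri(d)])
  }, numeric(1))
  expect_lt(abs(mean(paths) - 2 * 0.05) / (2 * 0.05), 0.10)
})

test_that("sequence evolution follows the Jukes-Cantor expectation", {
  root <- sample(BASES4, 500, replace = TRUE)
  tr <- ape::read.tree(text = "(a:0.025,b:0.025);")

  ## zero rate: leaves identical to root
  out0 <- evolve_alignment(root, tr, rate_per_site = 0, seed = 1)
  expect_identical(unname(out0["a", ]), root)
  expect_identical(unname(out0["b", ]), root)

  ## determinism under a fixed seed
  o1 <- evolve_alignment(root, tr, seed = 5)
  o2 <- evolve_alignment(root, tr, seed = 5)
  expect_identical(o1, o2)

  ## closed-form JC oracle: two leaves at total path t = 0.05
  t <- 0.05
  expected_p <- 0.75 * (1 - exp(-4 * t / 3))
  nsites <- 10000; nrep <- 200
  root_l <- sample(BASES4, nsites, replace = TRUE)
  set.seed(17)
  phat <- vapply(seq_len(nrep), function(i) {
    leaves <- evolve_alignment(root_l, tr)
    mean(leaves["a", ] != leaves["b", ])
  }, numeric(1))
  se <- sd(phat) / sqrt(nrep)
  expect_lt(abs(mean(phat) - expected_p), 3 * se)

  expect_error(evolve_alignment(root, ape::read.tree(text = "(a:-1,b:1);")),
               "negative")
})

test_that("chimera construction respects breakpoints and boundary cases", {
  a <- strsplit("AAAAAAAAAAAAAAAAAAAA", "")[[1]]
  b <- strsplit("CCCCCCCCCCCCCCCCCCCC", "")[[1]]
  expect_identical(make_chimera(a, b, 0), b)
  expect_identical(make_chimera(a, b, 20), a)
  expect_error(make_chimera(a, b, 21), "breakpoint")
  expect_error(make_chimera(a, b, -1), "breakpoint")

  ## mid-point chimera of ~10% divergent parents: identity to each parent is
  ## strictly between the parents' mutual identity and 100%
  set.seed(3)
  pa <- rand_aln(1, 200, "pa")[1, ]
  pb <- mutate_row(pa, 20)
  ch <- make_chimera(pa, pb, 100)
  w <- internal_window(0, 200)
  id_ab <- pairwise_identity(pa, pb, w)
  id_ca <- pairwise_identity(ch, pa, w)
  id_cb <- pairwise_identity(ch, pb, w)
  expect_true(id_ca > id_ab && id_ca < 100)
  expect_true(id_cb > id_ab && id_cb < 100)
})

test_that("generated datasets are deterministic with complete, exclusive truth tables", {
  cfg <- sim_config(n_phyla = 3, otus_per_phylum = 5, seqs_per_otu = 4,
                    chimera_fraction = 0, truncated_fraction = 0,
                    gappy_fraction = 0, rng_seed = 11)
  sim <- generate_dataset(cfg)
  sim2 <- generate_dataset(cfg)
  expect_identical(sim$aln, sim2$aln)
  expect_identical(sim$truth, sim2$truth)

  ## bookkeeping: 3 x 5 x 4 = 60 non-artifact sequences in 15 true OTUs
  expect_equal(nrow(sim$aln), 60)
  expect_false(any(sim$truth$is_chimera | sim$truth$is_truncated |
                     sim$truth$is_gappy | sim$truth$is_rogue))
  expect_equal(length(unique(sim$truth$true_otu)), 15)

  ## every sequence appears exactly once in the truth table
  expect_setequal(sim$truth$seq_id, rownames(sim$aln))
  expect_equal(anyDuplicated(sim$truth$seq_id), 0)
})

test_that("artifact fractions are honored and flags are mutually exclusive", {
  cfg <- sim_config(n_phyla = 5, otus_per_phylum = 5, seqs_per_otu = 8,
                    chimera_fraction = 0.05, truncated_fraction = 0.1,
                    gappy_fraction = 0.05, rng_seed = 23)
  sim <- generate_dataset(cfg)   # 200 sequences
  tr <- sim$truth
  expect_equal(sum(tr$is_truncated), round(0.1 * 200))
  expect_equal(sum(tr$is_chimera), round(0.05 * 200))
  flags <- tr$is_chimera + tr$is_truncated + tr$is_gappy + tr$is_rogue
  expect_true(all(flags <= 1))

  ## truncated sequences really fall below 1200 ungapped bases
  lens <- ungapped_length(sim$aln)
  expect_true(all(lens[tr$seq_id[tr$is_truncated]] < 1200))
  expect_true(all(lens[tr$seq_id[!tr$is_truncated & !tr$is_gappy]] == 1534))

  ## gappy sequences exceed 40 gaps in any 900-column window
  gappy <- tr$seq_id[tr$is_gappy]
  w <- internal_window(0, 900)
  gaps <- rowSums(sim$aln[gappy, 1:900, drop = FALSE] == "-")
  expect_true(all(gaps > 40))

  ## chimera parents are clean sequences from distinct true OTUs
  ch <- tr[tr$is_chimera, ]
  expect_false(any(ch$chimera_parent_a %in% tr$seq_id[tr$is_chimera]))
  pa_otu <- tr$true_otu[match(ch$chimera_parent_a, tr$seq_id)]
  pb_otu <- tr$true_otu[match(ch$chimera_parent_b, tr$seq_id)]
  expect_true(all(pa_otu != pb_otu))
})

test_that("divergence ordering in the config is reflected in pairwise identities", {
  cfg <- sim_config(n_phyla = 3, otus_per_phylum = 4, seqs_per_otu = 4,
                    chimera_fraction = 0, truncated_fraction = 0,
                    gappy_fraction = 0, rng_seed = 31)
  sim <- generate_dataset(cfg)
  w <- internal_window(0, 900)
  tr <- sim$truth
  set.seed(1)
  pick_pairs <- function(cond, n = 40) {
    out <- numeric(0)
    for (i in seq_len(500)) {
      ij <- sample(nrow(sim$aln), 2)
      if (!cond(ij[1], ij[2])) next
      out <- c(out, pairwise_identity(sim$aln[ij[1], ], sim$aln[ij[2], ], w))
      if (length(out) >= n) break
    }
    out
  }
  same_otu <- pick_pairs(function(i, j) tr$true_otu[i] == tr$true_otu[j])
  same_ph <- pick_pairs(function(i, j) tr$true_otu[i] != tr$true_otu[j] &&
                          tr$true_phylum[i] == tr$true_phylum[j])
  diff_ph <- pick_pairs(function(i, j) tr$true_phylum[i] != tr$true_phylum[j])
  expect_gt(mean(same_otu), mean(same_ph))
  expect_gt(mean(same_ph), mean(diff_ph))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(within_otu_divergence = 0.1,
                          between_otu_divergence = 0.05), "ordered")
  expect_error(sim_config(chimera_fraction = 0.7, truncated_fraction = 0.4),
               "fractions")
  expect_error(sim_config(otus_per_phylum = 0), ">= 1")
  expect_error(sim_config(source_mix = c(metagenome = 1, genome = 0.5,
                                         reference_db = 0)), "source_mix")
})
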