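## Synthetic phylum-structured SSU rRNA communities with known truth.
##
## Families are evolved by independent-site Jukes-Cantor substitution along
## simulated guide trees; artifacts (chimeras, truncated and gap-riddled
## sequences, rogue mosaics) are injected post hoc by masking/recombination,
## so alignment coordinates stay exact and every downstream filter is
## directly testable against the emitted truth tables.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Divergences are expected substitutions per site along a lineage: sequences
#' within one OTU each diverge `within_otu_divergence` from their OTU
#' ancestor (a pair therefore separates by about twice that), OTU ancestors
#' within a phylum separate by about `2 * between_otu_divergence`, and phylum
#' roots each diverge `between_phylum_divergence` from a global ancestor.
#' The strict ordering within < between-OTU < between-phylum is required so
#' that 97% OTUs and 85% clusters are recoverable in principle.
#'
#' @param n_phyla,otus_per_phylum,seqs_per_otu community shape.
#' @param match_length alignment length in match columns.
#' @param within_otu_divergence,between_otu_divergence,between_phylum_divergence
#'   lineage divergences in substitutions/site (see Details above).
#' @param chimera_fraction,truncated_fraction,gappy_fraction,rogue_fraction
#'   proportions of sequences converted into planted artifacts; they must sum
#'   to at most 1 and are mutually exclusive per sequence.
#' @param source_mix named proportions over metagenome / genome /
#'   reference_db; must sum to 1.
#' @param environments environment labels assigned to metagenome sequences.
#' @param env_spread probability that a metagenome sequence is observed in a
#'   second environment besides its OTU's home environment.
#' @param n_outgroup,outgroup_divergence deeply diverged outgroup sequences
#'   emitted in a separate slot, for rooting.
#' @param rng_seed integer seed; a fixed seed yields a bit-identical dataset.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_phyla = 4, otus_per_phylum = 6, seqs_per_otu = 5,
                       match_length = 1534,
                       within_otu_divergence = 0.003,
                       between_otu_divergence = 0.065,
                       between_phylum_divergence = 0.15,
                       chimera_fraction = 0.05,
                       truncated_fraction = 0.03,
                       gappy_fraction = 0.03,
                       rogue_fraction = 0,
                       source_mix = c(metagenome = 0.6, genome = 0.25,
                                      reference_db = 0.15),
                       environments = c("soil", "groundwater", "freshwater",
                                        "seawater", "host_associated"),
                       env_spread = 0.25,
                       n_outgroup = 3, outgroup_divergence = 0.5,
                       rng_seed = 1) {
  cfg <- list(n_phyla = as.integer(n_phyla),
              otus_per_phylum = as.integer(otus_per_phylum),
              seqs_per_otu = as.integer(seqs_per_otu),
              match_length = as.integer(match_length),
              within_otu_divergence = within_otu_divergence,
              between_otu_divergence = between_otu_divergence,
              between_phylum_divergence = between_phylum_divergence,
              chimera_fraction = chimera_fraction,
              truncated_fraction = truncated_fraction,
              gappy_fraction = gappy_fraction,
              rogue_fraction = rogue_fraction,
              source_mix = source_mix,
              environments = environments,
              env_spread = env_spread,
              n_outgroup = as.integer(n_outgroup),
              outgroup_divergence = outgroup_divergence,
              rng_seed = as.integer(rng_seed))
  fr <- c(cfg$chimera_fraction, cfg$truncated_fraction, cfg$gappy_fraction,
          cfg$rogue_fraction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("artifact fractions must lie in [0,1] and sum to at most 1")
  if (!(cfg$within_otu_divergence < cfg$between_otu_divergence &&
        cfg$between_otu_divergence < cfg$between_phylum_divergence))
    stop("divergences must be strictly ordered: within_otu < between_otu < between_phylum")
  if (cfg$n_phyla < 1 || cfg$otus_per_phylum < 1 || cfg$seqs_per_otu < 1)
    stop("n_phyla, otus_per_phylum and seqs_per_otu must be >= 1")
  if (!setequal(names(cfg$source_mix),
                c("metagenome", "genome", "reference_db")) ||
      abs(sum(cfg$source_mix) - 1) > 1e-8 || any(cfg$source_mix < 0))
    stop("source_mix must be proportions over metagenome/genome/reference_db summing to 1")
  if (cfg$match_length < 900)
    stop("match_length must be at least the downstream window width (900)")
  structure(cfg, class = "sim_config")
}

## single-tip "tree": zero edges, the leaf is the root
single_tip_tree <- function(label) {
  structure(list(edge = matrix(integer(0), 0, 2), tip.label = label,
                 edge.length = numeric(0), Nnode = 1L),
            class = "phylo")
}

## one coalescent guide tree, rescaled so the mean pairwise leaf-to-leaf path
## length equals 2 * between_otu_divergence (each lineage carries the
## between-OTU divergence on average).  Half of the pairwise divergence is
## carried by private terminal stems, so every leaf pair is separated by at
## least between_otu_divergence: OTUs stay individually resolvable instead
## of collapsing when two lineages happen to coalesce recently.  Uses the
## current RNG stream.
guide_tree <- function(n_leaves, between_otu_divergence,
                       labels = paste0("otu", seq_len(n_leaves))) {
  if (n_leaves < 1) stop("otus_per_phylum must be >= 1")
  if (n_leaves == 1) return(single_tip_tree(labels))
  tr <- ape::rcoal(n_leaves, tip.label = labels)
  d <- ape::cophenetic.phylo(tr)
  mean_path <- mean(d[upper.tri(d)])
  target <- 2 * between_otu_divergence
  tr$edge.length <- tr$edge.length * (target / 2 / mean_path)
  term <- tr$edge[, 2] <= n_leaves
  tr$edge.length[term] <- tr$edge.length[term] + target / 4
  tr
}

#' Simulate per-phylum guide trees
#'
#' One random bifurcating coalescent (hence ultrametric) tree per phylum with
#' `otus_per_phylum` leaves, branch lengths rescaled so the mean pairwise
#' leaf-to-leaf path length equals `2 * between_otu_divergence`.
#'
#' @param config a [sim_config()].
#' @return named list of `phylo` objects, one per phylum.
#' @export
simulate_guide_trees <- function(config) {
  set.seed(config$rng_seed)
  phyla <- phylum_names(config$n_phyla)
  setNames(lapply(phyla, function(p)
    guide_tree(config$otus_per_phylum, config$between_otu_divergence)),
    phyla)
}

phylum_names <- function(n) sprintf("phylum_%02d", seq_len(n))

random_sequence <- function(n) sample(BASES, n, replace = TRUE)

## Jukes-Cantor substitution of a residue vector over branch length t
## (expected substitutions/site): each site changes to a specific other base
## with probability (1 - exp(-4t/3)) / 4
jc_evolve <- function(seq, t) {
  if (t < 0) stop("negative branch length")
  if (t == 0) return(seq)
  p_change <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- runif(length(seq)) < p_change
  n <- sum(hit)
  if (n) {
    idx <- match(seq[hit], BASES)
    shift <- sample.int(3, n, replace = TRUE)        # 1..3 positions away
    seq[hit] <- BASES[((idx - 1 + shift) %% 4) + 1]
  }
  seq
}

#' Evolve a root sequence along a tree under Jukes-Cantor substitution
#'
#' Sites evolve independently with no indels, so alignment coordinates are
#' preserved exactly.  Branch lengths are in expected substitutions per site,
#' multiplied by `rate_per_site`.
#'
#' @param root_sequence character vector of residues (or a single string).
#' @param tree a `phylo` with branch lengths (a single-tip tree returns the
#'   root unchanged).
#' @param rate_per_site rate multiplier applied to all branch lengths.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return character matrix of leaf sequences (rows named by tip labels).
#' @export
evolve_alignment <- function(root_sequence, tree, rate_per_site = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(root_sequence) == 1) root_sequence <- strsplit(root_sequence, "")[[1]]
  if (!all(root_sequence %in% BASES)) stop("root sequence must be over A/C/G/T")
  ntip <- length(tree$tip.label)
  if (nrow(tree$edge) == 0) {
    m <- matrix(root_sequence, nrow = 1)
    rownames(m) <- tree$tip.label
    return(m)
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_sequence
  # tree$edge rows of an ape phylo are in preorder from the root
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    seqs[[child]] <- jc_evolve(seqs[[par]], tree$edge.length[i] * rate_per_site)
  }
  out <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(out) <- tree$tip.label
  out
}

#' Recombine two aligned parents into a chimera at a breakpoint
#'
#' Columns `[0, breakpoint)` are taken from `parent_a` and `[breakpoint,
#' end)` from `parent_b` (0-based, half-open).
#'
#' @param parent_a,parent_b residue vectors in shared alignment coordinates.
#' @param breakpoint 0-based column, in `[0, length]`.
#' @return chimeric residue vector.
#' @export
make_chimera <- function(parent_a, parent_b, breakpoint) {
  if (length(parent_a) == 1) parent_a <- strsplit(parent_a, "")[[1]]
  if (length(parent_b) == 1) parent_b <- strsplit(parent_b, "")[[1]]
  if (length(parent_a) != length(parent_b))
    stop("parents must share alignment coordinates")
  L <- length(parent_a)
  if (breakpoint < 0 || breakpoint > L)
    stop("breakpoint ", breakpoint, " outside [0, ", L, "]")
  c(parent_a[seq_len(breakpoint)],
    parent_b[seq_len(L - breakpoint) + breakpoint])
}

#' Generate a complete synthetic dataset with truth tables
#'
#' Evolves `n_phyla * otus_per_phylum * seqs_per_otu` sequences from a global
#' random ancestor (phylum roots diverged by `between_phylum_divergence`, OTU
#' ancestors along per-phylum guide trees, members by
#' `within_otu_divergence`), then converts disjoint random subsets into
#' planted artifacts: chimeras (two clean parents from distinct phyla,
#' breakpoint uniform in the middle third of the default clustering window),
#' truncated sequences (terminal columns masked so the ungapped length falls
#' below 1200), gap-riddled sequences (about 90 gaps spread evenly along the
#' alignment, so any 900-column window holds well over 40), and rogue mosaics
#' (alternating blocks from several phylum roots, yielding an unstable
#' phylogenetic position).  Sources are drawn per sequence from
#' `source_mix`; each OTU gets a home environment, and metagenome-source
#' members may additionally be observed in one other environment with
#' probability `env_spread`.  Genome-source sequences carry their true phylum
#' as `phylum_label` metadata (emulating taxonomy known from genome
#' annotation).
#'
#' @param config a [sim_config()].
#' @return object of class `ssu_sim`: list with `aln` (alignment matrix),
#'   `meta` (seq_id, source, environment, phylum_label), `truth` (per-seq
#'   truth table), `guide_trees`, `outgroup` (alignment matrix or NULL) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$match_length
  trees <- simulate_guide_trees(config)   # seeds the stream with rng_seed
  ancestor <- random_sequence(L)
  phyla <- phylum_names(config$n_phyla)

  rows <- list(); ids <- character(0)
  true_otu <- character(0); true_phylum <- character(0)
  phylum_roots <- list()
  for (p in seq_along(phyla)) {
    root_p <- jc_evolve(ancestor, config$between_phylum_divergence)
    phylum_roots[[phyla[p]]] <- root_p
    otu_anc <- evolve_alignment(root_p, trees[[p]])
    for (o in seq_len(nrow(otu_anc))) {
      otu_name <- sprintf("%s_otu%03d", phyla[p], o)
      for (s in seq_len(config$seqs_per_otu)) {
        id <- sprintf("%s_s%02d", otu_name, s)
        rows[[id]] <- jc_evolve(otu_anc[o, ], config$within_otu_divergence)
        ids <- c(ids, id)
        true_otu <- c(true_otu, otu_name)
        true_phylum <- c(true_phylum, phyla[p])
      }
    }
  }
  aln <- do.call(rbind, rows)
  rownames(aln) <- ids
  N <- nrow(aln)

  source <- sample(names(config$source_mix), N, replace = TRUE,
                   prob = config$source_mix)

  ## disjoint artifact subsets
  n_chim <- round(config$chimera_fraction * N)
  n_trunc <- round(config$truncated_fraction * N)
  n_gappy <- round(config$gappy_fraction * N)
  n_rogue <- round(config$rogue_fraction * N)
  perm <- sample.int(N)
  chim_i  <- perm[seq_len(n_chim)]
  trunc_i <- perm[n_chim + seq_len(n_trunc)]
  gappy_i <- perm[n_chim + n_trunc + seq_len(n_gappy)]
  rogue_i <- perm[n_chim + n_trunc + n_gappy + seq_len(n_rogue)]
  clean_i <- perm[-seq_len(n_chim + n_trunc + n_gappy + n_rogue)]

  is_chimera <- is_truncated <- is_gappy <- is_rogue <- logical(N)
  parent_a <- parent_b <- rep(NA_character_, N)
  breakpoint <- rep(NA_integer_, N)

  if (n_chim > 0 && length(clean_i) < 2)
    stop("not enough clean sequences to draw chimera parents")
  pick1 <- function(v) v[sample.int(length(v), 1)]
  for (i in chim_i) {
    repeat {
      pa <- pick1(clean_i)
      pb <- pick1(clean_i)
      distinct <- if (config$n_phyla > 1) true_phylum[pa] != true_phylum[pb]
                  else true_otu[pa] != true_otu[pb]
      if (distinct) break
    }
    bp <- sample(300:600, 1)     # middle third of the default [0,900) window
    aln[i, ] <- make_chimera(aln[pa, ], aln[pb, ], bp)
    is_chimera[i] <- TRUE
    parent_a[i] <- ids[pa]; parent_b[i] <- ids[pb]; breakpoint[i] <- bp
    source[i] <- "metagenome"
  }
  for (i in trunc_i) {
    keep <- sample(950:1150, 1)  # surviving leading/trailing bases, < 1200
    if (runif(1) < 0.5) aln[i, (keep + 1):L] <- GAP
    else aln[i, 1:(L - keep)] <- GAP
    is_truncated[i] <- TRUE
  }
  if (n_gappy) {
    gap_cols <- unique(round(seq(1, L, length.out = 92)))
    for (i in gappy_i) {
      jitter <- sample(0:14, 1)
      cols <- pmin(gap_cols + jitter, L)
      aln[i, cols] <- GAP
      is_gappy[i] <- TRUE
    }
  }
  for (i in rogue_i) {
    donors <- sample(phyla, min(3, length(phyla)))
    block <- 150
    starts <- seq(1, L, by = block)
    for (b in seq_along(starts)) {
      cols <- starts[b]:min(starts[b] + block - 1, L)
      aln[i, cols] <- phylum_roots[[donors[(b - 1) %% length(donors) + 1]]][cols]
    }
    is_rogue[i] <- TRUE
    source[i] <- "metagenome"
  }
  artifact <- is_chimera | is_rogue
  true_otu[artifact] <- NA_character_
  true_phylum[artifact] <- NA_character_

  ## environments: home environment per true OTU; metagenome members may be
  ## observed in a second environment with probability env_spread
  all_otus <- unique(stats::na.omit(true_otu))
  home <- setNames(sample(config$environments, length(all_otus),
                          replace = TRUE), all_otus)
  environment <- rep("", N)
  for (i in seq_len(N)) {
    if (source[i] != "metagenome") next
    env <- if (!is.na(true_otu[i])) home[[true_otu[i]]]
           else sample(config$environments, 1)
    if (length(config$environments) > 1 && runif(1) < config$env_spread)
      env <- sample(setdiff(config$environments, env), 1)
    environment[i] <- env
  }

  meta <- data.frame(seq_id = ids, source = source, environment = environment,
                     phylum_label = ifelse(source == "genome" &
                                             !is.na(true_phylum),
                                           true_phylum, ""),
                     stringsAsFactors = FALSE)
  truth <- data.frame(seq_id = ids, true_otu = true_otu,
                      true_phylum = true_phylum,
                      is_chimera = is_chimera, chimera_parent_a = parent_a,
                      chimera_parent_b = parent_b,
                      chimera_breakpoint = breakpoint,
                      is_truncated = is_truncated, is_gappy = is_gappy,
                      is_rogue = is_rogue,
                      source = source, environment = environment,
                      stringsAsFactors = FALSE)

  outgroup <- NULL
  if (config$n_outgroup > 0) {
    ## outgroup sequences share a long stem (80% of the divergence) so they
    ## form a clade and rooting on them is well-defined
    og_root <- jc_evolve(ancestor, 0.8 * config$outgroup_divergence)
    og <- lapply(seq_len(config$n_outgroup), function(i)
      jc_evolve(og_root, 0.2 * config$outgroup_divergence))
    outgroup <- do.call(rbind, og)
    rownames(outgroup) <- sprintf("outgroup%02d", seq_len(config$n_outgroup))
  }

  structure(list(aln = aln, meta = meta, truth = truth, guide_trees = trees,
                 outgroup = outgroup, config = config),
            class = "ssu_sim")
}

#' @export
print.ssu_sim <- function(x, ...) {
  cat(sprintf("<ssu_sim: %d sequences x %d columns; %d phyla, %d true OTUs>\n",
              nrow(x$aln), ncol(x$aln), x$config$n_phyla,
              length(unique(stats::na.omit(x$truth$true_otu)))))
  cat(sprintf("  planted: %d chimeras, %d truncated, %d gappy, %d rogues\n",
              sum(x$truth$is_chimera), sum(x$truth$is_truncated),
              sum(x$truth$is_gappy), sum(x$truth$is_rogue)))
  invisible(x)
}

#' Write a synthetic dataset to disk as plain-text files
#'
#' Emits aligned FASTA, metadata TSV, truth TSV and guide trees as Newick.
#'
#' @param sim an `ssu_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$aln, file.path(dir, "sequences.fasta"))
  if (!is.null(sim$outgroup))
    write_alignment(sim$outgroup, file.path(dir, "outgroup.fasta"))
  write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  multi <- vapply(sim$guide_trees, function(t) nrow(t$edge) > 0, logical(1))
  if (any(multi))
    ape::write.tree(do.call(c, unname(sim$guide_trees[multi])),
                    file.path(dir, "guide_trees.nwk"))
  invisible(dir)
}
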