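## Census statistics: phylogenetic diversity (Faith-style branch-length
## sums), PD increase contributed by metagenome-only OTUs, per-phylum
## richness tables and per-environment tallies.

#' Phylogenetic diversity: sum of all branch lengths
#'
#' @param tree `phylo` with branch lengths (pendant and internal branches
#'   all count; a single-leaf or empty tree has PD 0).
#' @return branch-length sum in substitutions/site.
#' @export
phylogenetic_diversity <- function(tree) {
  if (is.null(tree$edge) || nrow(tree$edge) == 0) return(0)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  sum(tree$edge.length)
}

#' Percentage increase in phylogenetic diversity
#'
#' @param pd_known PD of the tree restricted to previously known OTUs.
#' @param pd_all PD of the tree over all OTUs.
#' @return `100 * (pd_all - pd_known) / pd_known`.
#' @export
pd_increase_percent <- function(pd_known, pd_all) {
  if (any(pd_known <= 0)) stop("pd_known must be positive")
  100 * (pd_all - pd_known) / pd_known
}

#' Per-phylum increase in phylogenetic diversity from metagenome-only OTUs
#'
#' For each phylum two NJ trees are built from 97% OTU representatives: one
#' from the OTUs not exclusively found in metagenomic data (novelty other
#' than `mg_only`), and one from all OTUs.  The PD increase is
#' `100 * (pd_all - pd_known) / pd_known`.  Phyla with fewer than
#' `min_known` non-metagenome-only OTUs are skipped, and at least 3
#' representatives are required on each side to build a tree.
#'
#' @param aln alignment matrix holding the OTU representative sequences.
#' @param otus OTU table with columns `otu_id`, `centroid_id`, `novelty`.
#' @param phylum_of named character vector: otu_id -> phylum.
#' @param window an [internal_window()].
#' @param min_known minimum number of non-mg_only OTUs for a phylum to be
#'   reported.
#' @return data frame: phylum, n_known, n_all, pd_known, pd_all,
#'   pd_increase_percent.
#' @export
pd_increase <- function(aln, otus, phylum_of, window, min_known = 5) {
  otus$phylum <- unname(phylum_of[otus$otu_id])
  otus <- otus[!is.na(otus$phylum), , drop = FALSE]
  out <- list()
  for (ph in sort(unique(otus$phylum))) {
    sub <- otus[otus$phylum == ph, , drop = FALSE]
    known <- sub$centroid_id[sub$novelty != "mg_only"]
    all_reps <- sub$centroid_id
    if (length(known) < min_known) next
    if (length(known) < 3 || length(all_reps) < 3) next
    pdk <- phylogenetic_diversity(build_nj_tree(aln[known, , drop = FALSE],
                                                window))
    pda <- phylogenetic_diversity(build_nj_tree(aln[all_reps, , drop = FALSE],
                                                window))
    inc <- if (pdk > 0) pd_increase_percent(pdk, pda) else NA_real_
    out[[ph]] <- data.frame(phylum = ph, n_known = length(known),
                            n_all = length(all_reps), pd_known = pdk,
                            pd_all = pda, pd_increase_percent = inc,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(phylum = character(0), n_known = integer(0),
                      n_all = integer(0), pd_known = numeric(0),
                      pd_all = numeric(0), pd_increase_percent = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-phylum taxonomic richness table
#'
#' Counts 97% OTUs (total and by novelty category) and 85% clusters per
#' phylum.  A cluster is counted under every phylum its member OTUs map to
#' only once (distinct cluster ids per phylum).
#'
#' @param otus OTU table with columns `otu_id`, `cluster_id`, `novelty`.
#' @param phylum_of named character vector: otu_id -> phylum (NA allowed;
#'   such OTUs are tallied under `"unassigned"`).
#' @return data frame with one row per phylum plus novelty-category columns.
#' @export
richness_table <- function(otus, phylum_of) {
  ph <- unname(phylum_of[otus$otu_id])
  ph[is.na(ph)] <- "unassigned"
  cats <- c("mg_only", "mg_and_silva", "genome_backed")
  rows <- lapply(sort(unique(ph)), function(p) {
    sub <- otus[ph == p, , drop = FALSE]
    cnt <- vapply(cats, function(cc) sum(sub$novelty == cc), integer(1))
    data.frame(phylum = p, n_otu97 = nrow(sub),
               n_mg_only = cnt[["mg_only"]],
               n_mg_and_silva = cnt[["mg_and_silva"]],
               n_genome_backed = cnt[["genome_backed"]],
               n_cluster85 = length(unique(stats::na.omit(sub$cluster_id))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-environment, per-novelty-category OTU tally
#'
#' An OTU contributes at most one count to each environment in which at
#' least one member sequence occurs, regardless of how many members were
#' sampled there.  Sequences with an empty environment label count under
#' `"unknown"`.  Environments listed in `drop_environments` (e.g.
#' `"engineered"`) are excluded.
#'
#' @param membership data frame `seq_id`, `otu_id` (from
#'   [two_level_cluster()]).
#' @param meta metadata data frame with `seq_id` and `environment`.
#' @param otus OTU table with `otu_id` and `novelty`.
#' @param drop_environments environment labels to exclude.
#' @return data frame: environment, novelty, n_otus.
#' @export
environment_tally <- function(membership, meta, otus,
                              drop_environments = NULL) {
  if (!nrow(otus))
    return(data.frame(environment = character(0), novelty = character(0),
                      n_otus = integer(0)))
  env <- setNames(meta$environment, meta$seq_id)
  nov <- setNames(otus$novelty, otus$otu_id)
  df <- data.frame(otu_id = membership$otu_id,
                   environment = unname(env[membership$seq_id]),
                   stringsAsFactors = FALSE)
  df$environment[is.na(df$environment) | !nzchar(df$environment)] <- "unknown"
  df <- df[!(df$environment %in% drop_environments), , drop = FALSE]
  df <- df[df$otu_id %in% names(nov), , drop = FALSE]
  df <- unique(df)                      # max one count per OTU and environment
  df$novelty <- unname(nov[df$otu_id])
  agg <- stats::aggregate(list(n_otus = df$otu_id),
                          by = list(environment = df$environment,
                                    novelty = df$novelty),
                          FUN = length)
  agg[order(agg$environment, agg$novelty), , drop = FALSE]
}
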