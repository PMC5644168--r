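## End-to-end census pipeline: QC -> two-level clustering -> novelty ->
## chimera screen -> bootstrap NJ tree with rogue removal -> rooting,
## phylum assignment and census tables.

#' Run the full SSU rRNA census pipeline
#'
#' Input sequences are split by source: metagenome and genome sequences form
#' the pipeline set, `reference_db` sequences play the role of the amplicon
#' reference database (used for novelty categorisation only, never counted
#' towards cluster sizes).  After length and window-gap QC, sequences are
#' clustered at `t1`/`t2` with [two_level_cluster()], OTU novelty is
#' assigned with [categorize_novelty()], and 85%-cluster representatives are
#' screened for chimeras against the genome-source sequences with
#' [screen_chimeras()].  Surviving representatives (plus outgroup sequences,
#' when given) enter bootstrap NJ tree building with iterative rogue-taxon
#' removal; the final tree is rebuilt on the surviving leaf set, rooted on
#' the outgroup, annotated with bootstrap supports, and clusters are
#' assigned to phyla by supported monophyly against leaves whose clusters
#' carry a known `phylum_label` (e.g. from genome taxonomy).  Census tables
#' (richness, PD increase, environment tally, primer report) are computed
#' last.
#'
#' @param aln alignment matrix (all sources).
#' @param meta metadata data frame: seq_id, source, environment,
#'   phylum_label.
#' @param outgroup optional alignment matrix of outgroup sequences.
#' @param window_width,window_start internal window selection (see
#'   [select_internal_window()]).
#' @param min_len,max_gaps QC thresholds.
#' @param t1,t2 clustering thresholds in percent.
#' @param bootstrap_n number of bootstrap replicates.
#' @param seed RNG seed for bootstrap resampling.
#' @param rogue_stop stop rogue removal when a round finds fewer rogues.
#' @param support_min minimum percent support for phylum assignment.
#' @param primers primer pair for the mismatch report ([emp_primers()] by
#'   default); NULL skips the report.
#' @param chimera_args list of overrides for [screen_chimeras()] parameters.
#' @param drop_environments environment labels excluded from the tally.
#' @return object of class `ssu_census`: list with qc, window, tlc (the
#'   clustering), otus (with novelty), chimera verdicts, tree, assignments,
#'   and the census tables.
#' @export
run_census <- function(aln, meta, outgroup = NULL,
                       window_width = 900, window_start = NULL,
                       min_len = 1200, max_gaps = 40,
                       t1 = 97, t2 = 85,
                       bootstrap_n = 100, seed = 1, rogue_stop = 5,
                       support_min = 50, primers = emp_primers(),
                       chimera_args = list(),
                       drop_environments = "engineered") {
  src <- setNames(meta$source, meta$seq_id)
  pipe_ids <- meta$seq_id[meta$source %in% c("metagenome", "genome")]
  ref_ids <- meta$seq_id[meta$source == "reference_db"]

  ## ---- QC (applied identically to pipeline and reference sequences)
  lf <- filter_by_length(aln, min_len)
  window <- select_internal_window(
    lf$kept[rownames(lf$kept) %in% pipe_ids, , drop = FALSE],
    width = window_width, start = window_start)
  gf <- filter_by_gaps(lf$kept, window, max_gaps)
  qc <- list(length_discarded = lf$discarded, gap_discarded = gf$discarded)
  keep <- rownames(gf$kept)
  paln <- gf$kept[keep %in% pipe_ids, , drop = FALSE]
  raln <- gf$kept[keep %in% ref_ids, , drop = FALSE]

  ## ---- clustering and novelty
  tlc <- two_level_cluster(paln, window, t1 = t1, t2 = t2)
  otus <- categorize_novelty(tlc, paln, raln, window, meta, t1 = t1)

  ## ---- chimera screen of 85%-cluster representatives against
  ## genome-source sequences
  rep_seq <- setNames(otus$centroid_id[match(tlc$clusters85$centroid_otu_id,
                                             otus$otu_id)],
                      tlc$clusters85$cluster_id)
  genome_aln <- paln[rownames(paln) %in% names(src)[src == "genome"], ,
                     drop = FALSE]
  chim <- do.call(screen_chimeras,
                  c(list(queries = paln[unname(rep_seq), , drop = FALSE],
                         ref_aln = genome_aln, window = window),
                    chimera_args))
  chim$cluster_id <- names(rep_seq)[match(chim$query_id, unname(rep_seq))]
  clean_clusters <- chim$cluster_id[chim$verdict != "chimeric"]

  ## ---- tree on surviving cluster representatives (+ outgroup)
  tree <- NULL; rogue <- NULL; assignments <- NULL
  tree_ids <- unname(rep_seq[clean_clusters])
  taln <- paln[tree_ids, , drop = FALSE]
  if (!is.null(outgroup)) taln <- rbind(taln, outgroup)
  if (nrow(taln) >= 5) {
    reps <- bootstrap_trees(taln, window, n = bootstrap_n, seed = seed)
    rogue <- find_and_drop_rogues(reps, stop_when_fewer_than = rogue_stop)
    taln2 <- taln[rogue$leaves, , drop = FALSE]
    tree <- build_nj_tree(taln2, window)
    reps2 <- bootstrap_trees(taln2, window, n = bootstrap_n, seed = seed + 1)
    if (!is.null(outgroup) &&
        any(rownames(outgroup) %in% rogue$leaves)) {
      og <- intersect(rownames(outgroup), rogue$leaves)
      tree <- root_with_outgroup(tree, og)
    }
    tree <- map_supports(tree, reps2)
    ## known labels: clusters whose members carry a phylum_label
    lab_of <- setNames(meta$phylum_label, meta$seq_id)
    cl_of_otu <- setNames(otus$cluster_id, otus$otu_id)
    cl_of_seq <- setNames(cl_of_otu[tlc$membership$otu_id],
                          tlc$membership$seq_id)
    leaf_labels <- vapply(rogue$leaves, function(lf_id) {
      cid <- names(rep_seq)[match(lf_id, unname(rep_seq))]
      if (is.na(cid)) return(NA_character_)
      members <- tlc$membership$seq_id[!is.na(cl_of_seq[tlc$membership$seq_id]) &
                                         cl_of_seq[tlc$membership$seq_id] == cid]
      labs <- lab_of[members]
      labs <- labs[!is.na(labs) & nzchar(labs)]
      if (!length(labs)) return(NA_character_)
      tt <- sort(table(labs), decreasing = TRUE)
      names(tt)[1]
    }, character(1))
    assignments <- assign_phyla(tree, leaf_labels, support_min = support_min)
    if (!is.null(outgroup))
      assignments <- assignments[!(assignments$leaf %in% rownames(outgroup)), ,
                                 drop = FALSE]
  }

  ## ---- census tables
  ## each OTU inherits the phylum of its cluster's leaf in the tree
  phylum_of <- rep(NA_character_, nrow(otus))
  names(phylum_of) <- otus$otu_id
  if (!is.null(assignments)) {
    leaf_phylum <- setNames(assignments$phylum, assignments$leaf)
    cl_phylum <- setNames(unname(leaf_phylum[unname(rep_seq)]),
                          names(rep_seq))
    phylum_of[] <- unname(cl_phylum[otus$cluster_id])
  }
  richness <- richness_table(otus, phylum_of)
  envtab <- environment_tally(tlc$membership, meta, otus,
                              drop_environments = drop_environments)
  pd <- pd_increase(paln, otus, phylum_of, window)
  prim <- if (!is.null(primers)) primer_report(tlc, paln, primers) else NULL

  structure(list(window = window, qc = qc, tlc = tlc, otus = otus,
                 chimera = chim, rogue = rogue, tree = tree,
                 assignments = assignments, phylum_of = phylum_of,
                 richness = richness, environment = envtab, pd = pd,
                 primer = prim),
            class = "ssu_census")
}

#' @export
print.ssu_census <- function(x, ...) {
  cat("<ssu_census>\n")
  cat(sprintf("  window: [%d, %d)\n", x$window$start,
              x$window$start + x$window$width))
  cat(sprintf("  97%% OTUs: %d (%s)\n", nrow(x$otus),
              paste(sprintf("%s %d", names(table(x$otus$novelty)),
                            table(x$otus$novelty)), collapse = ", ")))
  cat(sprintf("  85%% clusters: %d (+%d unplaced OTUs)\n",
              nrow(x$tlc$clusters85), sum(x$otus$unplaced)))
  cat(sprintf("  chimeric cluster representatives: %d\n",
              sum(x$chimera$verdict == "chimeric")))
  if (!is.null(x$tree))
    cat(sprintf("  tree: %d leaves after rogue removal (%d rogues pruned)\n",
                length(x$rogue$leaves), nrow(x$rogue$rounds)))
  if (nrow(x$pd))
    cat(sprintf("  mean PD increase: %.1f%% over %d phyla\n",
                mean(x$pd$pd_increase_percent, na.rm = TRUE), nrow(x$pd)))
  invisible(x)
}

#' Write census tables as TSV files
#'
#' @param census an `ssu_census` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_census <- function(census, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) if (!is.null(df))
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(census$tlc$membership, "otu_membership.tsv")
  wt(census$otus, "otus.tsv")
  wt(census$tlc$clusters85, "clusters85.tsv")
  wt(census$chimera, "chimera_verdicts.tsv")
  wt(census$assignments, "phylum_assignments.tsv")
  wt(census$richness, "richness.tsv")
  wt(census$environment, "environment_tally.tsv")
  wt(census$pd, "pd_increase.tsv")
  wt(census$primer, "primer_report.tsv")
  if (!is.null(census$tree))
    ape::write.tree(census$tree, file.path(dir, "census_tree.nwk"))
  invisible(dir)
}
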