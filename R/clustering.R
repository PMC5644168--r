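## Greedy centroid clustering at fixed identity thresholds over the internal
## window, the two-level 97% -> 85% scheme, and novelty categorisation by
## joint reclustering with an amplicon reference database.

#' Pairwise identity of two aligned sequences inside a window
#'
#' Identity is 100 x (columns where both sequences carry the same residue) /
#' (columns where at least one carries a residue).  Columns gapped in both
#' sequences are excluded from numerator and denominator; a residue opposite
#' a gap counts as a mismatch (it inflates the denominator only).
#'
#' @param a,b aligned sequences: single-row character vectors, strings, or
#'   names into `aln`.
#' @param window an [internal_window()]; NULL scores all columns.
#' @param aln optional alignment matrix from which `a`/`b` rows are taken.
#' @return identity percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, window = NULL, aln = NULL) {
  fetch <- function(x) {
    if (length(x) == 1 && !is.null(aln)) x <- aln[x, ]
    else if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
    match(toupper(x), c("A", "C", "G", "T"), nomatch = 0L)
  }
  ea <- fetch(a); eb <- fetch(b)
  if (length(ea) != length(eb)) stop("sequences differ in aligned length")
  if (!is.null(window)) {
    cols <- window_cols(window, length(ea))
    ea <- ea[cols]; eb <- eb[cols]
  }
  if (all(ea == 0L) || all(eb == 0L))
    stop("undefined identity: a sequence is all-gap inside the window")
  scored <- ea != 0L | eb != 0L
  100 * sum(ea == eb & ea != 0L) / sum(scored)
}

## identity of one encoded query (length w) against k encoded centroids
## stored column-major as a w x k matrix; returns a length-k percent vector
identity_to_centroids <- function(q, cent_t, k) {
  ct <- cent_t[, seq_len(k), drop = FALSE]
  eqs <- ct == q & q != 0L
  scored <- .colSums(ct != 0L | q != 0L, length(q), k)
  out <- 100 * .colSums(eqs, length(q), k) / scored
  out[scored == 0] <- -1  # no scorable columns: never joins
  out
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' Sequences are visited in order of decreasing ungapped length (ties broken
#' by ascending seq_id, C-locale).  Each sequence joins the first existing
#' centroid — in centroid-creation order — whose window identity to it is at
#' least `threshold`; otherwise it founds a new cluster with itself as
#' centroid.  The scan is fully deterministic.
#'
#' @param aln alignment matrix of QC-passed sequences.
#' @param threshold identity threshold in percent, in (0, 100].
#' @param window an [internal_window()].
#' @return data frame with columns `seq_id`, `cluster` (integer index in
#'   centroid-creation order), `centroid_id`, `is_centroid`, in input row
#'   order.
#' @export
greedy_cluster <- function(aln, threshold, window) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 100)
    stop("threshold must lie in (0, 100]")
  n <- nrow(aln)
  if (n == 0)
    return(data.frame(seq_id = character(0), cluster = integer(0),
                      centroid_id = character(0), is_centroid = logical(0)))
  cols <- window_cols(window, ncol(aln))
  len <- ungapped_length(aln)
  ids <- rownames(aln)
  ord <- order(-len, ids, method = "radix")
  enc <- encode_aln(aln[, cols, drop = FALSE])
  w <- length(cols)
  cent_t <- matrix(0L, nrow = w, ncol = n)   # encoded centroids, column-major
  cent_row <- integer(n)                      # row index of each centroid
  k <- 0L
  assign <- integer(n)
  for (r in ord) {
    q <- enc[r, ]
    hit <- 0L
    if (k > 0L) {
      idp <- identity_to_centroids(q, cent_t, k)
      ok <- which(idp >= threshold)
      if (length(ok)) hit <- ok[1L]
    }
    if (hit == 0L) {
      k <- k + 1L
      cent_t[, k] <- q
      cent_row[k] <- r
      hit <- k
    }
    assign[r] <- hit
  }
  data.frame(seq_id = ids, cluster = assign,
             centroid_id = ids[cent_row[assign]],
             is_centroid = ids == ids[cent_row[assign]],
             stringsAsFactors = FALSE)
}

#' Two-level 97% / 85% clustering with linkage and singleton removal
#'
#' All sequences are clustered at `t1` (97%) identity into OTUs; the OTU
#' centroids are then clustered at `t2` (85%) identity into coarse
#' (order-level) clusters, linking every OTU to exactly one cluster.
#' Coarse clusters whose total underlying sequence count is 1 (or, with
#' `singleton_unit = "otu"`, which contain a single OTU) are removed; their
#' OTUs are flagged unplaced (`cluster_id = NA`).
#'
#' @param aln alignment matrix of QC-passed sequences.
#' @param window an [internal_window()].
#' @param t1,t2 identity thresholds in percent for the two levels.
#' @param singleton_unit what counts as "one single sequence" when removing
#'   singleton coarse clusters: one underlying sequence (default) or one OTU.
#' @return list with `membership` (seq_id, otu_id, centroid flag), `otus`
#'   (otu_id, centroid_id, n_members, cluster_id, unplaced) and `clusters85`
#'   (cluster_id, centroid_otu_id, n_otus, n_seqs).
#' @export
two_level_cluster <- function(aln, window, t1 = 97, t2 = 85,
                              singleton_unit = c("sequence", "otu")) {
  singleton_unit <- match.arg(singleton_unit)
  lv1 <- greedy_cluster(aln, t1, window)
  otu_id <- sprintf("OTU%04d", lv1$cluster)
  membership <- data.frame(seq_id = lv1$seq_id, otu_id = otu_id,
                           is_centroid = lv1$is_centroid,
                           stringsAsFactors = FALSE)
  cent <- unique(data.frame(otu_id = otu_id, centroid_id = lv1$centroid_id,
                            stringsAsFactors = FALSE))
  cent <- cent[order(cent$otu_id), , drop = FALSE]
  n_members <- as.vector(table(otu_id)[cent$otu_id])

  lv2 <- greedy_cluster(aln[cent$centroid_id, , drop = FALSE], t2, window)
  # lv2 rows follow cent order (rownames preserved by subsetting)
  cl_id <- sprintf("CL%03d", lv2$cluster)
  otus <- data.frame(otu_id = cent$otu_id, centroid_id = cent$centroid_id,
                     n_members = n_members, cluster_id = cl_id,
                     stringsAsFactors = FALSE)
  n_seqs <- tapply(otus$n_members, otus$cluster_id, sum)
  n_otus <- tapply(otus$otu_id, otus$cluster_id, length)
  cl_cent <- tapply(seq_len(nrow(lv2)), cl_id, function(i)
    cent$otu_id[i[lv2$is_centroid[i]][1]])
  clusters85 <- data.frame(cluster_id = names(n_seqs),
                           centroid_otu_id = as.character(cl_cent[names(n_seqs)]),
                           n_otus = as.integer(n_otus[names(n_seqs)]),
                           n_seqs = as.integer(n_seqs),
                           stringsAsFactors = FALSE)
  single <- if (singleton_unit == "sequence") clusters85$n_seqs == 1L
            else clusters85$n_otus == 1L
  dropped <- clusters85$cluster_id[single]
  otus$unplaced <- otus$cluster_id %in% dropped
  otus$cluster_id[otus$unplaced] <- NA_character_
  clusters85 <- clusters85[!single, , drop = FALSE]
  rownames(clusters85) <- NULL
  list(membership = membership, otus = otus, clusters85 = clusters85)
}

#' Categorize OTU novelty against an amplicon reference database
#'
#' Pipeline and reference sequences (QC-filtered to the same coordinates) are
#' jointly reclustered at `t1` identity.  An OTU whose representative
#' (centroid) lands in a joint cluster containing at least one reference
#' sequence is categorized `mg_and_silva`; an OTU containing any genome-source
#' member is `genome_backed` (which takes precedence); all others are
#' `mg_only`.  Joint clusters consisting solely of reference sequences are
#' discarded and counted (attribute `reference_only_clusters`).
#'
#' @param tlc result of [two_level_cluster()].
#' @param aln alignment matrix of the pipeline sequences.
#' @param ref_aln alignment matrix of reference sequences (same coordinates).
#' @param window an [internal_window()].
#' @param meta pipeline metadata data frame (`seq_id`, `source`).
#' @param t1 identity threshold of the joint clustering, in percent.
#' @param match_by match OTUs to joint clusters by their representative
#'   sequence (default) or by any member sequence.
#' @return the `otus` data frame of `tlc` with a `novelty` column, carrying
#'   attribute `reference_only_clusters`.
#' @export
categorize_novelty <- function(tlc, aln, ref_aln, window, meta, t1 = 97,
                               match_by = c("representative", "any_member")) {
  match_by <- match.arg(match_by)
  if (ncol(ref_aln) != ncol(aln))
    stop("reference alignment coordinates differ from pipeline alignment")
  otus <- tlc$otus
  src <- setNames(meta$source, meta$seq_id)
  by_otu <- split(tlc$membership$seq_id, tlc$membership$otu_id)
  genome_backed <- vapply(by_otu[otus$otu_id], function(m)
    any(src[m] == "genome", na.rm = TRUE), logical(1))

  joint <- rbind(aln, ref_aln)
  jc <- greedy_cluster(joint, t1, window)
  is_ref <- jc$seq_id %in% rownames(ref_aln)
  ref_clusters <- unique(jc$cluster[is_ref])
  pipe_clusters <- unique(jc$cluster[!is_ref])
  ref_only <- setdiff(ref_clusters, pipe_clusters)

  jmap <- setNames(jc$cluster, jc$seq_id)
  has_ref <- if (match_by == "representative") {
    vapply(otus$centroid_id, function(s) jmap[[s]] %in% ref_clusters,
           logical(1))
  } else {
    vapply(by_otu[otus$otu_id], function(m)
      any(jmap[m] %in% ref_clusters), logical(1))
  }
  otus$novelty <- ifelse(genome_backed, "genome_backed",
                         ifelse(has_ref, "mg_and_silva", "mg_only"))
  attr(otus, "reference_only_clusters") <- length(ref_only)
  otus
}
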