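## Tree building and bootstrap machinery: Jukes-Cantor-corrected
## neighbor-joining trees, majority-rule consensus with bipartition supports,
## iterative rogue-taxon removal, outgroup rooting, long-branch screening and
## monophyly-based phylum assignment.

## Jukes-Cantor distance matrix from window identities.  p is capped at
## P_CAP with a warning (the JC correction diverges at p = 0.75).
P_CAP <- 0.70

jc_distance_matrix <- function(aln, window) {
  cols <- window_cols(window, ncol(aln))
  E <- encode_aln(aln[, cols, drop = FALSE])
  n <- nrow(E)
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    M <- E == b
    storage.mode(M) <- "numeric"
    matches <- matches + tcrossprod(M)
  }
  nongap <- E != 0L
  storage.mode(nongap) <- "numeric"
  both <- tcrossprod(nongap)
  nres <- rowSums(nongap)
  scored <- outer(nres, nres, "+") - both
  if (any(scored == 0))
    stop("sequence pair with no scorable columns in window")
  p <- 1 - matches / scored
  if (any(p > P_CAP)) {
    warning("saturated distances: ", sum(p > P_CAP & upper.tri(p)),
            " pair(s) with p > ", P_CAP, " capped")
    p[p > P_CAP] <- P_CAP
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(aln)
  d
}

## clamp negative NJ branch lengths to zero, moving the deficit to a sibling
## branch (first other edge sharing the parent node); a final pass clamps any
## remaining negatives
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  for (i in which(el < 0)) {
    deficit <- el[i]
    sib <- which(tree$edge[, 1] == tree$edge[i, 1])
    sib <- sib[sib != i]
    if (length(sib)) el[sib[1]] <- el[sib[1]] + deficit
    el[i] <- 0
  }
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Build a neighbor-joining tree from aligned sequences
#'
#' Pairwise window identities (definition of [pairwise_identity()]) are
#' converted to Jukes-Cantor distances `d = -(3/4) ln(1 - (4/3) p)` with the
#' mismatch proportion `p` capped at 0.70 (saturation warning), and a
#' neighbor-joining tree is computed.  Negative NJ branch lengths are clamped
#' to zero with the deficit moved to a sibling branch.
#'
#' @param aln alignment matrix (at least 3 sequences).
#' @param window an [internal_window()].
#' @return unrooted `phylo` tree, leaves keyed by sequence id.
#' @export
build_nj_tree <- function(aln, window) {
  if (nrow(aln) < 3) stop("need at least 3 sequences for a tree")
  nj_from_distances(jc_distance_matrix(aln, window))
}

#' Neighbor-joining tree from a distance matrix
#'
#' The tree-building engine behind [build_nj_tree()], usable with any
#' distance matrix: neighbor joining followed by clamping of negative branch
#' lengths (deficits moved to a sibling branch).
#'
#' @param d symmetric distance matrix with at least 3 labeled taxa.
#' @return unrooted `phylo` tree.
#' @export
nj_from_distances <- function(d) {
  if (nrow(d) < 3) stop("need at least 3 taxa")
  clamp_negative_edges(ape::nj(d))
}

#' Bootstrap replicate trees by resampling window columns
#'
#' Each replicate resamples the window columns with replacement and rebuilds
#' the NJ tree on the resampled alignment.
#'
#' @param aln alignment matrix.
#' @param window an [internal_window()].
#' @param n number of replicates.
#' @param seed RNG seed (replicates are deterministic under a fixed seed).
#' @return list of `phylo` trees (empty when `n = 0`).
#' @export
bootstrap_trees <- function(aln, window, n = 100, seed = 1) {
  set.seed(seed)
  if (n == 0) return(list())
  cols <- window_cols(window, ncol(aln))
  waln <- aln[, cols, drop = FALSE]
  w <- length(cols)
  full <- internal_window(0, w)
  lapply(seq_len(n), function(i) {
    build_nj_tree(waln[, sample.int(w, w, replace = TRUE), drop = FALSE], full)
  })
}

## --- bipartition machinery -------------------------------------------------
## canonical form of a split: the side NOT containing the lexicographically
## smallest leaf, as a sorted comma-joined label string

split_keys <- function(tree, anchor) {
  labs <- tree$tip.label
  L <- length(labs)
  pp <- ape::prop.part(tree)
  plabs <- attr(pp, "labels")
  keys <- character(0)
  for (part in pp) {
    side <- plabs[part]
    if (anchor %in% side) side <- setdiff(plabs, side)
    k <- length(side)
    if (k < 2 || k > L - 2) next
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

## tally canonical splits across trees (same leaf set assumed)
count_splits <- function(trees) {
  anchor <- min(trees[[1]]$tip.label)
  tab <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    for (k in split_keys(tr, anchor)) {
      tab[[k]] <- (if (is.null(tab[[k]])) 0L else tab[[k]]) + 1L
    }
  }
  counts <- unlist(as.list(tab))
  if (is.null(counts)) counts <- integer(0)
  counts
}

## number of splits present in strictly more than half of the trees
n_resolved_splits <- function(trees) {
  counts <- count_splits(trees)
  sum(counts > length(trees) / 2)
}

## support-sum score of the majority consensus: the sum, over all splits
## with strict-majority support, of their support fractions.  Pruning an
## unstable leaf concentrates support on the remaining splits and raises
## this score; pruning a stable leaf merely removes one fully supported
## split and lowers it.
consensus_support_score <- function(trees) {
  counts <- count_splits(trees)
  R <- length(trees)
  sum(counts[counts > R / 2]) / R
}

#' Majority-rule consensus with bipartition supports
#'
#' Returns the strict-majority (> 50%) consensus of a set of replicate trees
#' on a common leaf set; retained internal edges carry the percentage of
#' replicates containing the bipartition as node labels.
#'
#' @param trees list of `phylo` trees on the same leaf set.
#' @return unrooted consensus `phylo` with supports in `node.label`.
#' @export
majority_consensus <- function(trees) {
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(sets, paste, character(1), collapse = ","))) != 1)
    stop("trees have mismatched leaf sets")
  counts <- count_splits(trees)
  R <- length(trees)
  keep <- counts[counts > R / 2]
  cons <- build_tree_from_splits(sort(sets[[1]]), names(keep))
  attach_supports(cons, 100 * keep / R)
}

## construct an unrooted topology from a laminar family of canonical splits
build_tree_from_splits <- function(labs, keys) {
  anchor <- labs[1]
  rest <- setdiff(labs, anchor)
  sides <- lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  ## laminar nesting: attach each split (by decreasing size) as a clade
  ## under its smallest strict superset, or under the root
  sides <- sides[order(-vapply(sides, length, integer(1)))]
  n <- length(sides)
  parent <- rep(0L, n)
  if (n > 1) {
    for (i in 2:n) {
      for (j in (i - 1):1) {
        if (all(sides[[i]] %in% sides[[j]])) { parent[i] <- j; break }
      }
    }
  }
  node_newick <- function(i) {
    members <- if (i == 0) rest else sides[[i]]
    kids <- which(parent == i)
    covered <- unlist(sides[kids])
    free <- setdiff(members, covered)
    parts <- c(vapply(kids, function(k2) paste0("(", node_newick(k2), ")"),
                      character(1)),
               sort(free))
    paste(parts, collapse = ",")
  }
  txt <- paste0("(", anchor, ",", node_newick(0L), ");")
  tr <- ape::read.tree(text = txt)
  ape::unroot(tr)
}

## attach percent supports (named by canonical split key) as node labels
attach_supports <- function(tree, support_by_key) {
  anchor <- min(tree$tip.label)
  labs <- tree$tip.label
  L <- length(labs)
  pp <- ape::prop.part(tree)
  plabs <- attr(pp, "labels")
  node.label <- rep("", tree$Nnode)
  for (i in seq_along(pp)) {
    side <- plabs[pp[[i]]]
    if (anchor %in% side) side <- setdiff(plabs, side)
    k <- length(side)
    if (k < 2 || k > L - 2) next
    key <- paste(sort(side), collapse = ",")
    if (!is.na(support_by_key[key]))
      node.label[i] <- format(round(unname(support_by_key[key]), 1))
  }
  tree$node.label <- node.label
  tree
}

#' Map bootstrap supports from replicate trees onto a reference tree
#'
#' Each internal edge of `tree` receives, as a node label, the percentage of
#' replicate trees containing its bipartition.
#'
#' @param tree reference `phylo` (rooted or unrooted).
#' @param trees list of replicate trees on the same leaf set.
#' @return `tree` with numeric percent supports in `node.label`.
#' @export
map_supports <- function(tree, trees) {
  counts <- count_splits(trees)
  attach_supports(tree, 100 * counts / length(trees))
}

#' Identify and iteratively remove rogue taxa from bootstrap replicates
#'
#' Per round, for each leaf `t` the improvement is the consensus support
#' score — the sum of support fractions over all strict-majority
#' bipartitions — of the replicate set with `t` pruned, minus the same score
#' for the full replicates.  Pruning a rogue (a leaf whose position varies
#' across replicates) re-concentrates split support and raises the score;
#' pruning a stable leaf removes one well-supported split and lowers it, so
#' stable trees yield no rogues.  All leaves with positive improvement are
#' the round's rogues; they are pruned and the procedure repeats, stopping
#' when a round identifies fewer than `stop_when_fewer_than` rogues (those
#' last rogues are still pruned) or `max_rounds` is reached.  Pruning never
#' proceeds below 4 leaves.
#'
#' @param trees list of replicate trees on a common leaf set (>= 5 leaves).
#' @param max_rounds maximum number of pruning rounds.
#' @param stop_when_fewer_than stop once a round finds fewer rogues than this.
#' @return list with `leaves` (surviving leaf ids), `rounds` (data frame:
#'   round, rogue_id, improvement), `support_score` (consensus support score
#'   after each round, round 0 first), `resolved` (strict-majority split
#'   count, same rounds) and `trees` (pruned replicates).
#' @export
find_and_drop_rogues <- function(trees, max_rounds = 10,
                                 stop_when_fewer_than = 5) {
  if (length(trees) < 2) stop("need at least 2 replicate trees")
  leaves <- trees[[1]]$tip.label
  if (length(leaves) < 5) stop("need at least 5 leaves")
  rounds <- data.frame(round = integer(0), rogue_id = character(0),
                       improvement = numeric(0), stringsAsFactors = FALSE)
  support_score <- consensus_support_score(trees)
  resolved <- n_resolved_splits(trees)
  round <- 0L
  repeat {
    round <- round + 1L
    base <- consensus_support_score(trees)
    improvement <- vapply(leaves, function(t) {
      pruned <- lapply(trees, ape::drop.tip, t)
      consensus_support_score(pruned) - base
    }, numeric(1))
    rogues <- leaves[improvement > 1e-9]
    if (length(rogues)) {
      if (length(leaves) - length(rogues) < 4) {
        warning("pruning would leave fewer than 4 leaves; stopping")
        break
      }
      rounds <- rbind(rounds, data.frame(round = round, rogue_id = rogues,
                                         improvement = improvement[rogues],
                                         stringsAsFactors = FALSE))
      trees <- lapply(trees, ape::drop.tip, rogues)
      leaves <- trees[[1]]$tip.label
      support_score <- c(support_score, consensus_support_score(trees))
      resolved <- c(resolved, n_resolved_splits(trees))
    }
    if (length(rogues) < stop_when_fewer_than || round >= max_rounds) break
  }
  list(leaves = leaves, rounds = rounds, support_score = support_score,
       resolved = resolved, trees = trees)
}

#' Root a tree with an outgroup
#'
#' The root is placed on the edge separating the smallest clade containing
#' all outgroup leaves from the rest.  When the outgroup is not monophyletic
#' in the unrooted tree, the root goes on the edge maximizing outgroup-side
#' purity (Jaccard overlap between the edge's leaf side and the outgroup
#' set), with a warning.
#'
#' @param tree unrooted `phylo`.
#' @param outgroup_ids leaf ids of the outgroup (all must be present).
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  if (!length(outgroup_ids)) stop("outgroup_ids must be non-empty")
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing)) stop("outgroup id absent from tree: ", missing[1])
  if (setequal(outgroup_ids, tree$tip.label))
    stop("outgroup cannot contain all leaves")
  if (length(outgroup_ids) == 1 ||
      ape::is.monophyletic(tree, outgroup_ids))
    return(ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE))
  warning("outgroup is not monophyletic; rooting on the maximum-purity edge")
  pp <- ape::prop.part(tree)
  plabs <- attr(pp, "labels")
  best <- NULL; best_score <- -1
  ntip <- length(tree$tip.label)
  for (node in seq_along(pp)) {
    side <- plabs[pp[[node]]]
    for (S in list(side, setdiff(plabs, side))) {
      sc <- length(intersect(S, outgroup_ids)) / length(union(S, outgroup_ids))
      if (sc > best_score) { best_score <- sc; best <- node + ntip }
    }
  }
  ape::root(tree, node = best, resolve.root = TRUE)
}

#' Flag leaves on abnormally long pendant branches
#'
#' Flags leaves whose pendant branch exceeds `multiplier` times the median
#' pendant branch length.  Flags are advisory; removal is the caller's
#' choice.
#'
#' @param tree `phylo` with branch lengths.
#' @param multiplier length multiplier over the median pendant branch.
#' @return character vector of flagged leaf ids.
#' @export
flag_long_branches <- function(tree, multiplier = 10) {
  ntip <- length(tree$tip.label)
  pend <- tree$edge[, 2] <= ntip
  len <- tree$edge.length[pend]
  tips <- tree$tip.label[tree$edge[pend, 2]]
  med <- stats::median(len)
  tips[len > multiplier * med]
}

#' Assign phyla to unlabeled leaves by supported monophyly
#'
#' For each unlabeled leaf the walk proceeds towards the root until the
#' smallest clade containing at least one labeled leaf; the leaf receives
#' that clade's phylum iff all labeled leaves inside agree on a single
#' phylum and the clade's bootstrap support is at least `support_min`
#' (missing support fails).
#'
#' @param tree rooted `phylo` with percent supports in `node.label`.
#' @param labels named character vector: leaf id -> known phylum (partial).
#' @param support_min minimum percent support of the assigning clade.
#' @return data frame with `leaf`, `phylum` (NA when unassigned) and `basis`
#'   (`"labeled"`, `"assigned"` or `"unassigned"`).
#' @export
assign_phyla <- function(tree, labels, support_min = 50) {
  labels <- labels[!is.na(labels) & nzchar(labels)]
  tips <- tree$tip.label
  if (!length(labels)) {
    warning("no labeled leaves; all leaves unassigned")
    return(data.frame(leaf = tips, phylum = NA_character_,
                      basis = "unassigned", stringsAsFactors = FALSE))
  }
  ntip <- length(tips)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  desc <- phangorn::Descendants(tree, (ntip + 1):(ntip + tree$Nnode), "tips")
  out <- data.frame(leaf = tips, phylum = NA_character_, basis = "unassigned",
                    stringsAsFactors = FALSE)
  for (i in seq_len(ntip)) {
    id <- tips[i]
    if (id %in% names(labels)) {
      out$phylum[i] <- labels[[id]]
      out$basis[i] <- "labeled"
      next
    }
    node <- parent[i]
    while (node != 0) {
      dt <- tips[desc[[node - ntip]]]
      lab_in <- labels[intersect(dt, names(labels))]
      if (length(lab_in)) {
        s <- if (length(sup)) sup[node - ntip] else NA_real_
        if (length(unique(lab_in)) == 1 && !is.na(s) && s >= support_min) {
          out$phylum[i] <- unique(lab_in)
          out$basis[i] <- "assigned"
        }
        break
      }
      node <- parent[node]
    }
  }
  out
}
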