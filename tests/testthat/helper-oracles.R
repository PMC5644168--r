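## Independent reference implementations ("oracles") and fixture builders.
## Each oracle re-implements the stated definition naively, sharing no code
## with the package internals it checks.

BASES4 <- c("A", "C", "G", "T")

## random gap-free alignment matrix
rand_aln <- function(n, w, ids = sprintf("s%03d", seq_len(n))) {
  m <- matrix(sample(BASES4, n * w, replace = TRUE), nrow = n)
  rownames(m) <- ids
  m
}

## mutate `k` random columns of one row away from their current base
mutate_row <- function(row, k) {
  idx <- sample(length(row), k)
  row[idx] <- vapply(row[idx], function(b) sample(setdiff(BASES4, b), 1), "")
  row
}

## naive window identity straight from the definition (character level)
naive_identity <- function(a, b, from, width) {
  cols <- from + seq_len(width)          # from is 0-based
  a <- a[cols]; b <- b[cols]
  scored <- !(a == "-" & b == "-")
  100 * sum(a == b & a != "-" & scored) / sum(scored)
}

## naive greedy centroid clustering: explicit double loop over the scan rule
naive_greedy <- function(aln, threshold, from, width) {
  len <- rowSums(aln != "-")
  ord <- order(-len, rownames(aln), method = "radix")
  centroids <- integer(0)
  assign <- integer(nrow(aln))
  for (r in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      idp <- naive_identity(aln[r, ], aln[centroids[ci], ], from, width)
      if (idp >= threshold) { assign[r] <- ci; placed <- TRUE; break }
    }
    if (!placed) {
      centroids <- c(centroids, r)
      assign[r] <- length(centroids)
    }
  }
  list(assign = assign, centroid_id = rownames(aln)[centroids[assign]])
}

## does an unrooted tree contain the split separating `side`?
tree_has_split <- function(tree, side) {
  others <- setdiff(tree$tip.label, side)
  if (length(side) < 2 || length(others) < 2) return(TRUE)
  rooted <- ape::root(tree, outgroup = others[1], resolve.root = TRUE)
  mrca <- ape::getMRCA(rooted, side)
  tips <- rooted$tip.label[phangorn::Descendants(rooted, mrca, "tips")[[1]]]
  setequal(tips, side)
}

## brute-force split support: fraction of trees containing each non-trivial
## split, enumerated over all subsets of the leaf set
brute_split_supports <- function(trees) {
  labs <- sort(trees[[1]]$tip.label)
  L <- length(labs)
  anchor <- labs[1]
  res <- list()
  for (sz in 2:(L - 2)) {
    for (ss in utils::combn(setdiff(labs, anchor), sz, simplify = FALSE)) {
      cnt <- sum(vapply(trees, tree_has_split, logical(1), side = ss))
      if (cnt > 0) res[[paste(sort(ss), collapse = ",")]] <- cnt
    }
  }
  res
}

## naive chimera scan: all ordered parent pairs, all breakpoints (stride 1),
## model identity by direct column counting
naive_chimera_best <- function(q, parents, from, width) {
  cols <- from + seq_len(width)
  qc <- q[cols]
  best <- list(id = -Inf)
  for (pa in names(parents)) for (pb in names(parents)) {
    if (pa == pb) next
    ac <- parents[[pa]][cols]; bc <- parents[[pb]][cols]
    for (b in 0:width) {
      left <- seq_len(b); right <- setdiff(seq_len(width), left)
      num <- den <- 0
      for (i in left) {
        if (!(qc[i] == "-" && ac[i] == "-")) {
          den <- den + 1
          if (qc[i] == ac[i] && qc[i] != "-") num <- num + 1
        }
      }
      for (i in right) {
        if (!(qc[i] == "-" && bc[i] == "-")) {
          den <- den + 1
          if (qc[i] == bc[i] && qc[i] != "-") num <- num + 1
        }
      }
      idm <- if (den > 0) 100 * num / den else -Inf
      if (idm > best$id) best <- list(id = idm, bp = b, pa = pa, pb = pb)
    }
  }
  best
}

## --- primer scoring oracle -------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

expand_degenerate <- function(seq) {
  sets <- IUPAC_SETS[strsplit(seq, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

revcomp_plain <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## plain-R fit alignment of a concrete (non-degenerate) primer minimizing
## the weighted mismatch score; returns that score
r_fit_score <- function(primer, target, in3, w_mmN, w_mm3, w_gapN, w_gap3) {
  p <- strsplit(primer, "")[[1]]; t <- strsplit(target, "")[[1]]
  m <- length(p); n <- length(t)
  if (n < m) return(Inf)
  W <- matrix(0, m + 1, n + 1)
  for (i in 2:(m + 1))
    W[i, 1] <- W[i - 1, 1] + if (in3[i - 1]) w_gap3 else w_gapN
  for (i in 2:(m + 1)) {
    mmw <- if (in3[i - 1]) w_mm3 else w_mmN
    gpw <- if (in3[i - 1]) w_gap3 else w_gapN
    for (j in 2:(n + 1)) {
      w <- W[i - 1, j - 1] + if (p[i - 1] == t[j - 1]) 0 else mmw
      w <- min(w, W[i - 1, j] + gpw, W[i, j - 1] + gpw)
      W[i, j] <- w
    }
  }
  min(W[m + 1, ])
}

## oracle for primer_weighted_score: minimum over the full degenerate
## expansion, each variant scored by the plain-R DP
oracle_primer_score <- function(seq, primer) {
  seq <- gsub("-", "", toupper(seq), fixed = TRUE)
  pseq <- primer$sequence
  in3 <- rev(seq_len(nchar(pseq))) <= primer$three_prime_window
  if (primer$direction == "reverse") in3 <- rev(in3)
  variants <- expand_degenerate(pseq)
  if (primer$direction == "reverse")
    variants <- vapply(variants, revcomp_plain, "")
  w <- primer$weights
  min(vapply(variants, r_fit_score, numeric(1), target = seq, in3 = in3,
             w_mmN = w[["non3_mismatch"]], w_mm3 = w[["three_prime_mismatch"]],
             w_gapN = w[["non3_gap"]], w_gap3 = w[["three_prime_gap"]]))
}

## regraft one leaf at a uniformly random position of a tree
regraft_leaf <- function(tree, leaf) {
  backbone <- ape::drop.tip(tree, leaf)
  edge <- sample(nrow(backbone$edge), 1)
  node <- backbone$edge[edge, 2]
  pos <- runif(1) * backbone$edge.length[edge]
  phytools::bind.tip(backbone, leaf, edge.length = 0.3, where = node,
                     position = pos)
}
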