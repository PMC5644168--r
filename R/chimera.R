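## Reference-based two-parent chimera screening.  Candidate parents are
## pre-selected by shared k-mer counts; a breakpoint scan then asks whether a
## two-parent model explains the query substantially better than the best
## single parent.

ungapped_window_seq <- function(row, cols) {
  s <- row[cols]
  paste(s[s != GAP], collapse = "")
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Rank candidate chimera parents by chunked shared k-mer counts
#'
#' The query's ungapped window sequence is divided into `n_chunks`
#' contiguous chunks and each reference is scored per chunk by the number of
#' distinct query-chunk k-mers it shares.  As in UCHIME's per-segment
#' candidate search, the best-matching reference of every chunk is always a
#' candidate (so a parent matching only one side of a recombinant query is
#' never crowded out by full-length near-relatives of the other side);
#' remaining slots are filled by the best chunk-maximum scores.  All ties
#' are broken by ascending seq_id.
#'
#' @param query query id (row of `aln`) or residue vector.
#' @param ref_aln reference alignment matrix (non-chimeric by construction).
#' @param window an [internal_window()].
#' @param aln alignment holding the query when `query` is an id.
#' @param k k-mer size.
#' @param top number of candidates to return.
#' @param n_chunks number of query chunks scored separately.
#' @return character vector of up to `top` reference ids (empty when the
#'   reference set is empty).
#' @export
candidate_parents <- function(query, ref_aln, window, aln = NULL, k = 8,
                              top = 4, n_chunks = 4) {
  if (is.null(ref_aln) || nrow(ref_aln) == 0) return(character(0))
  cols <- window_cols(window, ncol(ref_aln))
  qrow <- if (length(query) == 1 && !is.null(aln)) aln[query, ] else query
  qseq <- ungapped_window_seq(qrow, cols)
  bounds <- round(seq(0, nchar(qseq), length.out = n_chunks + 1))
  qk <- lapply(seq_len(n_chunks), function(i)
    kmer_set(substr(qseq, bounds[i] + 1, bounds[i + 1]), k))
  ids <- rownames(ref_aln)
  shared <- t(vapply(ids, function(r) {
    rk <- kmer_set(ungapped_window_seq(ref_aln[r, ], cols), k)
    vapply(qk, function(ck) length(intersect(ck, rk)), integer(1))
  }, integer(length(qk))))                  # refs x chunks
  per_chunk_best <- vapply(seq_len(ncol(shared)), function(ch)
    ids[order(-shared[, ch], ids, method = "radix")[1]], character(1))
  overall <- ids[order(-apply(shared, 1, max), ids, method = "radix")]
  cand <- unique(c(per_chunk_best, overall))
  cand[seq_len(min(top, length(cand)))]
}

## per-column match/scored indicators of query vs one parent, inside window
match_profile <- function(q, p) {
  list(m = as.numeric(q == p & q != 0L), s = as.numeric(q != 0L | p != 0L))
}

#' Score a query against a two-parent chimera model
#'
#' All breakpoints `b` on a `stride`-column grid across the window (endpoints
#' included) are scanned in both parent orders.  The model identity at `b`
#' pools matched and scored column counts of (query vs left parent) on
#' columns `< b` with (query vs right parent) on columns `>= b`, under the
#' same identity definition as [pairwise_identity()].  The verdict is
#' `chimeric` iff the model beats the best single parent by at least `d_min`
#' percentage points and both parent-side identities reach `s_min`.
#'
#' @param query,parent_a,parent_b ids (rows of `aln`/`ref_aln`) or residue
#'   vectors in shared coordinates.
#' @param window an [internal_window()].
#' @param aln,ref_aln alignments holding the query and parents when ids are
#'   given.
#' @param stride breakpoint grid spacing in columns.
#' @param d_min minimum model-over-single improvement, percentage points.
#' @param s_min minimum per-side identity, percent.
#' @return one-row data frame: query_id, verdict, parent_left, parent_right,
#'   breakpoint (0-based window-relative column), id_to_model,
#'   id_to_best_single, divergence.
#' @export
chimera_score <- function(query, parent_a, parent_b, window, aln = NULL,
                          ref_aln = NULL, stride = 10, d_min = 2.0,
                          s_min = 90.0) {
  getrow <- function(x, m) {
    if (length(x) == 1 && !is.null(m) && x %in% rownames(m)) m[x, ]
    else if (length(x) == 1 && !is.null(aln) && x %in% rownames(aln)) aln[x, ]
    else x
  }
  qid <- if (length(query) == 1) query else "query"
  qrow <- getrow(query, aln)
  arow <- getrow(parent_a, ref_aln)
  brow <- getrow(parent_b, ref_aln)
  cols <- window_cols(window, length(qrow))
  enc <- function(r) match(r[cols], c("A", "C", "G", "T"), nomatch = 0L)
  q <- enc(qrow); a <- enc(arow); b <- enc(brow)
  w <- length(cols)
  pa <- match_profile(q, a); pb <- match_profile(q, b)
  cma <- c(0, cumsum(pa$m)); csa <- c(0, cumsum(pa$s))
  cmb <- c(0, cumsum(pb$m)); csb <- c(0, cumsum(pb$s))
  id_a <- 100 * cma[w + 1] / csa[w + 1]
  id_b <- 100 * cmb[w + 1] / csb[w + 1]
  best_single <- max(id_a, id_b)

  bps <- unique(c(seq(0, w, by = stride), w))
  best <- list(id = -Inf)
  for (orient in 1:2) {
    ml <- if (orient == 1) cma else cmb; sl <- if (orient == 1) csa else csb
    mr <- if (orient == 1) cmb else cma; sr <- if (orient == 1) csb else csa
    num <- ml[bps + 1] + (mr[w + 1] - mr[bps + 1])
    den <- sl[bps + 1] + (sr[w + 1] - sr[bps + 1])
    idm <- ifelse(den > 0, 100 * num / den, -Inf)
    j <- which.max(idm)
    if (idm[j] > best$id) {
      left_s <- sl[bps[j] + 1]; right_s <- sr[w + 1] - sr[bps[j] + 1]
      best <- list(id = idm[j], bp = bps[j], orient = orient,
                   id_left = if (left_s > 0) 100 * ml[bps[j] + 1] / left_s else NA_real_,
                   id_right = if (right_s > 0)
                     100 * (mr[w + 1] - mr[bps[j] + 1]) / right_s else NA_real_)
    }
  }
  if (!is.finite(best$id))
    return(data.frame(query_id = qid, verdict = "no_parents",
                      parent_left = NA_character_, parent_right = NA_character_,
                      breakpoint = NA_integer_, id_to_model = NA_real_,
                      id_to_best_single = best_single, divergence = NA_real_,
                      stringsAsFactors = FALSE))
  divergence <- best$id - best_single
  sides_ok <- !is.na(best$id_left) && !is.na(best$id_right) &&
    best$id_left >= s_min && best$id_right >= s_min
  verdict <- if (divergence >= d_min && sides_ok) "chimeric" else "clean"
  pleft <- if (best$orient == 1) parent_a else parent_b
  pright <- if (best$orient == 1) parent_b else parent_a
  data.frame(query_id = qid, verdict = verdict,
             parent_left = if (length(pleft) == 1) pleft else "parent",
             parent_right = if (length(pright) == 1) pright else "parent",
             breakpoint = best$bp, id_to_model = best$id,
             id_to_best_single = best_single, divergence = divergence,
             stringsAsFactors = FALSE)
}

#' Screen a set of queries for chimeras against a reference database
#'
#' For each query the top k-mer candidates are taken as potential parents;
#' all unordered candidate pairs are scored with [chimera_score()] (which
#' itself scans both orientations) and the pair with the highest model
#' identity decides the verdict.  Queries with fewer than two candidates are
#' reported `no_parents`.
#'
#' @param queries alignment matrix of query sequences.
#' @param ref_aln reference alignment matrix (e.g. genome-source sequences).
#' @param window an [internal_window()].
#' @param k,top candidate pre-selection parameters, see [candidate_parents()].
#' @param stride,d_min,s_min scoring parameters, see [chimera_score()].
#' @return data frame of per-query verdicts (one row each).
#' @export
screen_chimeras <- function(queries, ref_aln, window, k = 8, top = 4,
                            stride = 10, d_min = 2.0, s_min = 90.0) {
  empty <- data.frame(query_id = character(0), verdict = character(0),
                      parent_left = character(0), parent_right = character(0),
                      breakpoint = integer(0), id_to_model = numeric(0),
                      id_to_best_single = numeric(0), divergence = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(queries) == 0) return(empty)
  out <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    qid <- rownames(queries)[qi]
    ## the query id is not excluded from candidates: a trusted reference
    ## identical to the query correctly forces a clean verdict
    cand <- candidate_parents(queries[qi, ], ref_aln, window, k = k, top = top)
    if (length(cand) < 2) {
      out[[qi]] <- data.frame(query_id = qid, verdict = "no_parents",
                              parent_left = NA_character_,
                              parent_right = NA_character_,
                              breakpoint = NA_integer_,
                              id_to_model = NA_real_,
                              id_to_best_single = NA_real_,
                              divergence = NA_real_, stringsAsFactors = FALSE)
      next
    }
    pairs <- utils::combn(cand, 2, simplify = FALSE)
    best <- NULL
    for (pr in pairs) {
      v <- chimera_score(queries[qi, ], pr[1], pr[2], window,
                         ref_aln = ref_aln, stride = stride,
                         d_min = d_min, s_min = s_min)
      v$query_id <- qid
      v$parent_left <- ifelse(v$parent_left == "parent", pr[1], v$parent_left)
      v$parent_right <- ifelse(v$parent_right == "parent", pr[2], v$parent_right)
      if (is.null(best) ||
          (!is.na(v$id_to_model) &&
           (is.na(best$id_to_model) || v$id_to_model > best$id_to_model)))
        best <- v
    }
    out[[qi]] <- best
  }
  do.call(rbind, out)
}
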