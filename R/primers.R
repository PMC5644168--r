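## In-silico primer mismatch scoring with IUPAC degeneracy and a 3'-weighted
## penalty scheme: mismatches and gaps near the primer 3' end compromise
## polymerase extension far more than 5' differences, so they carry heavier
## weights, and a cluster whose mean weighted score exceeds 1 for either
## primer is predicted to be missed by the primer set.

IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
BASE_OF_MASK <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")

iupac_masks <- function(seq) {
  m <- IUPAC_MASK[strsplit(toupper(seq), "")[[1]]]
  if (anyNA(m)) stop("invalid IUPAC code in '", seq, "'")
  unname(m)
}

iupac_revcomp <- function(seq) {
  comp_mask <- function(m) {
    ## complement each base bit: A<->T (1<->8), C<->G (2<->4)
    ((m %% 2) * 8L) + (bitwAnd(m, 2L) * 2L) + (bitwAnd(m, 4L) %/% 2L) +
      (bitwAnd(m, 8L) %/% 8L)
  }
  rev_masks <- rev(comp_mask(iupac_masks(seq)))
  mask_to_code <- setNames(names(IUPAC_MASK)[match(1:15, IUPAC_MASK)],
                           as.character(1:15))
  paste(mask_to_code[as.character(rev_masks)], collapse = "")
}

#' Define a PCR primer with 3'-weighted mismatch penalties
#'
#' @param name primer name (e.g. `"515f"`).
#' @param direction `"forward"` or `"reverse"`; reverse primers are matched
#'   as their reverse complement, with the 3' window tracked accordingly.
#' @param sequence primer sequence in IUPAC nucleotide codes, written 5'->3'.
#' @param three_prime_window number of 3'-terminal primer bases in the
#'   heavily weighted window.
#' @param weights named penalties: `non3_mismatch`, `three_prime_mismatch`,
#'   `non3_gap`, `three_prime_gap`.
#' @return object of class `primer_spec`.
#' @export
primer_spec <- function(name, direction = c("forward", "reverse"), sequence,
                        three_prime_window = 5,
                        weights = c(non3_mismatch = 0.4,
                                    three_prime_mismatch = 1.0,
                                    non3_gap = 1.0, three_prime_gap = 3.0)) {
  direction <- match.arg(direction)
  if (!nzchar(sequence)) stop("primer sequence must be non-empty")
  iupac_masks(sequence)  # validates
  need <- c("non3_mismatch", "three_prime_mismatch", "non3_gap",
            "three_prime_gap")
  if (!all(need %in% names(weights)) || any(weights < 0))
    stop("weights must be non-negative and named ", paste(need, collapse = ", "))
  structure(list(name = name, direction = direction,
                 sequence = toupper(sequence),
                 three_prime_window = as.integer(three_prime_window),
                 weights = weights[need]),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer %s (%s): 5'-%s-3', 3' window %d>\n", x$name,
              x$direction, x$sequence, x$three_prime_window))
  invisible(x)
}

#' The Earth Microbiome Project 515f/806r primer pair
#'
#' Shipped convenience defaults: the EMP V4 primers 515F (Parada;
#' `GTGYCAGCMGCCGCGGTAA`) and 806R (Apprill; `GGACTACNVGGGTWTCTAAT`).  Any
#' primer pair can be supplied instead via [primer_spec()].
#'
#' @return list with elements `forward` and `reverse`.
#' @export
emp_primers <- function() {
  list(forward = primer_spec("515f", "forward", "GTGYCAGCMGCCGCGGTAA"),
       reverse = primer_spec("806r", "reverse", "GGACTACNVGGGTWTCTAAT"))
}

#' Score a primer against an ungapped sequence
#'
#' The primer (reverse primers as their reverse complement) is aligned to
#' its best binding site: the full primer against any contiguous stretch of
#' the target, choosing the site (and gap placement) that minimizes the
#' weighted mismatch score itself — the sum of the configured penalties over
#' mismatches and gaps inside and outside the 3' window.  A degenerate
#' primer position matches any base in its degeneracy set at zero cost, so
#' the reported score provably equals the minimum score over all concrete
#' expansions of the degenerate primer.  A target shorter than the primer
#' yields no site and an infinite score.
#'
#' @param seq target sequence: a string or residue vector; gap characters
#'   are removed.
#' @param primer a [primer_spec()].
#' @return one-row data frame (`PrimerHit`): primer, score, start, end
#'   (1-based on the ungapped target), n_mismatch_3p, n_mismatch_non3,
#'   n_gap_3p, n_gap_non3.
#' @export
primer_weighted_score <- function(seq, primer) {
  if (length(seq) > 1) seq <- paste(seq, collapse = "")
  seq <- gsub("-", "", toupper(seq), fixed = TRUE)
  pseq <- primer$sequence
  in3 <- rev(seq_len(nchar(pseq))) <= primer$three_prime_window
  if (primer$direction == "reverse") {
    pseq <- iupac_revcomp(pseq)
    in3 <- rev(in3)
  }
  pm <- iupac_masks(pseq)
  hit0 <- data.frame(primer = primer$name, score = Inf, start = NA_integer_,
                     end = NA_integer_, n_mismatch_3p = NA_integer_,
                     n_mismatch_non3 = NA_integer_, n_gap_3p = NA_integer_,
                     n_gap_non3 = NA_integer_, stringsAsFactors = FALSE)
  if (nchar(seq) < length(pm)) return(hit0)
  tm <- IUPAC_MASK[strsplit(seq, "")[[1]]]
  if (anyNA(tm)) stop("target contains invalid residues")
  w <- primer$weights
  res <- primer_fit_align(as.integer(pm), as.integer(unname(tm)),
                          as.logical(in3),
                          w[["non3_mismatch"]], w[["three_prime_mismatch"]],
                          w[["non3_gap"]], w[["three_prime_gap"]])
  data.frame(primer = primer$name, score = res$score,
             start = res$start, end = res$end,
             n_mismatch_3p = res$mm3, n_mismatch_non3 = res$mmN,
             n_gap_3p = res$gap3, n_gap_non3 = res$gapN,
             stringsAsFactors = FALSE)
}

#' Primer mismatch report for one cluster of sequences
#'
#' All member sequences of an 85% cluster are scored against the forward and
#' reverse primers; per-primer mean and standard deviation are computed and
#' the cluster is predicted missed iff either primer's mean weighted score
#' is strictly greater than `threshold`.  `mismatch_score` is the maximum of
#' the two primer means.
#'
#' @param seqs member sequences: character vector of (possibly gapped)
#'   sequence strings, or an alignment matrix.
#' @param primers list with elements `forward` and `reverse`
#'   ([primer_spec()] objects), e.g. [emp_primers()].
#' @param cluster_id optional cluster label for the report row.
#' @param threshold missed-prediction threshold on the per-primer mean.
#' @param sd_type population (n divisor, default) or sample (n-1) SD.
#' @return one-row data frame: cluster_id, n_seqs, forward/reverse mean and
#'   SD, mismatch_score, predicted_missed.
#' @export
cluster_primer_report <- function(seqs, primers, cluster_id = NA_character_,
                                  threshold = 1,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.matrix(seqs)) seqs <- apply(seqs, 1, paste, collapse = "")
  if (!length(seqs)) stop("empty cluster")
  fs <- vapply(seqs, function(s) primer_weighted_score(s, primers$forward)$score,
               numeric(1))
  rs <- vapply(seqs, function(s) primer_weighted_score(s, primers$reverse)$score,
               numeric(1))
  popsd <- function(x) {
    if (sd_type == "sample") return(if (length(x) > 1) stats::sd(x) else 0)
    sqrt(mean((x - mean(x))^2))
  }
  fm <- mean(fs); rm_ <- mean(rs)
  data.frame(cluster_id = cluster_id, n_seqs = length(seqs),
             forward_mean = fm, forward_sd = popsd(fs),
             reverse_mean = rm_, reverse_sd = popsd(rs),
             mismatch_score = max(fm, rm_),
             predicted_missed = fm > threshold | rm_ > threshold,
             stringsAsFactors = FALSE)
}

#' Primer mismatch report for every 85% cluster
#'
#' @param tlc result of [two_level_cluster()].
#' @param aln alignment matrix holding all member sequences.
#' @param primers list with `forward` and `reverse` [primer_spec()] objects.
#' @param ... passed to [cluster_primer_report()].
#' @return data frame with one row per 85% cluster.
#' @export
primer_report <- function(tlc, aln, primers, ...) {
  otu_of <- setNames(tlc$otus$cluster_id, tlc$otus$otu_id)
  cl <- unname(otu_of[tlc$membership$otu_id])
  rows <- lapply(tlc$clusters85$cluster_id, function(cid) {
    members <- tlc$membership$seq_id[!is.na(cl) & cl == cid]
    cluster_primer_report(aln[members, , drop = FALSE], primers,
                          cluster_id = cid, ...)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
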