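## Alignment container: a plain character matrix over {A,C,G,T,-}, one row per
## sequence (rownames = sequence ids), one column per alignment column.  All
## column coordinates exposed to users are 0-based, half-open, matching the
## conventions of the file formats this package consumes.

GAP <- "-"

#' Convert named sequence strings to an alignment matrix
#'
#' @param x named character vector of equal-length aligned sequences.
#' @return character matrix with one row per sequence.
#' @export
aln_matrix <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must carry unique names")
  n <- unique(nchar(x))
  if (length(n) > 1) {
    bad <- names(x)[nchar(x) != nchar(x)[1]][1]
    stop("unequal alignment lengths; offending record: ", bad)
  }
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

## integer encoding used by all identity/distance kernels: A=1 C=2 G=3 T=4,
## gap (or anything else) = 0
encode_aln <- function(aln) {
  codes <- match(aln, c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  dim(codes) <- dim(aln)
  rownames(codes) <- rownames(aln)
  codes
}

#' Ungapped length of each sequence
#'
#' @param aln alignment matrix (see [aln_matrix()]).
#' @return named integer vector of non-gap residue counts.
#' @export
ungapped_length <- function(aln) {
  rowSums(aln != GAP)
}

normalize_residues <- function(x, id = "?") {
  x <- toupper(x)
  x <- gsub(".", GAP, x, fixed = TRUE)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- regmatches(x, regexpr("[^ACGT-]", x))
  if (length(bad) && nzchar(bad))
    stop("invalid residue '", bad, "' in record ", id)
  x
}

#' Read an aligned FASTA file, optionally merging per-sequence metadata
#'
#' Residues are upper-cased, `U` is converted to `T` and `.` gap characters
#' are normalized to `-`.  Records must all have the same aligned length.
#' Metadata is a TSV with columns `seq_id`, `source`
#' (`metagenome`/`genome`/`reference_db`), `environment`, and optionally
#' `phylum_label` (known taxonomy, e.g. from genome annotation).  Sequences
#' without a metadata row default to `source = "metagenome"` and an empty
#' environment, with a warning.
#'
#' @param path aligned FASTA file.
#' @param metadata_path optional metadata TSV.
#' @return list with `aln` (alignment matrix) and `meta` (data frame).
#' @export
read_alignment <- function(path, metadata_path = NULL) {
  ss <- Biostrings::readBStringSet(path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(x)))
    stop("duplicate seq_id in FASTA: ", names(x)[duplicated(names(x))][1])
  x <- vapply(seq_along(x), function(i) normalize_residues(x[[i]], names(x)[i]),
              character(1))
  names(x) <- sub("\\s.*$", "", names(ss))
  aln <- aln_matrix(x)
  meta <- data.frame(seq_id = rownames(aln), source = "metagenome",
                     environment = "", phylum_label = "",
                     stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    md <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("seq_id", "source") %in% names(md)))
      stop("metadata must have columns seq_id and source")
    if (!"environment" %in% names(md)) md$environment <- ""
    if (!"phylum_label" %in% names(md)) md$phylum_label <- ""
    bad <- setdiff(unique(md$source), c("metagenome", "genome", "reference_db"))
    if (length(bad)) stop("unknown source category: ", bad[1])
    i <- match(meta$seq_id, md$seq_id)
    if (anyNA(i))
      warning(sum(is.na(i)), " sequence(s) missing metadata; ",
              "defaulting to source=metagenome, empty environment")
    ok <- !is.na(i)
    meta$source[ok] <- md$source[i[ok]]
    meta$environment[ok] <- md$environment[i[ok]]
    meta$phylum_label[ok] <- md$phylum_label[i[ok]]
  }
  list(aln = aln, meta = meta)
}

#' Write an alignment matrix as aligned FASTA
#'
#' @param aln alignment matrix.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  x <- apply(aln, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 20000L)
  invisible(path)
}

#' Read a Stockholm alignment and its match-column annotation
#'
#' Minimal single- or multi-block Stockholm 1.0 reader.  The `#=GC RF`
#' reference line, when present, yields a per-column match mask: columns
#' annotated with anything other than `.` or `~` are match (consensus model)
#' columns; the others are insert columns, removable with
#' [drop_insert_columns()].
#'
#' @param path Stockholm file.
#' @return list with `aln` (alignment matrix, residues normalized as in
#'   [read_alignment()]) and `match_mask` (logical per column, or NULL when no
#'   RF line is present).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file: ", path)
  seqs <- list()
  rf <- character(0)
  for (ln in lines[-1]) {
    if (ln == "//" || ln == "" ) next
    if (startsWith(ln, "#=GC RF")) {
      rf <- c(rf, sub("^#=GC RF\\s+", "", ln))
    } else if (startsWith(ln, "#")) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2) stop("malformed sequence line: ", ln)
      seqs[[f[1]]] <- paste0(if (is.null(seqs[[f[1]]])) "" else seqs[[f[1]]],
                             f[2])
    }
  }
  if (!length(seqs)) stop("no sequences in ", path)
  x <- vapply(names(seqs), function(id) normalize_residues(seqs[[id]], id),
              character(1))
  aln <- aln_matrix(x)
  mask <- NULL
  if (length(rf)) {
    rfc <- strsplit(paste(rf, collapse = ""), "")[[1]]
    if (length(rfc) != ncol(aln))
      stop("RF annotation length differs from alignment length")
    mask <- !(rfc %in% c(".", "~"))
  }
  list(aln = aln, match_mask = mask)
}

#' Drop insert columns according to a match-column mask
#'
#' Emulates the match-only projection of a covariance-model alignment: only
#' columns flagged as match columns are retained, in order.
#'
#' @param aln alignment matrix.
#' @param match_mask logical vector, one entry per alignment column.
#' @return alignment matrix restricted to match columns.
#' @export
drop_insert_columns <- function(aln, match_mask) {
  if (length(match_mask) != ncol(aln))
    stop("match_mask length (", length(match_mask),
         ") does not equal alignment length (", ncol(aln), ")")
  aln[, match_mask, drop = FALSE]
}

#' Filter sequences by ungapped length
#'
#' Sequences are kept iff their ungapped length (number of bases, not
#' alignment columns) is at least `min_bases`.  The default reproduces the
#' standard >= 1200 bp quality cut for full-length SSU rRNA genes.
#'
#' @param aln alignment matrix.
#' @param min_bases minimum ungapped length, in bases.
#' @return list with `kept` (alignment matrix) and `discarded` (data frame of
#'   seq_id and ungapped_length).
#' @export
filter_by_length <- function(aln, min_bases = 1200) {
  len <- ungapped_length(aln)
  keep <- len >= min_bases
  list(kept = aln[keep, , drop = FALSE],
       discarded = data.frame(seq_id = rownames(aln)[!keep],
                              ungapped_length = unname(len[!keep]),
                              stringsAsFactors = FALSE))
}

#' An internal clustering window
#'
#' @param start 0-based inclusive start column.
#' @param width window width in columns.
#' @return object of class `internal_window`.
#' @export
internal_window <- function(start, width = 900) {
  start <- as.integer(start); width <- as.integer(width)
  if (start < 0 || width < 1) stop("invalid window")
  structure(list(start = start, width = width), class = "internal_window")
}

#' @export
print.internal_window <- function(x, ...) {
  cat(sprintf("<internal_window [%d, %d) width %d>\n",
              x$start, x$start + x$width, x$width))
  invisible(x)
}

window_cols <- function(window, aln_len) {
  if (window$start + window$width > aln_len)
    stop("window [", window$start, ", ", window$start + window$width,
         ") exceeds alignment length ", aln_len)
  seq.int(window$start + 1L, window$start + window$width)
}

#' Select the internal clustering window
#'
#' Full-length SSU rRNA alignments carry terminal gaps on partially covered
#' sequences; clustering is therefore restricted to an internal window
#' (default 900 columns, spanning roughly the V3-V7 variable regions in the
#' bacterial model coordinates).  The window is chosen to maximize the
#' minimum per-sequence non-gap count over all contiguous candidate windows;
#' ties are broken towards the smallest start column.  Alternatively a fixed
#' start may be supplied.
#'
#' @param aln alignment matrix.
#' @param width window width in columns.
#' @param start optional fixed 0-based start column (config override).
#' @return an [internal_window()].
#' @export
select_internal_window <- function(aln, width = 900, start = NULL) {
  if (ncol(aln) < width)
    stop("alignment length ", ncol(aln), " shorter than window width ", width)
  if (!is.null(start)) {
    w <- internal_window(start, width)
    window_cols(w, ncol(aln))  # validates
    return(w)
  }
  nongap <- aln != GAP
  cs <- cbind(0L, t(apply(nongap, 1, cumsum)))  # nseq x (ncol+1)
  starts <- 0:(ncol(aln) - width)
  cov <- cs[, starts + width + 1L, drop = FALSE] - cs[, starts + 1L, drop = FALSE]
  mins <- apply(cov, 2, min)
  internal_window(starts[which.max(mins)], width)
}

#' Filter sequences by gap count inside the internal window
#'
#' Sequences with more than `max_gaps` gap characters inside the window are
#' discarded (strictly more: a sequence with exactly `max_gaps` gaps is kept).
#'
#' @param aln alignment matrix.
#' @param window an [internal_window()].
#' @param max_gaps maximum tolerated gap count inside the window.
#' @return list with `kept` (alignment matrix) and `discarded` (data frame of
#'   seq_id and window_gaps).
#' @export
filter_by_gaps <- function(aln, window, max_gaps = 40) {
  cols <- window_cols(window, ncol(aln))
  gaps <- rowSums(aln[, cols, drop = FALSE] == GAP)
  keep <- gaps <= max_gaps
  list(kept = aln[keep, , drop = FALSE],
       discarded = data.frame(seq_id = rownames(aln)[!keep],
                              window_gaps = unname(gaps[!keep]),
                              stringsAsFactors = FALSE))
}
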