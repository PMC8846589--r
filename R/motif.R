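IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

set_to_code <- local({
  m <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(m), m)
})

#' Parse a degenerate consensus motif
#'
#' Accepts plain IUPAC strings (e.g. `"GCATWATTWAT"`) and the parenthetical
#' notation used when writing binding consensi by hand, e.g.
#' `"AT(A/T)ATT(A/T)AT"`, which normalizes to `"ATWATTWAT"`. Any set of
#' distinct bases inside parentheses maps to its IUPAC code.
#'
#' @param text motif text in either notation.
#' @param label optional display label; defaults to the normalized
#'   consensus.
#' @return list with fields `label` and `consensus`, class
#'   `degenerate_motif`.
#' @export
parse_consensus <- function(text, label = NULL) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("motif text must be a single non-empty string")
  s <- toupper(gsub("\\s", "", text))
  out <- character()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      j <- regexpr(")", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed parenthesis in motif: ", text)
      inner <- substr(s, i + 1L, i + j - 2L)
      bases <- sort(unique(strsplit(gsub("/", "", inner), "")[[1L]]))
      if (!all(bases %in% c("A", "C", "G", "T")))
        stop("invalid bases in parenthetical group '", inner, "'")
      code <- set_to_code[[paste(bases, collapse = "")]]
      if (is.null(code)) stop("cannot encode group '", inner, "'")
      out <- c(out, code)
      i <- i + j
    } else {
      if (!ch %in% names(IUPAC_SETS))
        stop("invalid IUPAC code '", ch, "' in motif: ", text)
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  consensus <- paste(out, collapse = "")
  structure(list(label = label %||% consensus, consensus = consensus),
            class = "degenerate_motif")
}

as_motif <- function(m) {
  if (inherits(m, "degenerate_motif")) m else parse_consensus(m)
}

#' Expand a degenerate motif into its concrete sequences
#'
#' Cartesian expansion of every degenerate position.
#'
#' @param m a `degenerate_motif` or motif string.
#' @return character vector of concrete A/C/G/T sequences.
#' @export
expand_iupac <- function(m) {
  m <- as_motif(m)
  sets <- IUPAC_SETS[strsplit(m$consensus, "")[[1L]]]
  out <- do.call(expand.grid,
                 c(rev(sets), stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  sort(apply(out[, rev(seq_along(sets)), drop = FALSE], 1L, paste,
             collapse = ""))
}

#' Reverse complement of a nucleotide string
#' @param x character vector of sequences (IUPAC codes allowed).
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan sequence for degenerate motif matches
#'
#' Matches by per-position IUPAC set membership (not PWM scoring). `N` in
#' the subject never matches. Reverse-strand hits are found by matching
#' the reverse complement of the motif against the forward strand, and are
#' reported at the forward-strand coordinates of the matched window with
#' `matched_seq` being the forward-strand slice. Overlapping hits are all
#' reported; output is sorted by seqid, start, then strand (`+` first).
#'
#' @param seq a character vector of sequences, a `DNAString`, or a
#'   `DNAStringSet` (named elements give seqids).
#' @param m a `degenerate_motif` or motif string.
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @return data.frame with class `motif_hits`: `seqid`, `start` (1-based,
#'   forward coordinates), `strand`, `matched_seq`.
#' @export
scan_sequence <- function(seq, m, both_strands = TRUE) {
  m <- as_motif(m)
  if (inherits(seq, "DNAString"))
    seq <- Biostrings::DNAStringSet(seq)
  if (!inherits(seq, "DNAStringSet"))
    seq <- Biostrings::DNAStringSet(toupper(as.character(seq)))
  if (is.null(names(seq)))
    names(seq) <- if (length(seq) == 1L) "seq" else
      sprintf("seq%d", seq_along(seq))
  pat_fwd <- Biostrings::DNAString(m$consensus)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  one <- function(subject, seqid) {
    hit_df <- function(pattern, strand) {
      mt <- Biostrings::matchPattern(pattern, subject, fixed = "subject")
      if (length(mt) == 0L) return(NULL)
      matched <- as.character(mt)
      keep <- grepl("^[ACGT]+$", matched)   # subject N/ambiguity never matches
      if (!any(keep)) return(NULL)
      data.frame(seqid = seqid, start = BiocGenerics::start(mt)[keep],
                 strand = strand,
                 matched_seq = matched[keep],
                 stringsAsFactors = FALSE)
    }
    res <- list(hit_df(pat_fwd, "+"))
    if (both_strands) res <- c(res, list(hit_df(pat_rev, "-")))
    do.call(rbind, res[!vapply(res, is.null, TRUE)])
  }
  out <- do.call(rbind, lapply(seq_along(seq), function(i)
    one(seq[[i]], names(seq)[i])))
  if (is.null(out))
    out <- data.frame(seqid = character(), start = integer(),
                      strand = character(), matched_seq = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$seqid, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Scan a FASTA file for motif hits
#'
#' @param path FASTA file.
#' @inheritParams scan_sequence
#' @return a `motif_hits` data.frame (seqids from FASTA headers).
#' @export
scan_fasta <- function(path, m, both_strands = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  scan_sequence(Biostrings::readDNAStringSet(path), m, both_strands)
}

#' Central-enrichment test for motif hits in peak windows
#'
#' A hit is "central" when its position (callers typically pass the hit
#' midpoint) lies within the middle `central_fraction` of its window.
#' Under the uniform-placement null the number of central hits is
#' Binomial(n_hits, central_fraction); the one-sided upper-tail exact
#' binomial probability is returned. This positional test is a documented
#' stand-in for external motif-enrichment statistics: it tests the same
#' property (concentration of hits at peak centers) but is not numerically
#' identical to any specific external tool's p-value.
#'
#' @param hit_positions numeric positions of hits (1-based, same
#'   coordinates as the windows).
#' @param window_start,window_end interval bounds of the window containing
#'   each hit (recycled if scalar).
#' @param central_fraction fraction of the window considered central, in
#'   (0, 1); default 0.2.
#' @return list: `n_hits`, `n_central`, `p_value` (1.0 when no hits).
#' @export
central_enrichment_test <- function(hit_positions, window_start, window_end,
                                    central_fraction = 0.2) {
  if (central_fraction <= 0 || central_fraction >= 1)
    stop("central_fraction must lie in (0, 1)")
  n <- length(hit_positions)
  if (n == 0L)
    return(list(n_hits = 0L, n_central = 0L, p_value = 1.0))
  ws <- rep_len(window_start, n)
  we <- rep_len(window_end, n)
  if (any(hit_positions < ws | hit_positions > we))
    stop("every hit position must lie inside its window")
  len <- we - ws + 1
  rel <- (hit_positions - ws + 0.5) / len   # relative position in (0, 1)
  central <- abs(rel - 0.5) <= central_fraction / 2
  k <- sum(central)
  p <- stats::pbinom(k - 1L, n, central_fraction, lower.tail = FALSE)
  list(n_hits = n, n_central = as.integer(k), p_value = p)
}

#' Write motif hits as BED6
#'
#' Coordinates convert to 0-based half-open on write; the matched sequence
#' goes in the name column and score is 0.
#'
#' @param hits a `motif_hits` data.frame.
#' @param motif_length motif width in bp.
#' @param path output BED file.
#' @export
write_hits_bed <- function(hits, motif_length, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   hits$seqid, hits$start - 1L,
                   hits$start - 1L + motif_length,
                   hits$matched_seq, hits$strand)
  writeLines(lines, path)
  invisible(path)
}
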