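#' Longest open reading frame of a transcript
#'
#' Scans the three forward reading frames (and optionally the reverse
#' complement) for ATG-initiated frames ending at the first in-frame stop
#' codon (TAA/TAG/TGA). Used for sanity checks of assembled cDNAs, e.g.
#' verifying the protein length encoded by a cloned transcript.
#'
#' @param seq character string, `DNAString`, or single-sequence
#'   `DNAStringSet`.
#' @param both_strands also scan the reverse complement (default FALSE;
#'   a directional mRNA is scanned forward only).
#' @return list: `start`, `end` (1-based inclusive nucleotide coordinates
#'   of the ORF including the stop codon on the scanned strand), `strand`,
#'   `nt_length`, `aa_length` (codons excluding the stop). All-NA when no
#'   ORF exists.
#' @export
longest_orf <- function(seq, both_strands = FALSE) {
  if (inherits(seq, "DNAStringSet")) seq <- seq[[1L]]
  s <- toupper(as.character(seq))
  best <- list(start = NA_integer_, end = NA_integer_, strand = NA_character_,
               nt_length = 0L, aa_length = NA_integer_)
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    for (frame in 0:2) {
      codon_starts <- seq(1L + frame, n - 2L, by = 3L)
      if (length(codon_starts) == 0L) next
      codons <- substring(s, codon_starts, codon_starts + 2L)
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open_from <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open_from) && is_start[i]) open_from <- i
        if (!is.na(open_from) && is_stop[i]) {
          nt <- (i - open_from + 1L) * 3L
          if (nt > best$nt_length) {
            best <<- list(start = codon_starts[open_from],
                          end = codon_starts[i] + 2L,
                          strand = strand,
                          nt_length = nt,
                          aa_length = (nt %/% 3L) - 1L)
          }
          open_from <- NA_integer_
        }
      }
    }
  }
  scan_strand(s, "+")
  if (both_strands) scan_strand(revcomp(s), "-")
  if (best$nt_length == 0L) best$nt_length <- NA_integer_
  best
}

#' Transcript length and longest-ORF statistics from a FASTA file
#'
#' @param path FASTA with one or more transcripts.
#' @param both_strands passed to [longest_orf()].
#' @return data.frame: `transcript_id`, `nt_length` (transcript length),
#'   `orf_nt_length`, `orf_aa_length`.
#' @export
transcript_stats <- function(path, both_strands = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  rows <- lapply(seq_along(seqs), function(i) {
    orf <- longest_orf(seqs[[i]], both_strands)
    data.frame(transcript_id = sub("\\s.*$", "", names(seqs)[i]),
               nt_length = length(seqs[[i]]),
               orf_nt_length = orf$nt_length,
               orf_aa_length = orf$aa_length,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
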