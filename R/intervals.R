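#' Construct genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends throughout the package,
#' matching the coordinate style of genome-browser scaffold citations
#' (`scaffold:start-end`). BED-family inputs (0-based, half-open) are
#' converted on read; see [read_narrowpeak()].
#'
#' @param seqid character vector of scaffold/sequence identifiers.
#' @param start,end integer vectors, 1-based inclusive; `end >= start >= 1`.
#' @return A `data.frame` with columns `seqid`, `start`, `end` and class
#'   `genomic_interval`.
#' @examples
#' genomic_interval("scaffold_353", 49524, 53227)
#' @export
genomic_interval <- function(seqid, start, end) {
  iv <- data.frame(seqid = as.character(seqid),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  class(iv) <- c("genomic_interval", "data.frame")
  iv
}

validate_intervals <- function(iv) {
  if (any(is.na(iv$start)) || any(is.na(iv$end)))
    stop("interval coordinates must be non-missing integers")
  if (any(iv$start < 1L))
    stop("interval start must be >= 1 (coordinates are 1-based)")
  if (any(iv$end < iv$start))
    stop("interval end must be >= start")
  invisible(iv)
}

#' Interval length in base pairs
#'
#' Under the 1-based inclusive convention the length of `start-end` is
#' `end - start + 1`, so e.g. 49524-53227 spans 3704 bp.
#'
#' @param iv a `genomic_interval` (or any data.frame with `start`/`end`).
#' @return integer vector of lengths.
#' @export
interval_length <- function(iv) {
  validate_intervals(iv)
  as.integer(iv$end - iv$start + 1L)
}

#' Pairwise interval overlap
#'
#' Two intervals overlap iff they are on the same seqid and share at least
#' one base. Rows of `a` and `b` are compared elementwise (recycled if one
#' has a single row).
#'
#' @param a,b `genomic_interval` data.frames.
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$seqid[ai] == b$seqid[bi] &
    a$start[ai] <= b$end[bi] &
    b$start[bi] <= a$end[ai]
}

#' Construct gene models
#'
#' A gene model is a stranded scaffold span from the transcription start
#' site (TSS) through the transcription end. The TSS is the span start on
#' the `+` strand and the span end on the `-` strand; no transcript-isoform
#' resolution is attempted.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param seqid scaffold identifiers.
#' @param start,end 1-based inclusive span.
#' @param strand `"+"` or `"-"`.
#' @return data.frame with class `gene_model`.
#' @export
gene_model <- function(gene_id, seqid, start, end, strand) {
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  gm <- data.frame(gene_id = as.character(gene_id),
                   seqid = as.character(seqid),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(gm)
  class(gm) <- c("gene_model", "data.frame")
  gm
}

#' Transcription start sites of gene models
#' @param genes a `gene_model` data.frame.
#' @return integer vector of TSS positions.
#' @export
tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Promoter window rule
#'
#' Defaults follow the common terminal-selector target definition: the
#' promoter is the window from 350 bp upstream to 100 bp downstream of the
#' TSS. The window includes the TSS base itself, so its unclipped length is
#' `upstream_bp + downstream_bp + 1`.
#'
#' @param upstream_bp,downstream_bp non-negative integers (bp).
#' @return list with class `promoter_rule`.
#' @export
promoter_rule <- function(upstream_bp = 350L, downstream_bp = 100L) {
  upstream_bp <- as.integer(upstream_bp)
  downstream_bp <- as.integer(downstream_bp)
  if (is.na(upstream_bp) || is.na(downstream_bp) ||
      upstream_bp < 0L || downstream_bp < 0L)
    stop("promoter rule distances must be non-negative integers")
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp),
            class = "promoter_rule")
}

#' Strand-aware promoter windows
#'
#' On the `+` strand the window is `[TSS - upstream, TSS + downstream]`;
#' on the `-` strand the roles of upstream/downstream are mirrored:
#' `[TSS - downstream, TSS + upstream]`. Windows are clipped to
#' `[1, seq_length]` rather than rejected at scaffold edges.
#'
#' @param genes a `gene_model` data.frame.
#' @param rule a [promoter_rule()].
#' @param seq_lengths optional named integer vector of scaffold lengths
#'   (names are seqids) used for right-edge clipping.
#' @return a `genomic_interval` data.frame, one row per gene, with a
#'   `gene_id` column prepended.
#' @export
promoter_window <- function(genes, rule = promoter_rule(),
                            seq_lengths = NULL) {
  stopifnot(inherits(rule, "promoter_rule"))
  t <- tss(genes)
  plus <- genes$strand == "+"
  lo <- ifelse(plus, t - rule$upstream_bp, t - rule$downstream_bp)
  hi <- ifelse(plus, t + rule$downstream_bp, t + rule$upstream_bp)
  lo <- pmax(lo, 1L)
  if (!is.null(seq_lengths)) {
    sl <- seq_lengths[genes$seqid]
    if (any(is.na(sl)))
      stop("seq_lengths is missing scaffolds: ",
           paste(unique(genes$seqid[is.na(sl)]), collapse = ", "))
    hi <- pmin(hi, as.integer(sl))
  }
  out <- genomic_interval(genes$seqid, lo, hi)
  cbind(data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE), out)
}

#' Gene territory: promoter window united with the gene body
#'
#' The territory is the union of the promoter window and the gene span.
#' Because the promoter window always contains the TSS, which lies on the
#' span boundary, the union is a single contiguous interval per gene.
#' A gene is a direct target when at least one consensus peak overlaps its
#' territory; see [assign_targets()].
#'
#' @inheritParams promoter_window
#' @return a `genomic_interval` data.frame with a `gene_id` column.
#' @export
gene_territory <- function(genes, rule = promoter_rule(),
                           seq_lengths = NULL) {
  pw <- promoter_window(genes, rule, seq_lengths)
  lo <- pmin(pw$start, genes$start)
  hi <- pmax(pw$end, genes$end)
  out <- genomic_interval(genes$seqid, lo, hi)
  cbind(data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE), out)
}

#' Read gene models from GFF3
#'
#' Consumes features of one type (default `"gene"`) and uses the `ID`
#' attribute as the gene identifier. Score and phase columns may be
#' missing. Features with strand other than `+`/`-` are rejected.
#'
#' @param path GFF3 file path.
#' @param feature_type feature type to keep (GFF3 column 3).
#' @return a `gene_model` data.frame.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", path)
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | ids == ""))
    stop("every ", feature_type, " feature needs an ID attribute: ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (!all(strand %in% c("+", "-")))
    stop("gene features must be stranded (+/-): ", path)
  gene_model(ids,
             as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr),
             BiocGenerics::end(gr),
             strand)
}

#' Scaffold lengths from a FASTA file
#'
#' @param path FASTA file.
#' @return named integer vector of sequence lengths.
#' @export
read_scaffold_lengths <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  sl <- Biostrings::fasta.seqlengths(path)
  names(sl) <- sub("\\s.*$", "", names(sl))   # bare seqids, as in GFF3
  sl
}
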