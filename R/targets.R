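#' Assign consensus peaks to direct target genes
#'
#' A gene is a direct target iff at least one consensus peak overlaps its
#' territory — the strand-aware promoter window united with the gene body
#' (see [gene_territory()]) — by at least `min_overlap_bp`. A peak that
#' overlaps several territories supports every one of them; there is no
#' nearest-gene tie-breaking, because the target definition is per-gene
#' existence of a peak, not a partition of peaks.
#'
#' @param peaks a `consensus_peaks` data.frame (or any data.frame with
#'   `peak_id`, `seqid`, `start`, `end`).
#' @param genes a `gene_model` data.frame with unique `gene_id`s.
#' @param rule a [promoter_rule()].
#' @param seq_lengths optional named scaffold lengths for window clipping.
#' @param min_overlap_bp minimum shared bases to count an overlap
#'   (default 1).
#' @return data.frame with class `target_calls`, sorted by `gene_id`:
#'   `gene_id`, `n_supporting_peaks`, `peak_ids` (comma-joined),
#'   `seqid`, `territory_start`, `territory_end`.
#' @export
assign_targets <- function(peaks, genes, rule = promoter_rule(),
                           seq_lengths = NULL, min_overlap_bp = 1L) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  terr <- gene_territory(genes, rule, seq_lengths)
  empty <- data.frame(gene_id = character(), n_supporting_peaks = integer(),
                      peak_ids = character(), seqid = character(),
                      territory_start = integer(), territory_end = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("target_calls", "data.frame")
  if (nrow(peaks) == 0L) return(empty)
  pk_gr <- GenomicRanges::GRanges(peaks$seqid,
                                  IRanges::IRanges(peaks$start, peaks$end))
  te_gr <- GenomicRanges::GRanges(terr$seqid,
                                  IRanges::IRanges(terr$start, terr$end))
  hits <- GenomicRanges::findOverlaps(pk_gr, te_gr,
                                      minoverlap = as.integer(min_overlap_bp))
  if (length(hits) == 0L) return(empty)
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  gi <- as.integer(names(by_gene))
  out <- data.frame(
    gene_id = terr$gene_id[gi],
    n_supporting_peaks = lengths(by_gene),
    peak_ids = vapply(by_gene, function(p)
      paste(sort(unique(peaks$peak_id[p])), collapse = ","), ""),
    seqid = terr$seqid[gi],
    territory_start = terr$start[gi],
    territory_end = terr$end[gi],
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_calls", "data.frame")
  out
}
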