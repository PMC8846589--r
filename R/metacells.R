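#' Construct a metacell footprint matrix
#'
#' Rows are genes, columns are metacells (transcriptomically defined
#' cell-type clusters), values are non-negative footprints. A gene is
#' "represented" in a metacell iff its footprint is strictly greater than
#' `represented_threshold` (default 0, i.e. any nonzero footprint); the
#' cutoff is configurable because published metacell gene assignments do
#' not always restate one.
#'
#' @param footprint numeric matrix with rownames (gene ids) and colnames
#'   (metacell ids), values >= 0.
#' @param represented_threshold strict lower bound for representation.
#' @return list with class `metacell_matrix`.
#' @export
metacell_matrix <- function(footprint, represented_threshold = 0) {
  if (!is.matrix(footprint) || is.null(rownames(footprint)) ||
      is.null(colnames(footprint)))
    stop("footprint must be a matrix with gene rownames and metacell colnames")
  if (anyDuplicated(rownames(footprint)) || anyDuplicated(colnames(footprint)))
    stop("gene and metacell ids must be unique")
  if (any(footprint < 0)) stop("footprint values must be >= 0")
  structure(list(footprint = footprint,
                 represented_threshold = represented_threshold),
            class = "metacell_matrix")
}

#' Read a metacell footprint table
#'
#' Tab-separated; first column is the gene id, remaining columns one per
#' metacell with non-negative values.
#'
#' @param path TSV file.
#' @inheritParams metacell_matrix
#' @return a `metacell_matrix`.
#' @export
read_metacell_matrix <- function(path, represented_threshold = 0) {
  if (!file.exists(path)) stop("metacell table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("metacell table needs gene_id plus >= 1 metacell")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  metacell_matrix(m, represented_threshold)
}

represented_in <- function(M, gene_ids) {
  fp <- M$footprint[intersect(gene_ids, rownames(M$footprint)), ,
                    drop = FALSE]
  fp > M$represented_threshold
}

#' Represented activated/repressed targets per metacell
#'
#' @param M a `metacell_matrix`.
#' @param classes a `target_classes` data.frame from [split_targets()].
#'   Gene ids absent from the matrix count as not represented anywhere.
#' @return named list, one element per metacell, each a list with
#'   character vectors `activated` and `repressed`.
#' @export
represented_targets <- function(M, classes) {
  act <- represented_in(M, classes$gene_id[classes$label == "activated"])
  rep_ <- represented_in(M, classes$gene_id[classes$label == "repressed"])
  stats::setNames(lapply(colnames(M$footprint), function(mc) {
    list(activated = sort(rownames(act)[act[, mc]]),
         repressed = sort(rownames(rep_)[rep_[, mc]]))
  }), colnames(M$footprint))
}

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Repression proportion of a cell type's regulon
#'
#' `100 * n_repressed / (n_activated + n_repressed)`, rounded half-up to
#' `decimals`. With zero represented targets the proportion is undefined
#' and `NA` is returned (not 0).
#'
#' @param n_activated,n_repressed non-negative counts.
#' @param decimals digits kept after rounding half-up.
#' @return percentage, or `NA` when both counts are zero.
#' @export
repression_proportion <- function(n_activated, n_repressed, decimals = 2) {
  total <- n_activated + n_repressed
  ifelse(total == 0, NA_real_,
         round_half_up(100 * n_repressed / total, decimals))
}

#' Genes exclusive to one metacell
#'
#' Genes of `gene_set` represented in `metacell_id` and in no other
#' metacell.
#'
#' @param M a `metacell_matrix`.
#' @param gene_set character vector of gene ids.
#' @param metacell_id metacell column to test.
#' @return sorted character vector of exclusive gene ids.
#' @export
exclusive_markers <- function(M, gene_set, metacell_id) {
  if (!metacell_id %in% colnames(M$footprint))
    stop("unknown metacell: ", metacell_id)
  rep_ <- represented_in(M, gene_set)
  if (nrow(rep_) == 0L) return(character())
  here <- rep_[, metacell_id]
  elsewhere <- rowSums(rep_[, colnames(rep_) != metacell_id, drop = FALSE]) > 0
  sort(rownames(rep_)[here & !elsewhere])
}

#' Per-metacell regulon summaries
#'
#' One row per metacell containing at least one represented target
#' (activated or repressed): counts, the repression proportion, and the
#' represented targets exclusive to that metacell.
#'
#' @param M a `metacell_matrix`.
#' @param classes a `target_classes` data.frame.
#' @param decimals digits for the repression percentage (default 2).
#' @return data.frame with class `regulon_summary`, sorted by metacell id:
#'   `metacell_id`, `n_activated`, `n_repressed`, `n_total`,
#'   `repression_pct`, `exclusive_genes` (comma-joined).
#' @export
summarize_regulons <- function(M, classes, decimals = 2) {
  rep_by_mc <- represented_targets(M, classes)
  target_ids <- classes$gene_id[classes$label %in% c("activated", "repressed")]
  rows <- lapply(names(rep_by_mc), function(mc) {
    sets <- rep_by_mc[[mc]]
    n_act <- length(sets$activated)
    n_rep <- length(sets$repressed)
    if (n_act + n_rep == 0L) return(NULL)
    data.frame(metacell_id = mc,
               n_activated = n_act,
               n_repressed = n_rep,
               n_total = n_act + n_rep,
               repression_pct = repression_proportion(n_act, n_rep, decimals),
               exclusive_genes = paste(
                 exclusive_markers(M, target_ids, mc), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metacell_id = character(), n_activated = integer(),
               n_repressed = integer(), n_total = integer(),
               repression_pct = numeric(), exclusive_genes = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$metacell_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regulon_summary", "data.frame")
  out
}
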