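#' Read a differential-expression table
#'
#' Tab-separated with a header naming at least `gene_id`, `log2fc`, and
#' `padj`. The fold-change convention is mutant relative to unperturbed
#' sibling, and `padj` is assumed already multiplicity-adjusted (e.g. BH)
#' upstream; no re-fitting or re-adjustment is performed here.
#'
#' @param path TSV file.
#' @return data.frame `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  de[need]
}

#' Classify differential expression into down/up gene sets
#'
#' With the mutant-vs-sibling sign convention, genes *down* in the mutant
#' (`log2fc < 0`) are candidates for direct activation by the factor, and
#' genes *up* in the mutant are candidates for direct repression. Both
#' inequalities are strict: `padj < alpha` and `log2fc != 0`; genes at
#' exactly `padj == alpha` or `log2fc == 0` fall in neither set. Records
#' with missing `padj` are excluded with a warning.
#'
#' @param de data.frame with `gene_id`, `log2fc`, `padj` (unique ids).
#' @param alpha adjusted-p threshold, default 0.01.
#' @return list with character vectors `down` and `up`.
#' @export
classify_de <- function(de, alpha = 0.01) {
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene ids in DE table")
  if (any(!is.finite(de$log2fc) & !is.na(de$log2fc)))
    stop("log2fc must be finite")
  if (anyNA(de$padj)) {
    warning(sum(is.na(de$padj)), " DE records with missing padj excluded")
    de <- de[!is.na(de$padj), , drop = FALSE]
  }
  if (any(de$padj < 0 | de$padj > 1)) stop("padj must lie in [0, 1]")
  sig <- de$padj < alpha
  list(down = de$gene_id[sig & de$log2fc < 0],
       up = de$gene_id[sig & de$log2fc > 0])
}

#' Split direct targets into activated / repressed / target-only
#'
#' Directly-activated genes are targets that are down in the mutant;
#' directly-repressed genes are targets up in the mutant; remaining
#' targets are `target_only` (bound but not differentially expressed at
#' the chosen threshold). The three labels partition the target set.
#'
#' @param targets a `target_calls` data.frame or character vector of
#'   target gene ids.
#' @param down_set,up_set disjoint character vectors from [classify_de()].
#' @return data.frame with class `target_classes`: `gene_id`, `label`.
#' @export
split_targets <- function(targets, down_set, up_set) {
  ids <- if (is.data.frame(targets)) targets$gene_id else targets
  if (length(intersect(down_set, up_set)))
    stop("down_set and up_set must be disjoint")
  label <- ifelse(ids %in% down_set, "activated",
                  ifelse(ids %in% up_set, "repressed", "target_only"))
  out <- data.frame(gene_id = ids, label = label, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_classes", "data.frame")
  out
}

#' Detect autoregulation of the factor's own locus
#'
#' Terminal selectors commonly feed back on their own promoter; a
#' repressed label on the factor's own gene indicates negative
#' autoregulation.
#'
#' @param tf_gene_id the factor's gene id.
#' @param classes a `target_classes` data.frame from [split_targets()].
#' @param gene_ids all known gene ids (from the gene models); the factor
#'   must be among them.
#' @return one of `"none"`, `"activates_self"`, `"represses_self"`.
#' @export
detect_autoregulation <- function(tf_gene_id, classes, gene_ids) {
  if (!tf_gene_id %in% gene_ids)
    stop("factor gene '", tf_gene_id, "' absent from gene models")
  row <- classes[classes$gene_id == tf_gene_id, , drop = FALSE]
  if (nrow(row) == 0L) return("none")
  switch(row$label[1L],
         activated = "activates_self",
         repressed = "represses_self",
         "none")
}
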