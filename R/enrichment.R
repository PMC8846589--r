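#' One-sided hypergeometric overrepresentation test
#'
#' Tests whether a selected gene set is enriched for members of a term.
#' With `k = |selected ∩ members|`, `K = |members ∩ universe|`,
#' `n = |selected|`, `N = |universe|`, returns the upper-tail probability
#' `P(X >= k)` of the hypergeometric distribution. Term members are
#' intersected with the universe before testing; `selected` must be a
#' subset of the universe.
#'
#' @param selected character vector of selected gene ids.
#' @param members character vector of term member gene ids.
#' @param universe character vector of all testable gene ids (non-empty).
#' @return p-value.
#' @export
hypergeom_overrep <- function(selected, members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  members <- intersect(unique(members), universe)
  k <- length(intersect(selected, members))
  stats::phyper(k - 1L, length(members),
                length(universe) - length(members),
                length(selected), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; output is elementwise >= input, capped at 1,
#' and permutation-equivariant. Not idempotent in general.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read term memberships from a two-column TSV
#'
#' Columns `term_id` and `gene_id` (header required); an optional second
#' file maps `term_id` to `term_name`.
#'
#' @param path membership TSV.
#' @param names_path optional TSV with `term_id`, `term_name`.
#' @return data.frame `term_id`, `gene_id`, `term_name`.
#' @export
read_term_memberships <- function(path, names_path = NULL) {
  if (!file.exists(path)) stop("term membership file not found: ", path)
  tm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(tm)))
    stop("term membership table needs columns term_id, gene_id: ", path)
  tm$term_name <- tm$term_id
  if (!is.null(names_path)) {
    nm <- utils::read.delim(names_path, stringsAsFactors = FALSE)
    idx <- match(tm$term_id, nm$term_id)
    tm$term_name[!is.na(idx)] <- nm$term_name[idx[!is.na(idx)]]
  }
  tm[c("term_id", "gene_id", "term_name")]
}

#' Overrepresentation testing of a gene set across terms
#'
#' Runs [hypergeom_overrep()] per term and BH-adjusts across terms.
#'
#' @param selected character vector of selected gene ids (subset of
#'   universe).
#' @param terms data.frame from [read_term_memberships()] (columns
#'   `term_id`, `gene_id`, optional `term_name`).
#' @param universe all testable gene ids; a sensible default is every gene
#'   in the gene-model file.
#' @param alpha adjusted-p significance threshold for the `significant`
#'   flag (default 0.05).
#' @return data.frame sorted by p: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `padj`, `significant`.
#' @export
enrich_terms <- function(selected, terms, universe, alpha = 0.05) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (is.null(terms$term_name)) terms$term_name <- terms$term_id
  by_term <- split(terms$gene_id, terms$term_id)
  name_of <- tapply(terms$term_name, terms$term_id, `[`, 1L)
  rows <- lapply(names(by_term), function(tid) {
    members <- intersect(unique(by_term[[tid]]), universe)
    data.frame(term_id = tid,
               term_name = unname(name_of[tid]),
               k = length(intersect(selected, members)),
               K = length(members),
               n = length(selected),
               N = length(universe),
               p = hypergeom_overrep(selected, members, universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out$significant <- out$padj < alpha
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
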