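#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, chromStart, chromEnd, name, score, strand,
#' signalValue, -log10(pValue), -log10(qValue), summit offset. Coordinates
#' are converted from 0-based half-open to the package's 1-based inclusive
#' convention (`start + 1`, `end`). Missing optional columns default to
#' score 0, signal 0, p/q 0 and summit -1 (absent).
#'
#' @param path narrowPeak file path.
#' @param replicate_id label attached to every peak; defaults to the file
#'   name without extension.
#' @return data.frame with class `peak_set`: `seqid`, `start`, `end`,
#'   `name`, `score`, `strand`, `signal`, `neglog10_p`, `neglog10_q`,
#'   `summit_offset`, `replicate_id`.
#' @export
read_narrowpeak <- function(path, replicate_id = NULL) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  if (is.null(replicate_id))
    replicate_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_peak_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3L)
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": fewer than 3 columns")
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  start0 <- suppressWarnings(as.integer(get_col(2L, NA)))
  end0 <- suppressWarnings(as.integer(get_col(3L, NA)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": non-numeric coordinates")
  bad <- which(end0 <= start0)
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": end <= start")
  num_col <- function(i) {
    x <- suppressWarnings(as.numeric(get_col(i, "0")))
    x[is.na(x)] <- 0
    x
  }
  summit <- suppressWarnings(as.integer(get_col(10L, "-1")))
  summit[is.na(summit)] <- -1L
  pk <- data.frame(
    seqid = get_col(1L, ""),
    start = start0 + 1L,
    end = end0,
    name = get_col(4L, "."),
    score = num_col(5L),
    strand = get_col(6L, "."),
    signal = num_col(7L),
    neglog10_p = num_col(8L),
    neglog10_q = num_col(9L),
    summit_offset = summit,
    replicate_id = replicate_id,
    stringsAsFactors = FALSE)
  if (any(pk$neglog10_p < 0))
    stop("negative -log10 p-value in ", path)
  len <- pk$end - pk$start + 1L
  bad <- which(pk$summit_offset > len - 1L)
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], " in ", path,
         ": summit offset beyond peak end")
  class(pk) <- c("peak_set", "data.frame")
  pk
}

empty_peak_set <- function() {
  pk <- data.frame(seqid = character(), start = integer(), end = integer(),
                   name = character(), score = numeric(),
                   strand = character(), signal = numeric(),
                   neglog10_p = numeric(), neglog10_q = numeric(),
                   summit_offset = integer(), replicate_id = character(),
                   stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' Write peaks as narrowPeak
#'
#' Converts back to 0-based half-open coordinates on write.
#'
#' @param peaks a `peak_set`-shaped data.frame (1-based inclusive).
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   peaks$seqid, peaks$start - 1L, peaks$end,
                   if (is.null(peaks$name)) "." else peaks$name,
                   as.integer(round(peaks$score %||% 0)),
                   peaks$strand %||% ".",
                   format_num(peaks$signal %||% 0),
                   format_num(peaks$neglog10_p %||% 0),
                   format_num(peaks$neglog10_q %||% 0),
                   as.integer(peaks$summit_offset %||% -1L))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_num <- function(x) formatC(x, format = "g", digits = 6)

#' Consensus-calling configuration
#'
#' The weak/strong thresholds mirror the two-tier test used by
#' multi-sample peak consensus tools run as `-w 1e-4 -s 1e-8`: every member
#' peak of a candidate group must pass the weak threshold, and the group's
#' Fisher-combined p-value must pass the strong threshold.
#'
#' @param weak_threshold per-member p-value ceiling.
#' @param strong_threshold combined p-value ceiling; must be <= weak.
#' @param min_supporting_replicates minimum number of distinct replicates
#'   represented in a confirmed group.
#' @return list with class `consensus_config`.
#' @export
consensus_config <- function(weak_threshold = 1e-4,
                             strong_threshold = 1e-8,
                             min_supporting_replicates = 1L) {
  if (strong_threshold > weak_threshold)
    stop("strong_threshold must be <= weak_threshold")
  if (min_supporting_replicates < 0L)
    stop("min_supporting_replicates must be >= 0")
  structure(list(weak_threshold = weak_threshold,
                 strong_threshold = strong_threshold,
                 min_supporting_replicates =
                   as.integer(min_supporting_replicates)),
            class = "consensus_config")
}

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom; the upper-tail probability is returned. A
#' single p-value is returned unchanged (chi-square identity with 2 df).
#' Zero p-values are clamped to the smallest positive double with a
#' warning.
#'
#' @param pvalues numeric vector in `(0, 1]`, non-empty.
#' @return combined p-value.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("need at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(pvalues))
  stats::pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Build consensus peaks across replicates
#'
#' Candidate groups are maximal sets of transitively overlapping peaks
#' across all replicates (>= 1 bp overlap, per seqid). A group is
#' confirmed iff (a) its Fisher-combined p-value is <= the strong
#' threshold, (b) every member peak's p-value is <= the weak threshold,
#' and (c) it is supported by at least `min_supporting_replicates`
#' distinct replicates. Confirmed groups are emitted with the union
#' interval of their members, sorted by seqid then start. The result is
#' invariant to the order of replicate sets and of peaks within them.
#'
#' @param replicate_sets list of `peak_set` data.frames, one per
#'   replicate (or a single `peak_set`).
#' @param cfg a [consensus_config()].
#' @return data.frame with class `consensus_peaks`: `peak_id`, `seqid`,
#'   `start`, `end`, `combined_neglog10_p`, `n_replicates_supporting`,
#'   `n_member_peaks`, `member_peaks` (comma-joined
#'   `replicate_id:seqid:start-end` labels).
#' @export
build_consensus <- function(replicate_sets, cfg = consensus_config()) {
  if (inherits(replicate_sets, "data.frame"))
    replicate_sets <- list(replicate_sets)
  if (length(replicate_sets) == 0L) stop("need at least one replicate set")
  all_pk <- do.call(rbind, lapply(replicate_sets, as.data.frame))
  if (is.null(all_pk) || nrow(all_pk) == 0L) return(empty_consensus())
  gr <- GenomicRanges::GRanges(all_pk$seqid,
                               IRanges::IRanges(all_pk$start, all_pk$end))
  merged <- GenomicRanges::reduce(gr)   # transitive closure of overlaps
  hit <- GenomicRanges::findOverlaps(gr, merged)
  grp <- integer(nrow(all_pk))
  grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  rows <- lapply(split(seq_len(nrow(all_pk)), grp), function(idx) {
    members <- all_pk[idx, , drop = FALSE]
    p <- 10^(-members$neglog10_p)
    if (any(p > cfg$weak_threshold)) return(NULL)
    combined <- fisher_combine(p)
    if (combined > cfg$strong_threshold) return(NULL)
    n_rep <- length(unique(members$replicate_id))
    if (n_rep < cfg$min_supporting_replicates) return(NULL)
    data.frame(seqid = members$seqid[1L],
               start = min(members$start),
               end = max(members$end),
               combined_neglog10_p = -log10(max(combined,
                                                .Machine$double.xmin)),
               n_replicates_supporting = n_rep,
               n_member_peaks = nrow(members),
               member_peaks = paste(
                 sort(sprintf("%s:%s:%d-%d", members$replicate_id,
                              members$seqid, members$start, members$end)),
                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty_consensus())
  out <- do.call(rbind, rows)
  out <- out[order(out$seqid, out$start, out$end), , drop = FALSE]
  out <- cbind(data.frame(peak_id = sprintf("cons_%04d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  class(out) <- c("consensus_peaks", "data.frame")
  out
}

empty_consensus <- function() {
  out <- data.frame(peak_id = character(), seqid = character(),
                    start = integer(), end = integer(),
                    combined_neglog10_p = numeric(),
                    n_replicates_supporting = integer(),
                    n_member_peaks = integer(),
                    member_peaks = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_peaks", "data.frame")
  out
}

#' Write consensus peaks as narrowPeak plus an audit table
#'
#' @param consensus a `consensus_peaks` data.frame.
#' @param prefix output path prefix; writes `<prefix>.narrowPeak` and
#'   `<prefix>_audit.tsv`.
#' @return invisible character vector of the two paths.
#' @export
write_consensus <- function(consensus, prefix) {
  n <- nrow(consensus)
  np <- data.frame(seqid = consensus$seqid, start = consensus$start,
                   end = consensus$end, name = consensus$peak_id,
                   score = pmin(1000, round(consensus$combined_neglog10_p * 10)),
                   strand = rep(".", n), signal = rep(0, n),
                   neglog10_p = consensus$combined_neglog10_p,
                   neglog10_q = rep(0, n), summit_offset = rep(-1L, n),
                   stringsAsFactors = FALSE)
  np_path <- paste0(prefix, ".narrowPeak")
  write_narrowpeak(np, np_path)
  audit_path <- paste0(prefix, "_audit.tsv")
  write_tsv(consensus, audit_path)
  invisible(c(np_path, audit_path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
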