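# Independent oracles used across tests. These deliberately avoid the code
# paths of the package: motif matching is done by regex over exhaustively
# enumerated windows, grouping and target assignment by brute-force double
# loops, and BH by the literal step-up recursion.

IUPAC_ORACLE <- c(A = "A", C = "C", G = "G", T = "T",
                  M = "[AC]", R = "[AG]", W = "[AT]", S = "[CG]",
                  Y = "[CT]", K = "[GT]", V = "[ACG]", H = "[ACT]",
                  D = "[AGT]", B = "[CGT]", N = "[ACGT]")

motif_regex <- function(consensus) {
  paste(IUPAC_ORACLE[strsplit(consensus, "")[[1L]]], collapse = "")
}

rc_oracle <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# every window tested explicitly on both strands; N never matches because
# the character classes contain only A/C/G/T
oracle_scan <- function(seq, consensus, both_strands = TRUE) {
  w <- nchar(consensus)
  rx <- paste0("^", motif_regex(consensus), "$")
  rows <- list()
  for (i in seq_len(max(nchar(seq) - w + 1L, 0L))) {
    win <- substr(seq, i, i + w - 1L)
    if (grepl(rx, win))
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, strand = "+", matched_seq = win,
        stringsAsFactors = FALSE)
    if (both_strands && grepl(rx, rc_oracle(win)))
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, strand = "-", matched_seq = win,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), strand = character(),
               matched_seq = character(), stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force transitive closure of pairwise interval overlap
oracle_groups <- function(peaks) {
  n <- nrow(peaks)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] &&
          peaks$seqid[i] == peaks$seqid[j] &&
          peaks$start[i] <= peaks$end[j] &&
          peaks$start[j] <= peaks$end[i]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# brute-force consensus: enumerate groups, apply the three rules literally
oracle_consensus <- function(peaks, weak = 1e-4, strong = 1e-8,
                             min_reps = 1L) {
  if (nrow(peaks) == 0L) return(peaks[0, c("seqid", "start", "end")])
  grp <- oracle_groups(peaks)
  rows <- list()
  for (g in unique(grp)) {
    mem <- peaks[grp == g, , drop = FALSE]
    p <- 10^(-mem$neglog10_p)
    x <- -2 * sum(log(p))
    comb <- pchisq(x, df = 2 * length(p), lower.tail = FALSE)
    if (all(p <= weak) && comb <= strong &&
        length(unique(mem$replicate_id)) >= min_reps)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = mem$seqid[1L], start = min(mem$start), end = max(mem$end),
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  out[order(out$seqid, out$start, out$end), , drop = FALSE]
}

# brute-force target assignment: double loop over (gene, peak)
oracle_targets <- function(peaks, genes, up = 350L, down = 100L) {
  hits <- character()
  for (gi in seq_len(nrow(genes))) {
    t <- if (genes$strand[gi] == "+") genes$start[gi] else genes$end[gi]
    lo <- if (genes$strand[gi] == "+") t - up else t - down
    hi <- if (genes$strand[gi] == "+") t + down else t + up
    lo <- max(1L, min(lo, genes$start[gi]))
    hi <- max(hi, genes$end[gi])
    for (pi in seq_len(nrow(peaks))) {
      if (peaks$seqid[pi] == genes$seqid[gi] &&
          peaks$start[pi] <= hi && lo <= peaks$end[pi]) {
        hits <- c(hits, genes$gene_id[gi])
        break
      }
    }
  }
  sort(hits)
}

# literal BH step-up recursion
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  adj[n] <- sorted[n]
  for (i in seq(n - 1L, length.out = n - 1L, by = -1L))
    adj[i] <- min(adj[i + 1L], sorted[i] * n / i)
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive hypergeometric upper tail by enumerating all draws
oracle_hyper <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # members are items 1..K
  mean(hits >= k)
}

make_genes <- function(n, seqid = "s1", spacing = 5000L, len = 1000L,
                       strand = NULL) {
  start <- seq(1000L, by = spacing, length.out = n)
  gene_model(sprintf("g%03d", seq_len(n)), seqid, start, start + len - 1L,
             strand %||% sample(c("+", "-"), n, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
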