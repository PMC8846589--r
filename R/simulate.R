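#' Configuration for the synthetic-study generator
#'
#' Defaults state a small but complete regulon study: 200 genes on five
#' 200-kb scaffolds, 60 factor-bound genes of which half are activated and
#' a quarter repressed, three ChIP replicates (the replicate count of the
#' emulated design), the extended binding consensus GCATWATTWAT planted at
#' peak summits, decoy peaks confined to intergenic space, and a metacell
#' table with one activation-skewed and one repression-skewed cell type.
#'
#' @param seed integer seed; every output file derives from the one
#'   pseudo-random stream it keys.
#' @param n_scaffolds,scaffold_length_bp genome shape.
#' @param n_genes,gene_length_range gene count and span lengths (bp).
#' @param n_replicates ChIP replicate count.
#' @param n_true_bound_genes genes receiving a planted binding site.
#' @param frac_activated,frac_repressed fractions of bound genes planted
#'   as directly activated / repressed (sum <= 1; the remainder are bound
#'   but not differentially expressed).
#' @param motif consensus planted at peak summits (IUPAC or parenthetical).
#' @param peak_width_range per-replicate peak widths (bp).
#' @param motif_plant_prob probability a bound gene's site carries a
#'   literal motif instance (default 1).
#' @param summit_jitter_bp peak centers jitter by up to this many bp
#'   around the planted motif, so the central-enrichment statistic is
#'   exercised with signal.
#' @param n_decoy_peaks weak intergenic peaks that must not survive
#'   consensus calling.
#' @param n_metacells metacell count (>= 3: activation-skewed,
#'   repression-skewed, plus background).
#' @param n_exclusive_markers activated genes represented only in the
#'   activation-skewed metacell.
#' @param de_effect_log2fc planted absolute log2 fold change (mutant vs
#'   sibling; activated genes go down in the mutant).
#' @param de_null_padj_floor smallest adjusted p given to non-regulated
#'   genes (default 0.5, far from the 0.01 calling threshold).
#' @return list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 5L,
                       scaffold_length_bp = 200000L,
                       n_genes = 200L,
                       gene_length_range = c(1000L, 3000L),
                       n_replicates = 3L,
                       n_true_bound_genes = 60L,
                       frac_activated = 0.5,
                       frac_repressed = 0.25,
                       motif = "GCATWATTWAT",
                       peak_width_range = c(150L, 400L),
                       motif_plant_prob = 1,
                       summit_jitter_bp = 10L,
                       n_decoy_peaks = 100L,
                       n_metacells = 8L,
                       n_exclusive_markers = 3L,
                       de_effect_log2fc = 3,
                       de_null_padj_floor = 0.5) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length_bp = as.integer(scaffold_length_bp),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_replicates = as.integer(n_replicates),
              n_true_bound_genes = as.integer(n_true_bound_genes),
              frac_activated = frac_activated,
              frac_repressed = frac_repressed,
              motif = motif,
              peak_width_range = as.integer(peak_width_range),
              motif_plant_prob = motif_plant_prob,
              summit_jitter_bp = as.integer(summit_jitter_bp),
              n_decoy_peaks = as.integer(n_decoy_peaks),
              n_metacells = as.integer(n_metacells),
              n_exclusive_markers = as.integer(n_exclusive_markers),
              de_effect_log2fc = de_effect_log2fc,
              de_null_padj_floor = de_null_padj_floor)
  if (cfg$frac_activated < 0 || cfg$frac_repressed < 0 ||
      cfg$frac_activated + cfg$frac_repressed > 1)
    stop("frac_activated/frac_repressed must be >= 0 and sum to <= 1")
  if (cfg$motif_plant_prob < 0 || cfg$motif_plant_prob > 1)
    stop("motif_plant_prob must lie in [0, 1]")
  if (cfg$n_metacells < 3L)
    stop("need >= 3 metacells (activation-skewed, repression-skewed, background)")
  if (cfg$n_true_bound_genes > cfg$n_genes)
    stop("n_true_bound_genes exceeds n_genes")
  structure(cfg, class = "sim_config")
}

#' Generate a complete synthetic regulon study
#'
#' Writes, under `out_dir`: `genome.fa` (uniform-random bases with planted
#' motif instances), `genes.gff3` (non-overlapping stranded genes),
#' `rep<i>.narrowPeak` (one strong peak per bound gene per replicate,
#' centered on the planted motif up to summit jitter, plus weak intergenic
#' decoys), `de.tsv` (mutant-vs-sibling log2 fold changes; planted
#' activated genes strongly negative, repressed strongly positive, all
#' effects far from the calling thresholds), `metacells.tsv`, and
#' `truth.json` (machine-readable planted ground truth). Running twice
#' with the same config yields byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with `truth`, `paths`, and `config`.
#' @export
simulate_study <- function(cfg = sim_config(), out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rule <- promoter_rule()
  motif <- as_motif(cfg$motif)
  w <- nchar(motif$consensus)
  max_pw <- max(cfg$peak_width_range)
  edge_margin <- max_pw + rule$upstream_bp + 50L

  sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

  # --- feasibility: genes are packed one per slot with edge margins
  genes_per_scaf <- ceiling(cfg$n_genes / cfg$n_scaffolds)
  slot <- cfg$scaffold_length_bp %/% max(genes_per_scaf, 1L)
  if (cfg$n_genes > 0L &&
      slot < max(cfg$gene_length_range) + 2L * edge_margin)
    stop("infeasible packing: ", cfg$n_genes, " genes of up to ",
         max(cfg$gene_length_range), " bp do not fit ", cfg$n_scaffolds,
         " x ", cfg$scaffold_length_bp, " bp scaffolds with margins")

  scaf_ids <- sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))
  genome <- lapply(scaf_ids, function(s)
    paste(sample(c("A", "C", "G", "T"), cfg$scaffold_length_bp,
                 replace = TRUE), collapse = ""))
  names(genome) <- scaf_ids

  # --- gene placement
  gene_rows <- vector("list", cfg$n_genes)
  g <- 0L
  for (si in seq_len(cfg$n_scaffolds)) {
    for (sj in seq_len(genes_per_scaf)) {
      if (g >= cfg$n_genes) break
      g <- g + 1L
      len <- sample1(seq(cfg$gene_length_range[1L],
                         cfg$gene_length_range[2L]))
      slot_start <- (sj - 1L) * slot + 1L
      lo <- slot_start + edge_margin
      hi <- slot_start + slot - len - edge_margin
      start <- if (hi > lo) lo + sample.int(hi - lo, 1L) else lo
      gene_rows[[g]] <- data.frame(
        gene_id = sprintf("g%04d", g), seqid = scaf_ids[si],
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  genes <- gene_model(genes$gene_id, genes$seqid, genes$start, genes$end,
                      genes$strand)
  terr <- gene_territory(genes, rule)

  # --- planted regulon
  bound <- if (cfg$n_true_bound_genes > 0L)
    sort(sample(genes$gene_id, cfg$n_true_bound_genes)) else character()
  n_act <- round(cfg$frac_activated * length(bound))
  n_rep <- round(cfg$frac_repressed * length(bound))
  activated <- sort(sample(bound, n_act))
  repressed <- sort(sample(setdiff(bound, activated), n_rep))

  # --- motif planting and true peaks (one site per bound gene)
  expansions <- expand_iupac(motif)
  motif_rows <- list()
  true_peaks <- list()
  for (gid in bound) {
    ti <- which(terr$gene_id == gid)
    m_start <- terr$start[ti] +
      sample.int(interval_length(terr[ti, ]) - w + 1L, 1L) - 1L
    planted <- stats::runif(1L) < cfg$motif_plant_prob
    strand <- sample(c("+", "-"), 1L)
    if (planted) {
      inst <- sample(expansions, 1L)
      fwd <- if (strand == "+") inst else revcomp(inst)
      substr(genome[[terr$seqid[ti]]], m_start, m_start + w - 1L) <- fwd
      motif_rows[[gid]] <- data.frame(
        gene_id = gid, seqid = terr$seqid[ti], start = m_start,
        strand = strand, seq = fwd, stringsAsFactors = FALSE)
    }
    m_center <- m_start + (w - 1L) %/% 2L
    for (r in seq_len(cfg$n_replicates)) {
      pw <- sample1(seq(cfg$peak_width_range[1L], cfg$peak_width_range[2L]))
      jit <- sample1(seq(-cfg$summit_jitter_bp, cfg$summit_jitter_bp))
      center <- m_center + jit
      p_start <- max(1L, center - pw %/% 2L)
      true_peaks[[paste(gid, r)]] <- data.frame(
        seqid = terr$seqid[ti], start = p_start, end = p_start + pw - 1L,
        name = sprintf("true_%s_r%d", gid, r),
        score = 0, strand = ".", signal = stats::runif(1L, 5, 50),
        neglog10_p = stats::runif(1L, 10, 20), neglog10_q = 0,
        summit_offset = m_center - p_start, replicate_id = sprintf("rep%d", r),
        stringsAsFactors = FALSE)
    }
  }

  # --- decoy peaks: weak, strictly intergenic (never near a territory)
  decoys <- list()
  if (cfg$n_decoy_peaks > 0L) {
    forbidden <- GenomicRanges::reduce(GenomicRanges::GRanges(
      terr$seqid, IRanges::IRanges(pmax(1L, terr$start - max_pw),
                                   terr$end + max_pw)))
    whole <- GenomicRanges::GRanges(
      scaf_ids, IRanges::IRanges(max_pw + 1L,
                                 cfg$scaffold_length_bp - max_pw))
    allowed <- suppressWarnings(GenomicRanges::setdiff(whole, forbidden))
    allowed <- allowed[BiocGenerics::width(allowed) > 2L * max_pw]
    if (length(allowed) == 0L)
      stop("infeasible packing: no intergenic space left for decoy peaks")
    awidth <- BiocGenerics::width(allowed)
    pick <- sample(length(allowed), cfg$n_decoy_peaks,
                   replace = TRUE, prob = awidth)
    for (d in seq_len(cfg$n_decoy_peaks)) {
      iv <- allowed[pick[d]]
      pw <- sample1(seq(cfg$peak_width_range[1L], cfg$peak_width_range[2L]))
      lo <- BiocGenerics::start(iv) + max_pw %/% 2L
      hi <- BiocGenerics::end(iv) - pw - max_pw %/% 2L
      p_start <- if (hi > lo) lo + sample.int(hi - lo, 1L) else lo
      decoys[[d]] <- data.frame(
        seqid = as.character(GenomicRanges::seqnames(iv)),
        start = p_start, end = p_start + pw - 1L,
        name = sprintf("decoy_%04d", d), score = 0, strand = ".",
        signal = stats::runif(1L, 1, 5),
        neglog10_p = stats::runif(1L, 2, 3.5), neglog10_q = 0,
        summit_offset = pw %/% 2L,
        replicate_id = sprintf("rep%d", sample.int(cfg$n_replicates, 1L)),
        stringsAsFactors = FALSE)
    }
  }
  pieces <- c(true_peaks, decoys)
  all_peaks <- if (length(pieces)) do.call(rbind, pieces) else
    as.data.frame(empty_peak_set())

  # --- DE table (all genes; planted effects far from the 0.01 threshold)
  de <- data.frame(gene_id = genes$gene_id,
                   log2fc = round(stats::rnorm(cfg$n_genes, 0, 0.2), 4),
                   padj = round(stats::runif(cfg$n_genes,
                                             cfg$de_null_padj_floor, 1), 4),
                   stringsAsFactors = FALSE)
  ia <- de$gene_id %in% activated
  ir <- de$gene_id %in% repressed
  de$log2fc[ia] <- -round(cfg$de_effect_log2fc +
                            stats::runif(sum(ia), 0, 0.5), 4)
  de$log2fc[ir] <- round(cfg$de_effect_log2fc +
                           stats::runif(sum(ir), 0, 0.5), 4)
  de$padj[ia | ir] <- signif(10^-stats::runif(sum(ia | ir), 5, 9), 4)

  # --- metacell matrix
  mc_ids <- sprintf("mc%02d", seq_len(cfg$n_metacells))
  act_mc <- mc_ids[1L]   # activation-skewed (hair-cell-like)
  rep_mc <- mc_ids[2L]   # repression-skewed (cnidocyte-like)
  bg_mc <- mc_ids[-(1:2)]
  n_excl <- min(cfg$n_exclusive_markers, length(activated))
  exclusives <- sort(sample(activated, n_excl))
  shared_act <- setdiff(activated, exclusives)
  member <- matrix(FALSE, nrow = cfg$n_genes, ncol = cfg$n_metacells,
                   dimnames = list(genes$gene_id, mc_ids))
  member[activated, act_mc] <- TRUE
  member[repressed, rep_mc] <- TRUE
  if (length(repressed))   # slight repressed presence in the activated type
    member[sample(repressed, min(2L, length(repressed))), act_mc] <- TRUE
  if (length(shared_act))  # slight activated presence in the repressed type
    member[sample(shared_act, min(3L, length(shared_act))), rep_mc] <- TRUE
  for (gid in shared_act)  # break exclusivity of non-planted markers
    member[gid, sample(bg_mc, 1L)] <- TRUE
  nontargets <- setdiff(genes$gene_id, bound)
  for (mc in bg_mc) {
    n_bg <- min(25L, length(nontargets))
    if (n_bg > 0L) member[sample(nontargets, n_bg), mc] <- TRUE
  }
  footprint <- matrix(0, nrow = cfg$n_genes, ncol = cfg$n_metacells,
                      dimnames = dimnames(member))
  footprint[member] <- round(stats::runif(sum(member), 0.2, 1), 3)

  # --- truth record (derived from what was actually planted/written)
  class_of <- function(ids, set) sort(intersect(ids, set))
  per_mc <- lapply(mc_ids, function(mc) {
    rep_here <- rownames(footprint)[footprint[, mc] > 0]
    list(activated = class_of(rep_here, activated),
         repressed = class_of(rep_here, repressed))
  })
  names(per_mc) <- mc_ids
  target_cls <- c(activated, repressed)
  excl_mc <- lapply(mc_ids, function(mc) {
    rep_t <- footprint[intersect(target_cls, rownames(footprint)), ,
                       drop = FALSE] > 0
    if (nrow(rep_t) == 0L) return(character())
    sort(rownames(rep_t)[rep_t[, mc] &
                           rowSums(rep_t[, colnames(rep_t) != mc,
                                         drop = FALSE]) == 0])
  })
  names(excl_mc) <- mc_ids
  motif_df <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(gene_id = character(), seqid = character(),
               start = integer(), strand = character(), seq = character(),
               stringsAsFactors = FALSE)
  rownames(motif_df) <- NULL
  truth <- list(seed = cfg$seed,
                motif = motif$consensus,
                bound_genes = bound,
                activated_genes = activated,
                repressed_genes = repressed,
                target_only_genes = sort(setdiff(bound,
                                                 c(activated, repressed))),
                activation_metacell = act_mc,
                repression_metacell = rep_mc,
                represented = per_mc,
                exclusive_markers = excl_mc,
                motif_positions = motif_df)

  # --- write files
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                gff = file.path(out_dir, "genes.gff3"),
                peaks = file.path(out_dir,
                                  sprintf("rep%d.narrowPeak",
                                          seq_len(cfg$n_replicates))),
                de = file.path(out_dir, "de.tsv"),
                metacells = file.path(out_dir, "metacells.tsv"),
                truth = file.path(out_dir, "truth.json"))
  gset <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(gset, paths$genome, width = 80L)
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", scaf_ids,
                   cfg$scaffold_length_bp),
           sprintf("%s\tregulonscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$seqid, genes$start, genes$end, genes$strand,
                   genes$gene_id))
  writeLines(gff, paths$gff)
  for (r in seq_len(cfg$n_replicates)) {
    rid <- sprintf("rep%d", r)
    pk <- all_peaks[all_peaks$replicate_id == rid, , drop = FALSE]
    pk <- pk[order(pk$seqid, pk$start), , drop = FALSE]
    write_narrowpeak(pk, paths$peaks[r])
  }
  writeLines(c("gene_id\tlog2fc\tpadj",
               sprintf("%s\t%.4f\t%s", de$gene_id, de$log2fc,
                       formatC(de$padj, format = "g", digits = 6))),
             paths$de)
  writeLines(c(paste(c("gene_id", mc_ids), collapse = "\t"),
               vapply(seq_len(nrow(footprint)), function(i)
                 paste(c(rownames(footprint)[i],
                         formatC(footprint[i, ], format = "g", digits = 6)),
                       collapse = "\t"), "")),
             paths$metacells)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(truth = truth, paths = paths, config = cfg))
}

#' Planted motif positions as a BED-convertible table
#'
#' @param truth the `truth` element returned by [simulate_study()], or the
#'   list read back from `truth.json`.
#' @return data.frame `gene_id`, `seqid`, `start`, `strand`, `seq`.
#' @export
planted_motif_positions <- function(truth) {
  mp <- truth$motif_positions
  as.data.frame(mp, stringsAsFactors = FALSE)
}
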