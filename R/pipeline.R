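#' Run the full regulon pipeline
#'
#' Orchestrates consensus calling, motif scanning with central-enrichment
#' testing, peak-to-gene target assignment, activated/repressed
#' classification, metacell integration, and (optionally) term
#' overrepresentation. Each stage writes a TSV under `out_dir` so any
#' stage's output can be inspected or replaced by real data; a manifest
#' (JSON) and a human-readable report are written at the end. A failing
#' stage aborts with the stage name; outputs written so far are kept with
#' a `.partial` marker file alongside.
#'
#' @param peak_files character vector of per-replicate narrowPeak paths.
#' @param gff_file gene-model GFF3.
#' @param genome_fasta genome FASTA (used for motif scanning in consensus
#'   peaks and for scaffold-edge clipping).
#' @param de_file differential-expression TSV (`gene_id`, `log2fc`,
#'   `padj`; mutant vs sibling).
#' @param metacell_file metacell footprint TSV.
#' @param out_dir output directory.
#' @param motif binding consensus to scan for (IUPAC or parenthetical).
#' @param tf_gene_id optional gene id of the factor itself, for the
#'   autoregulation call.
#' @param rule a [promoter_rule()].
#' @param consensus_cfg a [consensus_config()].
#' @param alpha DE adjusted-p threshold (default 0.01).
#' @param central_fraction central window fraction for the enrichment
#'   test (default 0.2).
#' @param represented_threshold metacell representation cutoff.
#' @param terms_file optional term-membership TSV for enrichment of the
#'   activated and repressed sets.
#' @param feature_type GFF3 feature type holding gene models.
#' @param verbose log stage progress and row counts to stderr.
#' @return a list of class `regulon_report` (counts, per-stage tables,
#'   paths); see `print.regulon_report`.
#' @export
run_regulon_pipeline <- function(peak_files, gff_file, genome_fasta,
                                 de_file, metacell_file, out_dir,
                                 motif = "GCATWATTWAT",
                                 tf_gene_id = NULL,
                                 rule = promoter_rule(),
                                 consensus_cfg = consensus_config(),
                                 alpha = 0.01,
                                 central_fraction = 0.2,
                                 represented_threshold = 0,
                                 terms_file = NULL,
                                 feature_type = "gene",
                                 verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[regulonscan] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0(name, ".partial")))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (f in c(peak_files, gff_file, genome_fasta, de_file, metacell_file))
    if (!file.exists(f)) stop("input file not found: ", f)

  manifest <- list(inputs = list(peaks = peak_files, gff = gff_file,
                                 genome = genome_fasta, de = de_file,
                                 metacells = metacell_file,
                                 terms = terms_file),
                   parameters = list(
                     motif = as_motif(motif)$consensus,
                     upstream_bp = rule$upstream_bp,
                     downstream_bp = rule$downstream_bp,
                     weak_threshold = consensus_cfg$weak_threshold,
                     strong_threshold = consensus_cfg$strong_threshold,
                     min_supporting_replicates =
                       consensus_cfg$min_supporting_replicates,
                     alpha = alpha,
                     central_fraction = central_fraction,
                     represented_threshold = represented_threshold),
                   package_version =
                     as.character(utils::packageVersion("regulonscan")),
                   counts = list())

  # consensus
  consensus <- stage("consensus", {
    reps <- lapply(peak_files, read_narrowpeak)
    build_consensus(reps, consensus_cfg)
  })
  write_consensus(consensus, file.path(out_dir, "consensus"))
  manifest$counts$consensus_peaks <- nrow(consensus)
  say("consensus: ", nrow(consensus), " peaks")

  # gene models + territories
  genes <- stage("genes", read_gene_models(gff_file, feature_type))
  seq_lengths <- stage("genes", read_scaffold_lengths(genome_fasta))
  manifest$counts$genes <- nrow(genes)

  # motif scan within consensus peaks + central enrichment
  scan_res <- stage("scan", {
    m <- as_motif(motif)
    w <- nchar(m$consensus)
    genome <- Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    hits_list <- lapply(seq_len(nrow(consensus)), function(i) {
      s <- Biostrings::subseq(genome[[consensus$seqid[i]]],
                              consensus$start[i], consensus$end[i])
      h <- scan_sequence(s, m)
      if (nrow(h) == 0L) return(NULL)
      data.frame(peak_id = consensus$peak_id[i],
                 seqid = consensus$seqid[i],
                 start = consensus$start[i] + h$start - 1L,
                 strand = h$strand, matched_seq = h$matched_seq,
                 window_start = consensus$start[i],
                 window_end = consensus$end[i],
                 stringsAsFactors = FALSE)
    })
    hits_list <- hits_list[!vapply(hits_list, is.null, TRUE)]
    hits <- if (length(hits_list)) do.call(rbind, hits_list) else
      data.frame(peak_id = character(), seqid = character(),
                 start = integer(), strand = character(),
                 matched_seq = character(), window_start = integer(),
                 window_end = integer(), stringsAsFactors = FALSE)
    cent <- central_enrichment_test(hits$start + (w - 1) / 2,
                                    hits$window_start, hits$window_end,
                                    central_fraction)
    list(hits = hits, central = cent, motif_length = w)
  })
  write_tsv(scan_res$hits, file.path(out_dir, "motif_hits.tsv"))
  manifest$counts$motif_hits <- nrow(scan_res$hits)
  manifest$counts$central_hits <- scan_res$central$n_central
  say("scan: ", nrow(scan_res$hits), " motif hits, central-enrichment p = ",
      format(scan_res$central$p_value, digits = 3))

  # target assignment
  targets <- stage("targets",
                   assign_targets(consensus, genes, rule, seq_lengths))
  write_tsv(targets, file.path(out_dir, "targets.tsv"))
  manifest$counts$targets <- nrow(targets)
  say("targets: ", nrow(targets), " genes with >= 1 supporting peak")

  # classification against DE
  classes <- stage("classify", {
    de <- read_de_table(de_file)
    sets <- classify_de(de, alpha)
    cls <- split_targets(targets, sets$down, sets$up)
    idx <- match(cls$gene_id, de$gene_id)
    cls$log2fc <- de$log2fc[idx]
    cls$padj <- de$padj[idx]
    cls$n_supporting_peaks <-
      targets$n_supporting_peaks[match(cls$gene_id, targets$gene_id)]
    cls
  })
  write_tsv(classes, file.path(out_dir, "classification.tsv"))
  n_act <- sum(classes$label == "activated")
  n_rep <- sum(classes$label == "repressed")
  manifest$counts$activated <- n_act
  manifest$counts$repressed <- n_rep
  say("classify: ", n_act, " activated, ", n_rep, " repressed, ",
      sum(classes$label == "target_only"), " target-only")
  autoreg <- if (!is.null(tf_gene_id))
    stage("classify",
          detect_autoregulation(tf_gene_id, classes, genes$gene_id))
  else NA_character_

  # metacell integration
  summary_df <- stage("celltype", {
    M <- read_metacell_matrix(metacell_file, represented_threshold)
    summarize_regulons(M, classes)
  })
  write_tsv(summary_df, file.path(out_dir, "regulon_summary.tsv"))
  manifest$counts$metacells_with_targets <- nrow(summary_df)
  say("celltype: ", nrow(summary_df), " metacells with represented targets")

  # optional enrichment
  enrichment <- NULL
  if (!is.null(terms_file)) {
    enrichment <- stage("enrich", {
      terms <- read_term_memberships(terms_file)
      list(activated = enrich_terms(
             intersect(classes$gene_id[classes$label == "activated"],
                       genes$gene_id), terms, genes$gene_id),
           repressed = enrich_terms(
             intersect(classes$gene_id[classes$label == "repressed"],
                       genes$gene_id), terms, genes$gene_id))
    })
    write_tsv(enrichment$activated,
              file.path(out_dir, "enrichment_activated.tsv"))
    write_tsv(enrichment$repressed,
              file.path(out_dir, "enrichment_repressed.tsv"))
  }

  report <- structure(list(
    n_consensus_peaks = nrow(consensus),
    n_motif_hits = nrow(scan_res$hits),
    central_enrichment = scan_res$central,
    n_targets = nrow(targets),
    n_activated = n_act,
    n_repressed = n_rep,
    n_target_only = sum(classes$label == "target_only"),
    autoregulation = autoreg,
    regulon_summary = summary_df,
    consensus = consensus,
    targets = targets,
    classes = classes,
    motif_hits = scan_res$hits,
    enrichment = enrichment,
    out_dir = out_dir), class = "regulon_report")

  manifest$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  report
}

#' @export
print.regulon_report <- function(x, ...) {
  cat("Terminal-selector regulon report\n")
  cat("  consensus peaks:          ", x$n_consensus_peaks, "\n")
  cat("  motif hits in peaks:      ", x$n_motif_hits,
      sprintf(" (%d central; enrichment p = %s)\n",
              x$central_enrichment$n_central,
              format(x$central_enrichment$p_value, digits = 3)))
  cat("  direct target genes:      ", x$n_targets, "\n")
  cat("  directly activated:       ", x$n_activated, "\n")
  cat("  directly repressed:       ", x$n_repressed, "\n")
  cat("  bound, not DE (target-only):", x$n_target_only, "\n")
  if (!is.na(x$autoregulation))
    cat("  autoregulation:           ", x$autoregulation, "\n")
  if (nrow(x$regulon_summary)) {
    cat("  per-metacell regulon composition:\n")
    print(x$regulon_summary, row.names = FALSE)
  }
  invisible(x)
}
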