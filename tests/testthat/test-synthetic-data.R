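# The generator is first-class, tested code: its defaults state the
# emulated study (200 genes, 60 bound, 3 replicates, GCATWATTWAT planted
# at peak summits) and its truth file is the reference for recovery tests.

small_cfg <- function(seed = 101, n_bound = 12L, ...) {
  sim_config(seed = seed, n_scaffolds = 2L, scaffold_length_bp = 150000L,
             n_genes = 30L, n_true_bound_genes = n_bound,
             n_decoy_peaks = 30L, n_metacells = 4L,
             n_exclusive_markers = 2L, ...)
}

test_that("a fixed seed reproduces every output byte-for-byte", {
  d1 <- file.path(tempdir(), "sim_det_a")
  d2 <- file.path(tempdir(), "sim_det_b")
  simulate_study(small_cfg(), d1)
  simulate_study(small_cfg(), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6L)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the study
  d3 <- file.path(tempdir(), "sim_det_c")
  simulate_study(small_cfg(seed = 102), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "de.tsv"))),
                         unname(tools::md5sum(file.path(d3, "de.tsv")))))
})

test_that("truth is internally consistent and files parse with the readers", {
  out <- file.path(tempdir(), "sim_consistent")
  res <- simulate_study(small_cfg(103), out)
  tr <- res$truth
  expect_true(all(tr$activated_genes %in% tr$bound_genes))
  expect_true(all(tr$repressed_genes %in% tr$bound_genes))
  expect_length(intersect(tr$activated_genes, tr$repressed_genes), 0L)
  excl <- unlist(tr$exclusive_markers)
  expect_equal(anyDuplicated(excl), 0L)

  genes <- read_gene_models(res$paths$gff)
  expect_equal(nrow(genes), 30L)
  expect_equal(anyDuplicated(genes$gene_id), 0L)
  # genes do not overlap each other
  gr <- GenomicRanges::GRanges(genes$seqid,
                               IRanges::IRanges(genes$start, genes$end))
  expect_equal(GenomicRanges::countOverlaps(gr, gr), rep(1L, 30L))

  de <- read_de_table(res$paths$de)
  expect_equal(sort(de$gene_id), sort(genes$gene_id))
  # planted effects honor the mutant-vs-sibling sign convention
  expect_true(all(de$log2fc[de$gene_id %in% tr$activated_genes] < 0))
  expect_true(all(de$log2fc[de$gene_id %in% tr$repressed_genes] > 0))
  expect_true(all(de$padj[de$gene_id %in% c(tr$activated_genes,
                                            tr$repressed_genes)] < 1e-4))
  null_ids <- setdiff(de$gene_id, c(tr$activated_genes, tr$repressed_genes))
  expect_true(all(de$padj[de$gene_id %in% null_ids] >= 0.5))

  M <- read_metacell_matrix(res$paths$metacells)
  expect_equal(ncol(M$footprint), 4L)
  peaks <- read_narrowpeak(res$paths$peaks[1])
  expect_true(all(peaks$neglog10_p[grepl("^true", peaks$name)] >= 10))
  expect_true(all(peaks$neglog10_p[grepl("^decoy", peaks$name)] < 4))
})

test_that("planted motif positions are a subset of scan hits", {
  out <- file.path(tempdir(), "sim_planted")
  res <- simulate_study(small_cfg(104), out)
  planted <- planted_motif_positions(res$truth)
  expect_equal(nrow(planted), 12L)
  hits <- scan_fasta(res$paths$genome, res$truth$motif)
  key <- function(df) paste(df$seqid, df$start, df$strand)
  expect_true(all(key(planted) %in% key(hits)))
  # with plant probability zero nothing is recorded or planted
  res0 <- simulate_study(small_cfg(105, motif_plant_prob = 0),
                         file.path(tempdir(), "sim_unplanted"))
  expect_equal(nrow(planted_motif_positions(res0$truth)), 0L)
})

test_that("background motif rate in random sequence is Poisson-consistent", {
  out <- file.path(tempdir(), "sim_background")
  res <- simulate_study(sim_config(seed = 106, n_true_bound_genes = 0L,
                                   n_decoy_peaks = 0L), out)
  hits <- scan_fasta(res$paths$genome, "GCATWATTWAT")
  L <- 5 * 200000
  w <- 11
  lambda <- 2 * (L - w + 1) * 4 / 4^w   # both strands, 4 expansions
  expect_lte(abs(nrow(hits) - lambda), 3 * sqrt(lambda))
})

test_that("zero bound genes yield zero consensus peaks and targets", {
  out <- file.path(tempdir(), "sim_nobound")
  res <- simulate_study(small_cfg(107, n_bound = 0L, frac_activated = 0,
                                  frac_repressed = 0), out)
  cons <- build_consensus(lapply(res$paths$peaks, read_narrowpeak))
  expect_equal(nrow(cons), 0L)
  genes <- read_gene_models(res$paths$gff)
  expect_equal(nrow(assign_targets(cons, genes)), 0L)
})

test_that("infeasible packing fails before writing anything", {
  out <- file.path(tempdir(), "sim_infeasible")
  expect_error(simulate_study(sim_config(n_genes = 10000L), out),
               "infeasible packing")
  expect_false(file.exists(file.path(out, "genome.fa")))
  expect_error(sim_config(n_metacells = 2L), ">= 3 metacells")
  expect_error(sim_config(frac_activated = 0.8, frac_repressed = 0.5),
               "sum to <= 1")
})
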