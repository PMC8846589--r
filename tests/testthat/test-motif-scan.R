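# the two 50-bp gel-shift probe sequences used to validate the binding
# consensus: one carries a single core-motif instance, the other none
PROBE_MOTIF <- "AAACAAAGATTCTAAGCATCCATTATTAATATACATCCCTAGAAAAAATC"
PROBE_NOMOTIF <- "ATCGAAAACAAAGATTCTAAGCATCATACATCCCTAGAAAAAATCTCCGC"
CORE <- "AT(A/T)ATT(A/T)AT"
EXTENDED <- "GCAT(A/T)ATT(A/T)AT"

test_that("parenthetical consensus notation normalizes to IUPAC", {
  expect_equal(parse_consensus(CORE)$consensus, "ATWATTWAT")
  expect_equal(parse_consensus(EXTENDED)$consensus, "GCATWATTWAT")
  expect_equal(parse_consensus("AT(T/A)AT")$consensus, "ATWAT")
  expect_equal(parse_consensus("A(A/C)G")$consensus, "AMG")
  expect_equal(parse_consensus("a(c/g/t)n")$consensus, "ABN")
  expect_error(parse_consensus("AXT"), "invalid IUPAC")
  expect_error(parse_consensus("A(A/Z)T"), "invalid bases")
  expect_error(parse_consensus("A(AT"), "unclosed")
})

test_that("IUPAC expansion enumerates the degenerate positions", {
  expect_setequal(expand_iupac("ATWATTWAT"),
                  c("ATAATTAAT", "ATAATTTAT", "ATTATTAAT", "ATTATTTAT"))
  expect_length(expand_iupac("GCATWATTWAT"), 4L)
  expect_equal(expand_iupac("ACGT"), "ACGT")
  expect_length(expand_iupac("NN"), 16L)
})

test_that("every core expansion sits inside an extended expansion at offset 2", {
  core <- expand_iupac("ATWATTWAT")
  ext <- expand_iupac("GCATWATTWAT")
  for (cs in core)
    expect_true(any(substr(ext, 3, 11) == cs))
})

test_that("probe scanning finds exactly the planted core site", {
  hits <- scan_sequence(PROBE_MOTIF, CORE, both_strands = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 22L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched_seq, "ATTATTAAT")
  expect_equal(nrow(scan_sequence(PROBE_NOMOTIF, CORE)), 0L)
  # agreement with the exhaustive window oracle on both probes
  for (s in c(PROBE_MOTIF, PROBE_NOMOTIF))
    expect_equal(scan_sequence(s, CORE)[c("start", "strand", "matched_seq")],
                 oracle_scan(s, "ATWATTWAT"), ignore_attr = TRUE)
})

test_that("a motif expansion matches itself and not its reverse complement", {
  hits <- scan_sequence("ATTATTAAT", CORE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$strand, "+")
})

test_that("scanning equals the expansion oracle on random sequences", {
  set.seed(21)
  motifs <- c("ATWATTWAT", "GCATWATTWAT", "RYSWKM", "ACGTN")
  for (trial in 1:12) {
    seq <- random_dna(sample(200:2000, 1))
    m <- sample(motifs, 1)
    got <- scan_sequence(seq, m)
    want <- oracle_scan(seq, m)
    expect_equal(got[c("start", "strand", "matched_seq")], want,
                 ignore_attr = TRUE)
  }
})

test_that("N in the subject never matches", {
  expect_equal(nrow(scan_sequence("ATNATTAAT", CORE)), 0L)
  expect_equal(nrow(scan_sequence("NNNNNNNNNNN", "NNN")), 0L)
})

test_that("reverse-complementing the sequence reflects hits and swaps strands", {
  set.seed(22)
  for (trial in 1:10) {
    L <- sample(100:800, 1)
    seq <- random_dna(L)
    m <- "ATWATTWAT"
    w <- nchar(m)
    fwd <- scan_sequence(seq, m)
    rev <- scan_sequence(revcomp(seq), m)
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd)) {
      mapped <- sort(L - (rev$start + w - 1L) + 1L)
      expect_equal(mapped, sort(fwd$start))
      expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))
      expect_equal(sum(fwd$strand == "-"), sum(rev$strand == "+"))
    }
  }
})

test_that("central enrichment follows the exact binomial tail", {
  # 10 hits all central: 0.2^10
  all_central <- central_enrichment_test(rep(500, 10), 1, 1000, 0.2)
  expect_equal(all_central$n_central, 10L)
  expect_equal(all_central$p_value, 0.2^10, tolerance = 1e-12)
  # no hits: p = 1
  expect_equal(central_enrichment_test(numeric(), 1, 1000)$p_value, 1.0)
  # 1 of 5 central: 1 - 0.8^5 (frozen closed form)
  mixed <- central_enrichment_test(c(500, 10, 20, 990, 950), 1, 1000, 0.2)
  expect_equal(mixed$n_central, 1L)
  expect_equal(mixed$p_value, 0.67232, tolerance = 1e-10)
  # a hit outside its window is rejected
  expect_error(central_enrichment_test(1500, 1, 1000), "inside its window")
  expect_error(central_enrichment_test(500, 1, 1000, 1.2), "central_fraction")
})

test_that("central-enrichment p is super-uniform under the uniform null", {
  set.seed(23)
  trials <- 1000
  rejections <- 0
  for (i in seq_len(trials)) {
    pos <- runif(30, 1, 1000)
    p <- central_enrichment_test(pos, 1, 1000, 0.2)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / trials, 0.07)
})

test_that("FASTA scanning and BED output preserve hits", {
  seq <- paste0(strrep("C", 30), "ATTATTAAT", strrep("G", 30))
  fa <- write_lines_tmp(c(">chrTest", seq), ".fa")
  hits <- scan_fasta(fa, CORE)
  expect_equal(hits$seqid, "chrTest")
  expect_equal(hits$start, 31L)
  bed <- tempfile(fileext = ".bed")
  write_hits_bed(hits, 9L, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(30L, 39L))   # 0-based half-open
  expect_equal(fields[6], "+")
})
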