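np_line <- function(chrom, s0, e0, name = "p", score = 100, strand = ".",
                    sig = 5, p = 6, q = 4.5, summit = 50) {
  sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
          chrom, s0, e0, name, score, strand, sig, p, q, summit)
}

peak_row <- function(seqid, start, end, p, rep = "r1") {
  data.frame(seqid = seqid, start = start, end = end, name = "p",
             score = 0, strand = ".", signal = 0, neglog10_p = p,
             neglog10_q = 0, summit_offset = -1L, replicate_id = rep,
             stringsAsFactors = FALSE)
}

test_that("narrowPeak reading converts coordinates and applies defaults", {
  f <- write_lines_tmp(np_line("chr1", 99, 200), ".narrowPeak")
  pk <- read_narrowpeak(f, "r1")
  expect_equal(pk$start, 100L)        # 0-based half-open -> 1-based inclusive
  expect_equal(pk$end, 200L)
  expect_equal(pk$neglog10_p, 6)
  expect_equal(pk$summit_offset, 50L)
  expect_equal(pk$replicate_id, "r1")

  # missing optional columns default
  f2 <- write_lines_tmp("chr1\t0\t10", ".narrowPeak")
  pk2 <- read_narrowpeak(f2)
  expect_equal(pk2$score, 0)
  expect_equal(pk2$neglog10_p, 0)
  expect_equal(pk2$summit_offset, -1L)

  # empty file
  f3 <- write_lines_tmp(character(), ".narrowPeak")
  expect_equal(nrow(read_narrowpeak(f3)), 0L)

  # malformed lines name the line number
  f4 <- write_lines_tmp(c(np_line("chr1", 0, 10), "chr1\t50\t50"),
                        ".narrowPeak")
  expect_error(read_narrowpeak(f4), "line 2.*end <= start")
  f5 <- write_lines_tmp("chr1\tx\t10", ".narrowPeak")
  expect_error(read_narrowpeak(f5), "line 1")
})

test_that("narrowPeak writing round-trips through reading", {
  pk <- peak_row("chr2", 101, 300, 7.25)
  pk$summit_offset <- 42L
  f <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  back <- read_narrowpeak(f, "r1")
  expect_equal(back$start, 101L)
  expect_equal(back$end, 300L)
  expect_equal(back$neglog10_p, 7.25)
  expect_equal(back$summit_offset, 42L)
})

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(fisher_combine(0.5), 0.5)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  # frozen from the closed form: X = -2*2*ln(0.1) = 9.2103,
  # chi-square(4 df) upper tail
  expect_equal(fisher_combine(c(0.1, 0.1)), 0.05605170186, tolerance = 1e-9)
  expect_warning(p0 <- fisher_combine(c(0.5, 0)), "clamped")
  expect_true(p0 > 0 && p0 < 1e-100)
  expect_error(fisher_combine(numeric()), "at least one")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")

  set.seed(11)
  for (i in 1:100) {
    p <- runif(sample(1:6, 1))
    x <- -2 * sum(log(p))
    expect_equal(fisher_combine(p),
                 pchisq(x, 2 * length(p), lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # a single p-value is unchanged (chi-square identity with 2 df)
  for (p in c(1e-8, 0.01, 0.37, 0.999))
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
})

test_that("consensus building applies weak, strong, and replicate rules", {
  cfg <- consensus_config()
  # singleton strong peak passes
  one <- build_consensus(list(peak_row("c", 100, 200, 9)), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(100L, 200L))

  # two overlapping 1e-5 peaks combine below the strong threshold
  two <- build_consensus(list(peak_row("c", 100, 200, 5, "r1"),
                              peak_row("c", 150, 260, 5, "r2")), cfg)
  expect_equal(nrow(two), 1L)
  expect_equal(two$n_replicates_supporting, 2L)
  expect_equal(c(two$start, two$end), c(100L, 260L))   # union interval
  expect_equal(10^(-two$combined_neglog10_p),
               fisher_combine(c(1e-5, 1e-5)), tolerance = 1e-6)

  # one member above the weak threshold sinks the whole group
  weakmem <- build_consensus(list(peak_row("c", 100, 200, 3, "r1"),
                                  peak_row("c", 150, 260, 12, "r2")), cfg)
  expect_equal(nrow(weakmem), 0L)

  # replicate support requirement
  cfg2 <- consensus_config(min_supporting_replicates = 2)
  expect_equal(nrow(build_consensus(list(peak_row("c", 100, 200, 9)), cfg2)),
               0L)

  # every emitted combined p is at or below the strong threshold
  expect_true(all(10^(-two$combined_neglog10_p) <= cfg$strong_threshold))
})

test_that("consensus is invariant to replicate and peak order", {
  set.seed(12)
  mk <- function() {
    n <- sample(3:8, 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(1:2000, 1)
      peak_row("c", s, s + sample(50:400, 1), runif(1, 3, 15),
               sample(c("r1", "r2", "r3"), 1))
    }))
  }
  for (i in 1:10) {
    pk <- mk()
    sets <- split(pk, pk$replicate_id)
    a <- build_consensus(sets)
    b <- build_consensus(rev(sets))
    shuffled <- lapply(sets, function(s) s[sample(nrow(s)), , drop = FALSE])
    c_ <- build_consensus(shuffled)
    expect_identical(a, b)
    expect_identical(a, c_)
  }
})

test_that("consensus equals brute-force enumeration on small instances", {
  set.seed(13)
  for (trial in 1:25) {
    n <- sample(2:20, 1)
    pk <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(1:3000, 1)
      peak_row(sample(c("cA", "cB"), 1), s, s + sample(20:500, 1),
               runif(1, 2, 16), sample(c("r1", "r2", "r3"), 1))
    }))
    got <- build_consensus(split(pk, pk$replicate_id))
    want <- oracle_consensus(pk)
    expect_equal(got[c("seqid", "start", "end")],
                 want, ignore_attr = TRUE)
  }
})

test_that("permissive single-replicate consensus is the identity up to merging", {
  cfg <- consensus_config(weak_threshold = 1, strong_threshold = 1)
  set.seed(14)
  starts <- sample(seq(1, 10000, by = 600), 8)   # non-overlapping
  pk <- do.call(rbind, lapply(starts, function(s)
    peak_row("c", s, s + 100, runif(1, 0.1, 5))))
  out <- build_consensus(list(pk), cfg)
  expect_equal(nrow(out), nrow(pk))
  expect_equal(sort(out$start), sort(pk$start))
})
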