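mk_gr <- function(chrom, start, end, strand, read_id, genome) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, read_id = read_id,
                               seqinfo = genome$seqinfo)
  alignment_set(gr, read_length = 50L)
}

test_that("coverage increments every covered base once per segment", {
  g <- small_genome()
  a <- mk_gr("chr1", 101, 150, "+", "r1", g)
  tr <- compute_coverage(a, g)
  v <- as.numeric(tr$cov[["+"]][["chr1"]])
  expect_equal(sum(v), 50)
  expect_true(all(v[101:150] == 1))
  expect_true(all(v[-(101:150)] == 0))
  # overlapping segments are additive
  a2 <- mk_gr("chr1", c(101, 121), c(150, 170), "+", c("r1", "r2"), g)
  v2 <- as.numeric(compute_coverage(a2, g)$cov[["+"]][["chr1"]])
  expect_true(all(v2[121:150] == 2))
  expect_equal(sum(v2), 100)
})

test_that("coverage conserves segment bases for random record sets", {
  g <- small_genome()
  set.seed(99)
  n <- 1e4
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(5e4, n, replace = TRUE)
  len <- sample(20:80, n, replace = TRUE)
  a <- mk_gr(chrom, start, start + len - 1L,
             sample(c("+", "-"), n, replace = TRUE),
             sprintf("r%06d", seq_len(n)), g)
  tr <- compute_coverage(a, g)
  total <- sum(vapply(tr$cov, function(rl)
    sum(vapply(rl, function(r) sum(as.numeric(r)), 0)), 0))
  expect_equal(total, sum(len))
  expect_equal(tr$total_tags, n)
})

test_that("region read equivalents divide summed coverage by read length", {
  g <- small_genome()
  # 20 adjacent 50-bp reads tile [1001, 2000) at depth 1
  starts <- seq(1001, by = 50, length.out = 20)
  a <- mk_gr("chr1", starts, starts + 49, "+",
             sprintf("r%02d", 1:20), g)
  tr <- compute_coverage(a, g)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
                                   strand = "+")
  expect_equal(region_read_equivalents(tr, region), 20)
  empty <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1000),
                                  strand = "+")
  expect_equal(region_read_equivalents(tr, empty), 0)
  # reads fully inside a region equal direct counting
  region2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(950, 2050),
                                    strand = "+")
  expect_equal(region_read_equivalents(tr, region2), 20)
})

test_that("normalization formulas and linearity hold", {
  expect_equal(as.numeric(rpkm(20, 1000, 1e6)), 20)
  expect_equal(as.numeric(rpkm(0, 1000, 1e6)), 0)
  expect_equal(as.numeric(rpkm(20, 1000, 2e6)),
               as.numeric(rpkm(20, 1000, 1e6)) / 2)
  expect_equal(as.numeric(rptm(50, 5e6)), 100)
  expect_equal(as.numeric(rptm(123, 1e7)), 123)
  expect_equal(as.numeric(rptm(0, 5e6)), 0)
  # linearity: f(ax) = a f(x)
  expect_equal(as.numeric(rpkm(7 * 3, 1000, 1e6)),
               7 * as.numeric(rpkm(3, 1000, 1e6)))
  expect_equal(attr(rpkm(1, 1, 1), "unit"), "RPKM")
  expect_equal(attr(rptm(1, 1), "unit"), "RPTM")
  expect_error(rpkm(1, 0, 1e6), "region length")
  expect_error(rptm(1, 0), "total_tags")
})

test_that("TP10M normalization rescales depth and preserves totals", {
  g <- small_genome()
  a <- mk_gr("chr1", c(101, 201), c(150, 250), "+", c("r1", "r2"), g)
  tr <- compute_coverage(a, g)
  tr$total_tags <- 1e7
  expect_equal(as.numeric(tp10m(tr)$cov[["+"]][["chr1"]]),
               as.numeric(tr$cov[["+"]][["chr1"]]))
  tr$total_tags <- 2e6
  n <- tp10m(tr)
  expect_equal(sum(as.numeric(n$cov[["+"]][["chr1"]])),
               sum(as.numeric(tr$cov[["+"]][["chr1"]])) * 5)
})

test_that("feature containment filter keeps only strand-matched contained reads", {
  g <- small_genome()
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999),
                                  strand = "+", fid = "F1",
                                  seqinfo = g$seqinfo)
  a <- mk_gr("chr1",
             c(1100, 1100, 1950, 500, 1200, 1300),
             c(1149, 1149, 2020, 549, 1249, 1349),
             c("+", "-", "+", "+", "+", "+"),
             c("in_plus", "wrong_strand", "straddle", "outside",
               "split_ok", "split_ok"), g)
  fil <- filter_reads_in_features(a, feats, id_col = "fid")
  expect_setequal(fil$assignment$read_id, c("in_plus", "split_ok"))
  # relaxed overlap mode admits the straddler
  fil2 <- filter_reads_in_features(a, feats, mode = "overlap",
                                   id_col = "fid")
  expect_true("straddle" %in% fil2$assignment$read_id)
})

test_that("bedGraph export is 0-based half-open per strand", {
  g <- small_genome()
  a <- mk_gr("chr1", 101, 150, "+", "r1", g)
  tr <- compute_coverage(a, g)
  files <- write_bedgraph(tr, tempfile(fileext = ".bedgraph"))
  plus <- readLines(grep("plus", files, value = TRUE))
  expect_equal(plus, "chr1\t100\t150\t1")
})
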