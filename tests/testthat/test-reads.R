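test_that("emitted bases are conserved: segment lengths sum to depth x read length", {
  g <- small_genome()
  pool <- deplete_rrna(simulate_pool(g, "Col0", seed = 4L))
  ls <- library_spec("cons", "Col0", "RNaseR_minus", "RNAseq",
                     depth = 1000, read_length = 50L, p_junction = 0,
                     seed = 8L)
  a <- generate_alignments(pool, ls, g)
  expect_equal(sum(BiocGenerics::width(a)), 1000L * 50L)
  track <- compute_coverage(a, g)
  total_cov <- sum(vapply(track$cov, function(rl)
    sum(vapply(rl, function(r) sum(as.numeric(r)), 0)), 0))
  expect_equal(total_cov, 1000 * 50)
})

test_that("junction reads end at the branch point and restart at the intron 5' end", {
  g <- small_genome()
  pool <- deplete_rrna(simulate_pool(
    g, "dbr1_2", sim_effects(lariat_fraction = 0.5), seed = 4L))
  ls <- library_spec("jx", "dbr1_2", "RNaseR_minus", "RNAseq",
                     depth = 2e4, p_junction = 1, seed = 8L)
  a <- generate_alignments(pool, ls, g)
  jt <- attr(a, "junction_truth")
  expect_gt(nrow(jt), 0L)
  ii <- g$introns[match(jt$intron_id, g$introns$intron_id), ]
  for (k in sample(nrow(jt), min(50L, nrow(jt)))) {
    segs <- a[S4Vectors::mcols(a)$read_id == jt$read_id[k]]
    expect_equal(length(segs), 2L)
    if (ii$strand[k] == "+") {
      expect_true(any(BiocGenerics::end(segs) == ii$branch_pos[k]))
      expect_true(any(BiocGenerics::start(segs) == ii$start[k]))
    } else {
      expect_true(any(BiocGenerics::start(segs) == ii$branch_pos[k]))
      expect_true(any(BiocGenerics::end(segs) == ii$end[k]))
    }
  }
})

test_that("read generation is a pure function of (pool, libspec, genome)", {
  g <- small_genome()
  pool <- deplete_rrna(simulate_pool(g, "Col0", seed = 4L))
  ls <- library_spec("det", "Col0", "RNaseR_minus", "RNAseq",
                     depth = 2000, seed = 21L)
  a1 <- generate_alignments(pool, ls, g)
  a2 <- generate_alignments(pool, ls, g)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed12(a1, f1); write_bed12(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("RNase R treatment shifts the circular:linear read ratio by s_circ/s_lin", {
  g <- small_genome()
  eff <- sim_effects(survival_circular = 0.9, survival_linear = 0.01)
  pool <- deplete_rrna(simulate_pool(g, "dbr1_2", eff, seed = 4L))
  digested <- apply_rnase_r(pool, 0.9, 0.01)
  ratio_of <- function(p, id) {
    ls <- library_spec(id, "dbr1_2", "none", "RNAseq", depth = 1e5,
                       seed = 17L)
    cnt <- attr(generate_alignments(p, ls, g), "species_counts")
    circ <- pool$topology == "circular" & pool$length >= 60
    lin <- pool$topology == "linear" & pool$length >= 60 &
      pool$kind != "mature_miRNA"
    sum(cnt[circ]) / sum(cnt[lin])
  }
  fold <- ratio_of(digested, "post") / ratio_of(pool, "pre")
  expect_lt(abs(fold - 90) / 90, 0.1)
})

test_that("zero-abundance pools are rejected", {
  g <- small_genome()
  pool <- simulate_pool(g, "Col0", seed = 4L)
  pool$abundance[] <- 0
  ls <- library_spec("z", "Col0", "RNaseR_minus", "RNAseq", depth = 100)
  expect_error(generate_alignments(pool, ls, g), "zero total abundance")
})

test_that("small-RNA reads are insert plus adapter with clean qualities", {
  g <- small_genome()
  pool <- simulate_pool(g, "Col0", seed = 4L)
  mat <- pool[pool$kind == "mature_miRNA", ]
  pool2 <- pool[pool$kind == "mature_miRNA", ][1, , drop = FALSE]
  pool2$abundance <- 100
  attr(pool2, "effects") <- attr(pool, "effects")
  ls <- library_spec("sr", "Col0", "none", "sRNAseq", depth = 100,
                     seed = 6L)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  reads <- generate_small_rna_reads(pool2, ls, g, adapter = adapter,
                                    exhaustive = TRUE)
  expect_equal(nrow(reads), 100L)
  mat_gr <- mature_ranges(g)
  insert <- as.character(feature_seq(g, mat_gr[
    S4Vectors::mcols(mat_gr)$mirna_id == pool2$feature_id[1]]))
  expect_true(all(startsWith(reads$seq, insert)))
  expect_true(all(substr(reads$seq, nchar(insert) + 1L,
                         nchar(insert) + 8L) == substr(adapter, 1, 8)))
  # no low-quality reads planted -> the downstream filter removes none
  expect_equal(nrow(quality_filter(reads)), 100L)
  expect_error(generate_small_rna_reads(pool2, ls, g, adapter = ""),
               "adapter")
})

test_that("exhaustive small-RNA emission reproduces planted counts exactly", {
  g <- small_genome()
  pool <- simulate_pool(g, "Col0", seed = 4L)
  mat_rows <- which(pool$kind == "mature_miRNA")[1:2]
  pool3 <- pool[mat_rows, ]
  pool3$abundance <- c(300, 100)
  attr(pool3, "effects") <- attr(pool, "effects")
  ls <- library_spec("ex", "Col0", "none", "sRNAseq", depth = 400,
                     seed = 6L)
  reads <- generate_small_rna_reads(pool3, ls, g, exhaustive = TRUE)
  ins <- trim_adapter(reads, "TGGAATTCTCGGGTGCCAAGG")
  tab <- collapse_unique(ins)
  expect_equal(sort(tab$count), c(100L, 300L))
  mat_gr <- mature_ranges(g)
  ref <- setNames(as.character(feature_seq(g, mat_gr)),
                  S4Vectors::mcols(mat_gr)$mirna_id)
  asg <- assign_mirnas(tab, ref)
  cnt <- setNames(asg$count, asg$mirna_id)
  expect_equal(unname(cnt[pool3$feature_id]), c(300, 100))
})

test_that("the planted low-quality fraction is removed by the quality filter", {
  g <- small_genome()
  pool <- simulate_pool(g, "Col0", seed = 4L)
  ls <- library_spec("lq", "Col0", "none", "sRNAseq", depth = 1000,
                     seed = 6L)
  reads <- generate_small_rna_reads(pool, ls, g,
                                    low_quality_fraction = 0.2)
  kept <- quality_filter(reads)
  expect_equal(attr(kept, "n_removed"), 200L)
})
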