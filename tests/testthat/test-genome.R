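test_that("build_genome honours the requested feature counts", {
  g <- build_genome(n_chrom = 2L, chrom_length = 1e5, n_genes = 20L,
                    n_mirna = 5L, n_rrna = 2L, seed = 1L)
  expect_equal(nrow(g$genes), 20L)
  expect_equal(nrow(g$mirna), 5L)
  expect_equal(nrow(g$rrna), 2L)
  expect_equal(length(GenomeInfoDb::seqnames(g$seqinfo)), 2L)
  expect_silent(validate_genome(g))
})

test_that("genome construction is deterministic: identical GFF3 bytes", {
  g1 <- build_genome(n_chrom = 2L, chrom_length = 1e5, n_genes = 20L,
                     n_mirna = 5L, seed = 1L)
  g2 <- build_genome(n_chrom = 2L, chrom_length = 1e5, n_genes = 20L,
                     n_mirna = 5L, seed = 1L)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_annotation_gff3(g1, f1); write_annotation_gff3(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(as.character(g1$seq), as.character(g2$seq))
})

test_that("single-exon genes have no introns", {
  g <- build_genome(n_chrom = 1L, chrom_length = 5e4, n_genes = 10L,
                    exons_per_gene = 1L, n_mirna = 0L, n_rrna = 0L,
                    seed = 3L)
  expect_equal(nrow(g$introns), 0L)
})

test_that("introns are the inter-exon gaps, branch points near the 3' end", {
  g <- small_genome()
  derived <- lariatseq:::derive_introns(g$exons)
  key <- function(d) sort(paste(d$gene_id, d$start, d$end))
  expect_equal(key(derived), key(g$introns))
  d3 <- ifelse(g$introns$strand == "+",
               g$introns$end - g$introns$branch_pos,
               g$introns$branch_pos - g$introns$start)
  expect_true(all(d3 >= 10 & d3 <= 50))
  # intron ids follow <gene>I<ordinal> in transcript order
  expect_true(all(grepl("^AT\\dG\\d+I\\d+$", g$introns$intron_id)))
  plus <- g$introns[g$introns$strand == "+", ]
  for (gg in split(plus, plus$gene_id)) {
    gg <- gg[order(gg$start), ]
    expect_equal(gg$intron_rank, seq_len(nrow(gg)))
  }
  minus <- g$introns[g$introns$strand == "-", ]
  for (gg in split(minus, minus$gene_id)) {
    gg <- gg[order(gg$start, decreasing = TRUE), ]
    expect_equal(gg$intron_rank, seq_len(nrow(gg)))
  }
})

test_that("oversized feature requests raise a sizing error", {
  expect_error(
    build_genome(n_chrom = 1L, chrom_length = 5e3, n_genes = 50L,
                 seed = 1L),
    "available")
})

test_that("annotation survives a GFF3 round trip", {
  g <- small_genome()
  f <- tempfile(fileext = ".gff3")
  write_annotation_gff3(g, f)
  r <- read_annotation(f)
  key <- function(d) d[order(d$gene_id, d$start),
                       c("gene_id", "chrom", "strand", "start", "end")]
  expect_equal(key(r$exons), key(g$exons), ignore_attr = TRUE)
  m <- match(g$introns$intron_id, r$introns$intron_id)
  expect_false(anyNA(m))
  expect_equal(r$introns$start[m], g$introns$start)
  expect_equal(r$introns$end[m], g$introns$end)
  expect_equal(r$introns$branch_pos[m], g$introns$branch_pos)
  mm <- match(g$mirna$mirna_id, r$mirna$mirna_id)
  expect_equal(r$mirna$pre_start[mm], g$mirna$pre_start)
  expect_equal(r$mirna$mature_end[mm], g$mirna$mature_end)
})

test_that("overlapping exons within a gene are rejected on read", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t500\t.\t+\t.\tID=G1",
               "chr1\tx\texon\t1\t200\t.\t+\t.\tParent=G1",
               "chr1\tx\texon\t150\t400\t.\t+\t.\tParent=G1"), f)
  expect_error(read_annotation(f), "overlapping exons")
})

test_that("intron donor and branch bases are patched into the sequence", {
  g <- small_genome()
  ii <- g$introns
  gr <- lariatseq:::df_to_granges(ii, g)
  seqs <- as.character(feature_seq(g, gr))  # 5'->3' intron sequences
  expect_true(all(substr(seqs, 1, 2) == "GT"))
})
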