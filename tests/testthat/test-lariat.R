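test_that("the 5 RPKM floor is inclusive and the FDR cut strict", {
  iq <- fake_iq(
    rpkm_dbr1_rminus = c(4.99, 50, 5.00, 80),
    rpkm_dbr1_rplus  = c(100, 100, 5.00, 4.99),
    rpkm_col0_rminus = c(0.1, 50, 5.00, 0.1),
    counts_col0 = c(0, 500, 0, 0),
    counts_dbr1 = c(400, 500, 300, 400))
  tab <- call_lariat_introns(iq, dispersion = 0.05)
  # below the abundance floor: never enriched, whatever the p-value
  expect_false(tab$enriched[1])
  expect_lt(tab$fdr[1], 0.05)
  # abundant but identical counts: p = 1, not enriched
  expect_false(tab$enriched[2])
  expect_equal(tab$p_value[2], 1)
  # boundaries are inclusive: exactly 5 RPKM passes every filter
  expect_true(tab$enriched[3])
  expect_true(tab$rnase_r_stable[3])
  expect_true(tab$wt_expressed[3])
  # RNase R plus just under the floor: enriched but not stable
  expect_true(tab$enriched[4])
  expect_false(tab$rnase_r_stable[4])
  expect_false(tab$wt_expressed[4])
})

test_that("a missing library class is named in the error", {
  sim <- small_sim()
  man <- sim$manifest[sim$manifest$genotype != "Col0" |
                      sim$manifest$treatment != "RNaseR_minus", ]
  aln <- sim$alignments[man$library_id]
  expect_error(quantify_introns(aln, sim$genome, man),
               "Col0.RNaseR_minus")
})

test_that("intron quantification matches planted loop expectations", {
  sim <- small_sim()
  iq <- quantify_introns(sim$alignments, sim$genome, sim$manifest)
  expect_equal(sort(rownames(iq$rpkm)), sort(sim$genome$introns$intron_id))
  # zero-coverage introns quantify to zero everywhere
  zero <- rowSums(iq$counts) == 0
  expect_true(any(zero))
  expect_true(all(iq$rpkm[zero, ] == 0))
  # counts agree with read equivalents to within boundary effects
  lib <- sim$manifest$library_id[1]
  re_rpkm <- iq$rpkm[, lib]
  len <- sim$genome$introns$end - sim$genome$introns$start + 1
  len <- len[match(rownames(iq$rpkm), sim$genome$introns$intron_id)]
  implied <- re_rpkm * len * iq$lib_sizes[lib] / 1e9
  expect_true(all(abs(implied - iq$counts[, lib]) <= 1 + 0.3 * iq$counts[, lib]))
})

test_that("the flag nesting wt_expressed within stable within enriched always holds", {
  for (tab in list(default_lariat()$introns,
                   call_lariat_introns(
                     quantify_introns(small_sim()$alignments,
                                      small_sim()$genome,
                                      small_sim()$manifest)))) {
    expect_true(all(!tab$rnase_r_stable | tab$enriched))
    expect_true(all(!tab$wt_expressed | tab$rnase_r_stable))
  }
})

test_that("planted lariats, escapees and decoys are recovered at study scale", {
  ev <- default_lariat()$evaluation
  expect_gte(ev$sensitivity, 0.9)
  expect_lte(ev$empirical_fdr, 0.1)
  expect_gte(ev$circle_stable_rate, 0.95)
  expect_gte(ev$decoy_rejection_rate, 0.95)
  # escapee recovery: wild-type-expressed share of stable lariats tracks
  # the planted escape fraction (0.23)
  expect_gte(ev$wt_expressed_fraction, 0.15)
  expect_lte(ev$wt_expressed_fraction, 0.35)
  # linear decoys called enriched are kept out of the stable catalog
  tab <- default_lariat()$introns
  dec <- tab[tab$intron_id %in% default_sim()$truth$decoy_introns, ]
  expect_gt(sum(dec$enriched), 0)
  expect_true(all(!dec$rnase_r_stable[dec$enriched]))
})

test_that("deregulated genes follow the either-genotype rule", {
  sim <- small_sim()
  genes <- call_deregulated_genes(sim$alignments, sim$genome,
                                  sim$manifest)
  expect_true(all(c("gene_id", "fdr", "deregulated") %in% names(genes)))
  # the flag is exactly the printed rule applied to the table's own columns
  expect_equal(genes$deregulated,
               pmax(genes$rpkm_col0, genes$rpkm_dbr1) >= 5 &
                 genes$fdr < 0.05)
  # planted 4-fold genes at study scale: sensitivity >= 0.8
  res <- default_lariat()
  truth <- default_sim()$truth$deregulated_genes
  sens <- mean(truth %in% res$genes$gene_id[res$genes$deregulated])
  expect_gte(sens, 0.8)
})

test_that("branchpoints are recovered coordinate-exactly from junction reads", {
  res <- default_lariat()
  truth <- default_sim()$truth$branch_points
  bp <- res$branchpoints
  expect_gt(nrow(bp), 0)
  # every call with >= 3 supporting reads sits exactly on the planted branch
  strong <- bp[bp$n_junction_reads >= 3, ]
  expect_true(all(strong$branch_pos == truth[strong$intron_id]))
  # and no call is assigned to a non-lariat intron
  expect_true(all(bp$intron_id %in% names(truth)))
})

test_that("without junction-crossing reads there are no branchpoint calls", {
  g <- small_genome()
  pool <- deplete_rrna(simulate_pool(
    g, "dbr1_2", sim_effects(lariat_fraction = 0.5), seed = 4L))
  ls <- library_spec("nj", "dbr1_2", "RNaseR_minus", "RNAseq",
                     depth = 2e4, p_junction = 0, seed = 8L)
  a <- generate_alignments(pool, ls, g)
  expect_equal(nrow(detect_branchpoint_junctions(a, g)), 0L)
})

test_that("two introns of one gene give two distinct branch calls", {
  g <- small_genome()
  pool <- deplete_rrna(simulate_pool(
    g, "dbr1_2", sim_effects(lariat_fraction = 1), seed = 4L))
  ls <- library_spec("two", "dbr1_2", "RNaseR_minus", "RNAseq",
                     depth = 5e4, p_junction = 0.5, seed = 8L)
  a <- generate_alignments(pool, ls, g)
  calls <- detect_branchpoint_junctions(a, g, min_support = 2L)
  ii <- g$introns
  multi <- names(which(table(ii$gene_id[match(calls$intron_id,
                                              ii$intron_id)]) >= 2))
  expect_gt(length(multi), 0)
  for (gene in multi) {
    sub <- calls[calls$intron_id %in%
                   ii$intron_id[ii$gene_id == gene], ]
    expect_equal(sub$branch_pos,
                 ii$branch_pos[match(sub$intron_id, ii$intron_id)])
    expect_equal(anyDuplicated(sub$branch_pos), 0L)
  }
})
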