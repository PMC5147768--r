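#' Analysis thresholds
#'
#' The filtering constants of the pipeline: minimum mean RPKM for calling a
#' feature expressed (`rpkm_min = 5`, inclusive), minimum RPTM for the
#' small-RNA expression filter (`rptm_min = 100`, inclusive), FDR ceiling
#' (`fdr_max = 0.05`, strict), and the log2 fold-change magnitude beyond
#' which RIP occupancy counts as deregulated (`log2fc_cut = 1`, strict).
#'
#' @param rpkm_min,rptm_min,fdr_max,log2fc_cut see above.
#' @param stranded strand-aware quantification.
#' @param min_support minimum junction reads for a branchpoint call.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(rpkm_min = 5, rptm_min = 100, fdr_max = 0.05,
                            log2fc_cut = 1, stranded = TRUE,
                            min_support = 2L) {
  assert_that(rpkm_min > 0 && rptm_min > 0 && fdr_max > 0 && log2fc_cut > 0,
              "thresholds must be positive")
  structure(list(rpkm_min = rpkm_min, rptm_min = rptm_min,
                 fdr_max = fdr_max, log2fc_cut = log2fc_cut,
                 stranded = stranded, min_support = as.integer(min_support)),
            class = "analysis_config")
}

#' Quantify annotated introns across libraries
#'
#' For each library, reads are restricted to those uniquely contained in a
#' single annotated intron (strand-matched; every segment inside the
#' intron), coverage is computed from the restricted set, and intron RPKM
#' is derived via read equivalents. Raw contained-read counts are kept for
#' the exact test.
#'
#' @param aln_list named list of alignment `GRanges`, one per library.
#' @param genome a `GenomeModel`.
#' @param manifest `data.frame` with `library_id`, `genotype`, `treatment`,
#'   `replicate`; rownames/order must cover `names(aln_list)`.
#' @param config an [analysis_config()].
#' @return a list: `info` (intron metadata), `rpkm` and `counts` (introns x
#'   libraries matrices), `lib_sizes`, `manifest`.
#' @export
quantify_introns <- function(aln_list, genome, manifest,
                             config = analysis_config()) {
  manifest <- check_manifest(manifest, names(aln_list))
  need <- c("Col0.RNaseR_minus", "dbr1_2.RNaseR_minus")
  have <- paste(manifest$genotype, manifest$treatment, sep = ".")
  missing <- setdiff(need, have)
  assert_that(length(missing) == 0L,
              sprintf("missing library class: %s",
                      paste(missing, collapse = ", ")))
  introns <- intron_ranges(genome)
  ids <- S4Vectors::mcols(introns)$intron_id
  rpkm_m <- counts_m <- matrix(
    0, nrow = length(introns), ncol = nrow(manifest),
    dimnames = list(ids, manifest$library_id))
  lib_sizes <- setNames(numeric(nrow(manifest)), manifest$library_id)
  for (lib in manifest$library_id) {
    aln <- aln_list[[lib]]
    lib_sizes[lib] <- n_tags(aln)
    fil <- filter_reads_in_features(aln, introns, mode = "within",
                                    stranded = config$stranded,
                                    id_col = "intron_id")
    track <- compute_coverage(fil$aln, genome, stranded = config$stranded)
    track$total_tags <- lib_sizes[lib]  # normalize by the whole library
    re <- region_read_equivalents(track, introns)
    rpkm_m[, lib] <- rpkm(re, BiocGenerics::width(introns), lib_sizes[lib])
    cnt <- table(factor(fil$assignment$feature_id, levels = ids))
    counts_m[, lib] <- as.integer(cnt)
  }
  info <- data.frame(
    intron_id = ids,
    gene_id = S4Vectors::mcols(introns)$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(introns)),
    start = BiocGenerics::start(introns),
    end = BiocGenerics::end(introns),
    strand = as.character(BiocGenerics::strand(introns)),
    stringsAsFactors = FALSE)
  list(info = info, rpkm = rpkm_m, counts = counts_m,
       lib_sizes = lib_sizes, manifest = manifest)
}

check_manifest <- function(manifest, lib_ids) {
  need_cols <- c("library_id", "genotype", "treatment")
  assert_that(all(need_cols %in% names(manifest)),
              sprintf("manifest needs columns: %s",
                      paste(need_cols, collapse = ", ")))
  missing <- setdiff(manifest$library_id, lib_ids)
  assert_that(length(missing) == 0L,
              sprintf("no alignments for library: %s",
                      paste(missing, collapse = ", ")))
  if (is.null(manifest$replicate)) manifest$replicate <- 1L
  manifest
}

lib_class <- function(manifest, genotype, treatment) {
  manifest$library_id[manifest$genotype == genotype &
                      manifest$treatment == treatment]
}

#' Call lariat-enriched introns
#'
#' The enrichment rule: an intron is *enriched* iff its mean RPKM across
#' the mutant untreated (RNase R minus) libraries is at least `rpkm_min`
#' AND the BH-adjusted p-value of the conditional NB exact test
#' (mutant vs wild-type untreated counts) is below `fdr_max`. Then
#' *RNase-R-stable* iff additionally the mean RPKM across mutant RNase R
#' plus libraries is at least `rpkm_min`, and *wild-type expressed*
#' (escapee) iff additionally the mean RPKM across wild-type untreated
#' libraries is at least `rpkm_min` — the nesting mirrors the three-sheet
#' structure of a lariat catalog (all enriched > stable > escapee).
#'
#' @param iq result of [quantify_introns()].
#' @param config an [analysis_config()].
#' @param dispersion optional fixed NB dispersion.
#' @return `data.frame` (one row per intron): location, strand, intron id,
#'   per-class mean RPKM, `logFC`, `logCPM`, `p_value`, `fdr` and logical
#'   flags `enriched`, `rnase_r_stable`, `wt_expressed`.
#' @export
call_lariat_introns <- function(iq, config = analysis_config(),
                                dispersion = NULL) {
  man <- iq$manifest
  col0_m <- lib_class(man, "Col0", "RNaseR_minus")
  dbr1_m <- lib_class(man, "dbr1_2", "RNaseR_minus")
  dbr1_p <- lib_class(man, "dbr1_2", "RNaseR_plus")
  col0_p <- lib_class(man, "Col0", "RNaseR_plus")
  assert_that(length(col0_m) > 0L && length(dbr1_m) > 0L,
              "missing library class: RNase R(-) libraries for both genotypes")
  cols <- c(col0_m, dbr1_m)
  tt <- exact_test_table(
    iq$counts[, cols, drop = FALSE], iq$lib_sizes[cols],
    groups = c(rep("Col0", length(col0_m)), rep("dbr1_2", length(dbr1_m))),
    ref = "Col0", alt = "dbr1_2", dispersion = dispersion)
  mean_rpkm <- function(libs) if (length(libs))
    rowMeans(iq$rpkm[, libs, drop = FALSE]) else rep(NA_real_, nrow(iq$info))
  out <- cbind(iq$info, data.frame(
    rpkm_col0_rminus = mean_rpkm(col0_m),
    rpkm_dbr1_rminus = mean_rpkm(dbr1_m),
    rpkm_col0_rplus = mean_rpkm(col0_p),
    rpkm_dbr1_rplus = mean_rpkm(dbr1_p),
    logFC = tt$logFC, logCPM = tt$logCPM, p_value = tt$p_value,
    fdr = tt$fdr, stringsAsFactors = FALSE))
  out$enriched <- out$rpkm_dbr1_rminus >= config$rpkm_min &
    out$fdr < config$fdr_max
  out$rnase_r_stable <- if (length(dbr1_p))
    out$enriched & out$rpkm_dbr1_rplus >= config$rpkm_min
    else rep(NA, nrow(out))
  out$wt_expressed <- if (length(dbr1_p))
    out$rnase_r_stable & out$rpkm_col0_rminus >= config$rpkm_min
    else rep(NA, nrow(out))
  out
}

#' Call deregulated genes
#'
#' A gene is deregulated iff its mean RPKM reaches `rpkm_min` in *either*
#' genotype's untreated libraries and the exact-test FDR (mutant vs wild
#' type) is below `fdr_max`. Gene expression is quantified on
#' mRNA-compatible reads (every segment within the gene's exons, the
#' union-exon rule), so the mutant's intronic lariat burden does not leak
#' into gene-level counts; library sizes are composition-corrected by
#' median-of-ratios ([effective_library_sizes()]).
#'
#' @param aln_list named list of alignment `GRanges` (untreated libraries
#'   are used).
#' @param genome a `GenomeModel`.
#' @param manifest library manifest (see [quantify_introns()]).
#' @param config an [analysis_config()].
#' @param dispersion optional fixed NB dispersion.
#' @return `data.frame` per gene with RPKM per genotype, test fields and a
#'   `deregulated` flag.
#' @export
call_deregulated_genes <- function(aln_list, genome, manifest,
                                   config = analysis_config(),
                                   dispersion = NULL) {
  manifest <- check_manifest(manifest, names(aln_list))
  exons <- df_to_granges(genome$exons, genome, keep = "gene_id")
  ex_gene <- S4Vectors::mcols(exons)$gene_id
  ids <- unique(ex_gene)
  gene_len <- vapply(split(BiocGenerics::width(exons), ex_gene)[ids], sum, 0)
  col0_m <- lib_class(manifest, "Col0", "RNaseR_minus")
  dbr1_m <- lib_class(manifest, "dbr1_2", "RNaseR_minus")
  assert_that(length(col0_m) > 0L && length(dbr1_m) > 0L,
              "missing library class: RNase R(-) libraries for both genotypes")
  libs <- c(col0_m, dbr1_m)
  rpkm_m <- counts_m <- matrix(0, length(ids), length(libs),
                               dimnames = list(ids, libs))
  lib_sizes <- setNames(numeric(length(libs)), libs)
  for (lib in libs) {
    aln <- aln_list[[lib]]
    lib_sizes[lib] <- n_tags(aln)
    fil <- filter_reads_in_features(aln, exons, mode = "within",
                                    stranded = config$stranded,
                                    id_col = "gene_id")
    track <- compute_coverage(fil$aln, genome, stranded = config$stranded)
    re_ex <- region_read_equivalents(track, exons)
    re <- vapply(split(re_ex, ex_gene)[ids], sum, 0)
    rpkm_m[, lib] <- rpkm(re, gene_len, lib_sizes[lib])
    cnt <- table(factor(fil$assignment$feature_id, levels = ids))
    counts_m[, lib] <- as.integer(cnt)
  }
  eff_sizes <- effective_library_sizes(counts_m, lib_sizes)
  tt <- exact_test_table(
    counts_m, eff_sizes,
    groups = c(rep("Col0", length(col0_m)), rep("dbr1_2", length(dbr1_m))),
    ref = "Col0", alt = "dbr1_2", dispersion = dispersion)
  out <- data.frame(
    gene_id = ids,
    rpkm_col0 = rowMeans(rpkm_m[, col0_m, drop = FALSE]),
    rpkm_dbr1 = rowMeans(rpkm_m[, dbr1_m, drop = FALSE]),
    logFC = tt$logFC, logCPM = tt$logCPM, p_value = tt$p_value,
    fdr = tt$fdr, stringsAsFactors = FALSE)
  out$deregulated <- pmax(out$rpkm_col0, out$rpkm_dbr1) >= config$rpkm_min &
    out$fdr < config$fdr_max
  out
}

#' Detect branchpoint junction reads
#'
#' The in-silico analogue of divergent-primer PCR across the lariat 2'-5'
#' junction: a split read supports intron `I` at branch `b` iff one of its
#' segments lies within `I` with its strand-aware 3' end at `b`, and
#' another segment lies within `I` starting exactly at the intron's 5' end
#' (same strand). A branchpoint is called where at least `min_support`
#' junction reads agree; the reported branch position is the modal segment
#' end (ties resolved to the 3'-most coordinate).
#'
#' @param aln an alignment `GRanges` (or list of them, pooled).
#' @param genome a `GenomeModel`.
#' @param min_support minimum supporting junction reads.
#' @return `data.frame` with `intron_id`, `branch_pos`, `n_junction_reads`.
#' @export
detect_branchpoint_junctions <- function(aln, genome, min_support = 2L) {
  if (is.list(aln) && !inherits(aln, "GRanges")) {
    aln <- suppressWarnings(do.call(c, unname(aln)))
  }
  introns <- intron_ranges(genome)
  iid <- S4Vectors::mcols(introns)$intron_id
  rid <- S4Vectors::mcols(aln)$read_id
  multi <- rid %in% rid[duplicated(rid)]
  empty <- data.frame(intron_id = character(), branch_pos = integer(),
                      n_junction_reads = integer(), stringsAsFactors = FALSE)
  if (!any(multi)) return(empty)
  cand <- aln[multi]
  ov <- GenomicRanges::findOverlaps(cand, introns, type = "within")
  if (!length(ov)) return(empty)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  seg_str <- as.character(BiocGenerics::strand(cand))[qh]
  istr <- as.character(BiocGenerics::strand(introns))[sh]
  keep <- seg_str == istr
  qh <- qh[keep]; sh <- sh[keep]
  df <- data.frame(
    read_id = S4Vectors::mcols(cand)$read_id[qh],
    intron = sh,
    seg_start = BiocGenerics::start(cand)[qh],
    seg_end = BiocGenerics::end(cand)[qh],
    stringsAsFactors = FALSE)
  plus <- istr[keep] == "+"
  i5 <- ifelse(plus, BiocGenerics::start(introns)[sh],
               BiocGenerics::end(introns)[sh])
  # strand-aware: 5'-anchored segment starts at the intron 5' end;
  # the partner segment's 3' end is the branch candidate
  df$is_anchor <- ifelse(plus, df$seg_start == i5, df$seg_end == i5)
  df$branch_cand <- ifelse(plus, df$seg_end, df$seg_start)
  calls <- list()
  for (grp in split(df, df$intron)) {
    if (!any(grp$is_anchor)) next
    anchored_reads <- unique(grp$read_id[grp$is_anchor])
    partners <- grp[!grp$is_anchor & grp$read_id %in% anchored_reads, ,
                    drop = FALSE]
    if (!nrow(partners)) next
    support <- length(unique(partners$read_id))
    if (support < min_support) next
    tab <- table(partners$branch_cand)
    modal <- as.integer(names(tab)[tab == max(tab)])
    strand_i <- as.character(BiocGenerics::strand(introns))[grp$intron[1]]
    # 3'-most tie-break: largest coordinate on +, smallest on -
    branch <- if (strand_i == "+") max(modal) else min(modal)
    calls[[length(calls) + 1L]] <- data.frame(
      intron_id = iid[grp$intron[1]], branch_pos = branch,
      n_junction_reads = support, stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out[order(out$intron_id), , drop = FALSE]
}

#' Score lariat calls against the planted truth
#'
#' Sensitivity of the `enriched` call on the planted lariat introns;
#' empirical FDR of `enriched` against everything planted to accumulate in
#' the mutant (lariats and linear decoys both genuinely accumulate in the
#' untreated libraries); the fraction of enriched planted circles
#' classified RNase-R-stable; and the fraction of planted linear decoys
#' kept out of the stable catalog by the RNase R filter.
#'
#' @param calls table from [call_lariat_introns()].
#' @param truth planted truth (`attr(pool, "truth")`).
#' @return list of rates and counts.
#' @export
evaluate_lariat_calls <- function(calls, truth) {
  planted <- union(truth$lariat_introns, truth$decoy_introns)
  called <- calls$intron_id[calls$enriched]
  lar_called <- intersect(called, truth$lariat_introns)
  sens <- if (length(truth$lariat_introns))
    length(lar_called) / length(truth$lariat_introns) else NA_real_
  tp <- length(intersect(called, planted))
  fdr <- if (length(called)) 1 - tp / length(called) else 0
  circ_called <- calls[calls$intron_id %in% truth$lariat_introns &
                       calls$enriched, , drop = FALSE]
  stable_rate <- if (nrow(circ_called))
    mean(circ_called$rnase_r_stable) else NA_real_
  decoys <- calls[calls$intron_id %in% truth$decoy_introns, , drop = FALSE]
  decoy_rejected <- if (nrow(decoys))
    mean(!(decoys$enriched & decoys$rnase_r_stable)) else NA_real_
  esc_called <- calls[calls$intron_id %in% truth$lariat_introns &
                      !is.na(calls$rnase_r_stable) & calls$rnase_r_stable, ,
                      drop = FALSE]
  wt_frac <- if (nrow(esc_called)) mean(esc_called$wt_expressed) else NA_real_
  list(sensitivity = sens, empirical_fdr = fdr,
       circle_stable_rate = stable_rate,
       decoy_rejection_rate = decoy_rejected,
       wt_expressed_fraction = wt_frac,
       n_enriched = sum(calls$enriched),
       n_stable = sum(calls$rnase_r_stable, na.rm = TRUE),
       n_wt_expressed = sum(calls$wt_expressed, na.rm = TRUE))
}
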