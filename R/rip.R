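#' Pre-miRNA occupancy from RIP-seq
#'
#' Because pri-miRNA boundaries are ill-defined, dicing-complex occupancy
#' is scored on the pre-miRNA hairpin only: reads uniquely contained in a
#' pre-miRNA interval (strand-matched, every segment inside) are converted
#' to RPKM via coverage, per antibody and genotype. A pre-miRNA is
#' *detectable* when its RPKM reaches `rpkm_min` in either genotype
#' (inclusive by default; `strict = TRUE` uses a strictly-greater
#' comparison); the log2 mutant/wild-type RPKM ratio is reported for
#' detectable entries with both RPKMs positive.
#'
#' @param aln_list named list of alignment `GRanges`, one per IP library.
#' @param genome a `GenomeModel`.
#' @param manifest `data.frame` with `library_id`, `genotype`, `antibody`
#'   (e.g. `"DCL1"`, `"HYL1"`).
#' @param config an [analysis_config()].
#' @param strict use `>` instead of `>=` for detectability.
#' @return `data.frame` with one row per pre-miRNA x antibody: location,
#'   strand, `rpkm_col0`, `rpkm_dbr1`, `log2_ratio`, `detectable`.
#' @export
premirna_occupancy <- function(aln_list, genome, manifest,
                               config = analysis_config(),
                               strict = FALSE) {
  need_cols <- c("library_id", "genotype", "antibody")
  assert_that(all(need_cols %in% names(manifest)),
              sprintf("manifest needs columns: %s",
                      paste(need_cols, collapse = ", ")))
  missing <- setdiff(manifest$library_id, names(aln_list))
  assert_that(length(missing) == 0L,
              sprintf("no alignments for library: %s",
                      paste(missing, collapse = ", ")))
  pre <- premirna_ranges(genome)
  ids <- S4Vectors::mcols(pre)$mirna_id
  out <- list()
  for (ab in unique(manifest$antibody)) {
    lib_c <- manifest$library_id[manifest$antibody == ab &
                                 manifest$genotype == "Col0"]
    lib_d <- manifest$library_id[manifest$antibody == ab &
                                 manifest$genotype == "dbr1_2"]
    assert_that(length(lib_c) >= 1L && length(lib_d) >= 1L,
                sprintf("missing genotype library for antibody %s", ab))
    rpkm_one <- function(libs) {
      m <- vapply(libs, function(lib) {
        aln <- aln_list[[lib]]
        fil <- filter_reads_in_features(aln, pre, mode = "within",
                                        stranded = config$stranded,
                                        id_col = "mirna_id")
        track <- compute_coverage(fil$aln, genome,
                                  stranded = config$stranded)
        track$total_tags <- n_tags(aln)
        re <- region_read_equivalents(track, pre)
        as.numeric(rpkm(re, BiocGenerics::width(pre), n_tags(aln)))
      }, numeric(length(pre)))
      rowMeans(m)
    }
    r_c <- rpkm_one(lib_c); r_d <- rpkm_one(lib_d)
    det <- if (strict) pmax(r_c, r_d) > config$rpkm_min
           else pmax(r_c, r_d) >= config$rpkm_min
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = ids, antibody = ab,
      chrom = as.character(GenomeInfoDb::seqnames(pre)),
      start = BiocGenerics::start(pre), end = BiocGenerics::end(pre),
      strand = as.character(BiocGenerics::strand(pre)),
      rpkm_col0 = r_c, rpkm_dbr1 = r_d,
      log2_ratio = ifelse(det & r_c > 0 & r_d > 0, log2(r_d / r_c),
                          NA_real_),
      detectable = det, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify occupancy change
#'
#' Detectable pre-miRNAs are classified `deregulated_down` when their log2
#' mutant/wild-type ratio is strictly below `-log2fc_cut`,
#' `deregulated_up` when strictly above `+log2fc_cut`, `unchanged`
#' otherwise (a ratio of exactly +/-1 is unchanged — the cut is strict).
#'
#' @param table occupancy table from [premirna_occupancy()].
#' @param log2fc_cut fold-change cut on the log2 scale.
#' @return the table with an `occupancy_class` column.
#' @export
classify_occupancy <- function(table, log2fc_cut = 1) {
  cls <- rep(NA_character_, nrow(table))
  has <- table$detectable & !is.na(table$log2_ratio)
  cls[has] <- "unchanged"
  cls[has & table$log2_ratio < -log2fc_cut] <- "deregulated_down"
  cls[has & table$log2_ratio > log2fc_cut] <- "deregulated_up"
  table$occupancy_class <- cls
  table
}
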