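#' Default simulated genome
#'
#' The annotation frame used by the default experiment: 4 chromosomes of
#' 200 kb, 250 five-exon genes (1000 introns), 60 miRNA loci and 2 rRNA
#' loci.
#'
#' @param seed RNG seed.
#' @return a `GenomeModel`.
#' @export
default_genome <- function(seed = 42L) {
  build_genome(n_chrom = 4L, chrom_length = 2e5, n_genes = 250L,
               exons_per_gene = 5L, exon_length = c(120L, 180L),
               intron_length = c(200L, 400L), n_mirna = 60L, n_rrna = 2L,
               seed = seed)
}

#' Simulate a full dbr1 vs wild-type experiment
#'
#' Produces every library class of the study design from one seed:
#' ribo-depleted stranded RNA-seq of both genotypes with and without RNase
#' R (`replicates` each), small-RNA libraries of both genotypes, and
#' DCL1/HYL1 RIP-seq of both genotypes. Both genotypes share one base
#' transcript pool so the planted effects are the only systematic
#' differences. The ground-truth manifest (planted lariats and branch
#' points, escapees, decoys, deregulated genes, effect sizes) is returned
#' alongside the reads.
#'
#' @param genome a `GenomeModel` (default: [default_genome()]).
#' @param effects a [sim_effects()].
#' @param seed master seed; all library seeds derive from it.
#' @param replicates RNA-seq / small-RNA replicates per class.
#' @param depth_rnaseq,depth_srna,depth_rip reads per library.
#' @param read_length read length (bp) for aligned libraries.
#' @param p_junction probability a lariat read crosses the branch junction.
#' @param adapter small-RNA 3' adapter.
#' @param low_quality_fraction,noise_fraction small-RNA library impurities.
#' @return a list with `genome`, `effects`, `truth`, `alignments` +
#'   `manifest` (RNA-seq), `srna_reads` + `srna_manifest`, `rip_alignments`
#'   + `rip_manifest`, and `adapter`.
#' @export
simulate_experiment <- function(genome = NULL, effects = sim_effects(),
                                seed = 42L, replicates = 2L,
                                depth_rnaseq = 2e5, depth_srna = 1e6,
                                depth_rip = 2e5, read_length = 50L,
                                p_junction = 0.15,
                                adapter = "TGGAATTCTCGGGTGCCAAGG",
                                low_quality_fraction = 0.05,
                                noise_fraction = 0.05) {
  genome <- genome %||% default_genome(derive_seed(seed, "genome"))
  pools <- list(
    Col0 = deplete_rrna(simulate_pool(genome, "Col0", effects, seed),
                        effects$rrna_depletion),
    dbr1_2 = deplete_rrna(simulate_pool(genome, "dbr1_2", effects, seed),
                          effects$rrna_depletion))
  truth <- attr(pools$Col0, "truth")

  aln <- list(); man <- list()
  for (gt in c("Col0", "dbr1_2")) for (trt in c("RNaseR_minus",
                                                "RNaseR_plus"))
    for (r in seq_len(replicates)) {
      id <- sprintf("%s_%s_rep%d", gt, sub("RNaseR_", "R", trt), r)
      pool <- pools[[gt]]
      if (trt == "RNaseR_plus")
        pool <- apply_rnase_r(pool, effects$survival_circular,
                              effects$survival_linear)
      ls <- library_spec(id, gt, trt, "RNAseq", replicate = r,
                         depth = depth_rnaseq, read_length = read_length,
                         p_junction = p_junction,
                         seed = derive_seed(seed, id))
      aln[[id]] <- generate_alignments(pool, ls, genome,
                                       bio_dispersion =
                                         effects$bio_dispersion)
      man[[id]] <- data.frame(library_id = id, genotype = gt,
                              treatment = trt, replicate = r,
                              stringsAsFactors = FALSE)
    }

  srna <- list(); sman <- list()
  srna_bg <- simulate_srna_background(genome,
                                      seed = derive_seed(seed, "srnabg"))
  for (gt in c("Col0", "dbr1_2")) for (r in seq_len(replicates)) {
    id <- sprintf("%s_sRNA_rep%d", gt, r)
    ls <- library_spec(id, gt, "none", "sRNAseq", replicate = r,
                       depth = depth_srna, read_length = read_length,
                       seed = derive_seed(seed, id))
    srna[[id]] <- generate_small_rna_reads(
      pools[[gt]], ls, genome, adapter = adapter,
      low_quality_fraction = low_quality_fraction,
      noise_fraction = noise_fraction, background = srna_bg,
      bio_dispersion = effects$bio_dispersion)
    sman[[id]] <- data.frame(library_id = id, genotype = gt, replicate = r,
                             stringsAsFactors = FALSE)
  }

  rip <- list(); rman <- list()
  for (ab in c("DCL1", "HYL1")) for (gt in c("Col0", "dbr1_2")) {
    id <- sprintf("%s_RIP_%s", ab, gt)
    ls <- library_spec(id, gt, "none", paste0("RIP_", ab),
                       depth = depth_rip, read_length = read_length,
                       seed = derive_seed(seed, id))
    rip[[id]] <- generate_alignments(
      pools[[gt]], ls, genome,
      occupancy_factor = if (gt == "dbr1_2") effects$occupancy_reduction
                         else 1)
    rman[[id]] <- data.frame(library_id = id, genotype = gt, antibody = ab,
                             stringsAsFactors = FALSE)
  }

  list(genome = genome, effects = effects, truth = truth,
       alignments = aln, manifest = do.call(rbind, man),
       srna_reads = srna, srna_manifest = do.call(rbind, sman),
       rip_alignments = rip, rip_manifest = do.call(rbind, rman),
       adapter = adapter, seed = seed)
}

#' Run the lariat annotation pipeline on a simulated experiment
#'
#' Intron quantification, enrichment calling, RNase R stability and
#' wild-type escapee classification, branchpoint junction detection, and
#' deregulated-gene calling, plus scoring against the planted truth.
#'
#' @param sim result of [simulate_experiment()] (or an equivalent list of
#'   alignments/manifest/genome/truth).
#' @param config an [analysis_config()].
#' @return list: `introns` (the full intron table with flags),
#'   `branchpoints`, `genes`, `evaluation`.
#' @export
run_lariat_analysis <- function(sim, config = analysis_config()) {
  iq <- quantify_introns(sim$alignments, sim$genome, sim$manifest, config)
  introns <- call_lariat_introns(iq, config)
  dbr1_minus <- lib_class(sim$manifest, "dbr1_2", "RNaseR_minus")
  bp <- detect_branchpoint_junctions(sim$alignments[dbr1_minus],
                                     sim$genome, config$min_support)
  genes <- call_deregulated_genes(sim$alignments, sim$genome, sim$manifest,
                                  config)
  ev <- if (!is.null(sim$truth)) evaluate_lariat_calls(introns, sim$truth)
        else NULL
  list(introns = introns, branchpoints = bp, genes = genes,
       evaluation = ev)
}

#' Run the small-RNA miRNA analysis on a simulated experiment
#'
#' Processes each small-RNA library (quality filter, adapter trim,
#' collapse, assignment against the genome's mature miRNA sequences),
#' builds the per-replicate RPTM fold-change table and the commonly
#' reduced set.
#'
#' @param sim result of [simulate_experiment()].
#' @param config an [analysis_config()].
#' @return list: `table` (per miRNA x replicate), `common_reduced`,
#'   `median_log2_ratio`, `per_library` accounting.
#' @export
run_mirna_analysis <- function(sim, config = analysis_config()) {
  mat <- mature_ranges(sim$genome)
  mature <- setNames(as.character(feature_seq(sim$genome, mat)),
                     S4Vectors::mcols(mat)$mirna_id)
  per_lib <- lapply(sim$srna_reads, mirna_count_pipeline, mature = mature,
                    adapter = sim$adapter)
  counts <- lapply(per_lib, `[[`, "counts")
  tags <- vapply(per_lib, `[[`, 0, "total_tags")
  tab <- fold_change_table(counts, tags, sim$srna_manifest, config)
  reps <- sort(unique(tab$replicate))
  common <- if (length(reps) >= 2L)
    intersect_reduced(tab[tab$replicate == reps[1], ],
                      tab[tab$replicate == reps[2], ]) else character(0)
  list(table = tab, common_reduced = common,
       median_log2_ratio = median(tab$log2_ratio, na.rm = TRUE),
       per_library = per_lib)
}

#' Run the RIP-seq occupancy analysis on a simulated experiment
#'
#' @param sim result of [simulate_experiment()].
#' @param config an [analysis_config()].
#' @return the classified occupancy table (see [classify_occupancy()]).
#' @export
run_rip_analysis <- function(sim, config = analysis_config()) {
  occ <- premirna_occupancy(sim$rip_alignments, sim$genome,
                            sim$rip_manifest, config)
  classify_occupancy(occ, config$log2fc_cut)
}

#' Write a simulated experiment to disk
#'
#' Emits the plain-text artifact set of one run: `genome.fa`,
#' `annotation.gff3`, one BED12 per aligned library, one FASTQ per
#' small-RNA library, `mature_mirnas.fa`, library manifests and
#' ground-truth TSVs.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_annotation_gff3(sim$genome, fp("annotation.gff3"))
  for (id in names(sim$alignments))
    write_bed12(sim$alignments[[id]], fp(paste0(id, ".bed")))
  for (id in names(sim$rip_alignments))
    write_bed12(sim$rip_alignments[[id]], fp(paste0(id, ".bed")))
  for (id in names(sim$srna_reads))
    write_fastq(sim$srna_reads[[id]], fp(paste0(id, ".fastq")))
  mat <- mature_ranges(sim$genome)
  seqs <- feature_seq(sim$genome, mat)
  names(seqs) <- S4Vectors::mcols(mat)$mirna_id
  Biostrings::writeXStringSet(seqs, fp("mature_mirnas.fa"))
  wt <- function(df, f) write.table(df, fp(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(sim$manifest, "manifest_rnaseq.tsv")
  wt(sim$srna_manifest, "manifest_srna.tsv")
  wt(sim$rip_manifest, "manifest_rip.tsv")
  tr <- sim$truth
  wt(data.frame(intron_id = tr$lariat_introns,
                escapee = tr$lariat_introns %in% tr$escapee_introns,
                branch_pos = unname(tr$branch_points[tr$lariat_introns])),
     "truth_lariats.tsv")
  wt(data.frame(intron_id = tr$decoy_introns), "truth_decoys.tsv")
  wt(data.frame(gene_id = tr$deregulated_genes),
     "truth_deregulated_genes.tsv")
  invisible(dir)
}

#' Load a written experiment back from disk
#'
#' Re-reads the artifact set of [write_experiment()] so the analysis can be
#' run file-based (as the command-line interface does).
#'
#' @param dir directory written by [write_experiment()].
#' @param read_length read length used at simulation time.
#' @return a `sim`-shaped list (without `effects`).
#' @export
read_experiment <- function(dir, read_length = 50L) {
  fp <- function(...) file.path(dir, ...)
  assert_that(file.exists(fp("annotation.gff3")),
              sprintf("no annotation.gff3 under %s", dir))
  genome <- read_annotation(fp("annotation.gff3"),
                            seq = if (file.exists(fp("genome.fa")))
                              read_genome_fasta(fp("genome.fa")) else NULL)
  manifest <- read.delim(fp("manifest_rnaseq.tsv"),
                         stringsAsFactors = FALSE)
  aln <- list()
  for (id in manifest$library_id) {
    f <- fp(paste0(id, ".bed"))
    assert_that(file.exists(f),
                sprintf("missing alignment file for library %s", id))
    aln[[id]] <- read_alignments(f, "bed12", genome, library_id = id,
                                 read_length = read_length)
  }
  rip_manifest <- NULL; rip <- list()
  if (file.exists(fp("manifest_rip.tsv"))) {
    rip_manifest <- read.delim(fp("manifest_rip.tsv"),
                               stringsAsFactors = FALSE)
    for (id in rip_manifest$library_id)
      rip[[id]] <- read_alignments(fp(paste0(id, ".bed")), "bed12", genome,
                                   library_id = id,
                                   read_length = read_length)
  }
  srna_manifest <- NULL; srna <- list()
  if (file.exists(fp("manifest_srna.tsv"))) {
    srna_manifest <- read.delim(fp("manifest_srna.tsv"),
                                stringsAsFactors = FALSE)
    for (id in srna_manifest$library_id)
      srna[[id]] <- read_fastq(fp(paste0(id, ".fastq")))
  }
  truth <- NULL
  if (file.exists(fp("truth_lariats.tsv"))) {
    lar <- read.delim(fp("truth_lariats.tsv"), stringsAsFactors = FALSE)
    dec <- read.delim(fp("truth_decoys.tsv"), stringsAsFactors = FALSE)
    der <- read.delim(fp("truth_deregulated_genes.tsv"),
                      stringsAsFactors = FALSE)
    truth <- list(lariat_introns = lar$intron_id,
                  escapee_introns = lar$intron_id[lar$escapee],
                  decoy_introns = dec$intron_id,
                  deregulated_genes = der$gene_id,
                  branch_points = setNames(lar$branch_pos, lar$intron_id))
  }
  mature <- if (file.exists(fp("mature_mirnas.fa")))
    read_genome_fasta(fp("mature_mirnas.fa")) else NULL
  list(genome = genome, truth = truth, alignments = aln,
       manifest = manifest, srna_reads = srna,
       srna_manifest = srna_manifest, rip_alignments = rip,
       rip_manifest = rip_manifest, mature = mature,
       adapter = "TGGAATTCTCGGGTGCCAAGG")
}
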