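#' Simulation effect sizes
#'
#' Bundles the biological effect sizes the simulator plants, with defaults
#' reflecting the debranching-deficient (dbr1) vs wild-type (Col-0) study
#' design this pipeline analyzes:
#'
#' * `lariat_fold_dbr1`: over-accumulation of intron lariats in the mutant.
#' * `escape_fraction`: fraction of lariat-forming introns whose lariats
#'   naturally escape debranching and are therefore present in wild type
#'   (default 0.23, the escapee fraction observed among stable lariats).
#' * `mirna_reduction`: multiplier on mature miRNA abundance in the mutant
#'   (default 0.5, a genome-wide two-fold reduction).
#' * `occupancy_reduction`: multiplier on dicing-complex IP enrichment of
#'   pre-miRNAs in the mutant.
#' * `survival_circular`, `survival_linear`: RNase R survival probabilities
#'   for circular loops vs linear RNA.
#' * `lariat_fraction`: fraction of introns that form detectable lariats.
#' * `decoy_fraction`: fraction of introns planted as *linear* intronic RNA
#'   accumulating in the mutant — decoys that look lariat-like in untreated
#'   libraries but are RNase R sensitive.
#' * `gene_fold`, `deregulated_fraction`: planted gene-level deregulation.
#' * `premrna_fraction`: unspliced pre-mRNA abundance relative to mRNA,
#'   giving introns a low linear background.
#' * `rrna_abundance`, `rrna_depletion`: rRNA load and the efficiency of the
#'   ribo-depletion step applied before library emission.
#' * `lariat_base_abundance`, `decoy_base_abundance`: mean abundance of the
#'   planted lariat loops and linear decoys (mRNA mean is 1). The defaults
#'   place the mutant's lariats well above, and RNase-R-digested decoys
#'   well below, the 5 RPKM working threshold at the default depths.
#' * `ip_enrichment`: fold over-sampling of pre-miRNA reads in IP
#'   libraries; `bg_ip_ratio`: nonspecific background-to-IP weight ratio of
#'   an IP library (the carry-over mass, equal across genotypes, that
#'   anchors the cross-genotype occupancy comparison).
#' * `bio_dispersion`: squared biological CV between replicate libraries;
#'   per-library expected counts get a Gamma factor with this dispersion,
#'   giving replicate counts negative-binomial marginals.
#'
#' @param lariat_fold_dbr1,escape_fraction,mirna_reduction,occupancy_reduction
#'   see above.
#' @param survival_circular,survival_linear RNase R survival in `[0,1]`.
#' @param lariat_fraction,decoy_fraction,gene_fold,deregulated_fraction,premrna_fraction,rrna_abundance,rrna_depletion,lariat_base_abundance,decoy_base_abundance,ip_enrichment,bg_ip_ratio,bio_dispersion
#'   see above.
#' @return an object of class `sim_effects`.
#' @export
sim_effects <- function(lariat_fold_dbr1 = 8, escape_fraction = 0.23,
                        mirna_reduction = 0.5, occupancy_reduction = 0.4,
                        survival_circular = 0.9, survival_linear = 0.01,
                        lariat_fraction = 0.1, decoy_fraction = 0.05,
                        gene_fold = 4, deregulated_fraction = 0.1,
                        premrna_fraction = 1e-4, rrna_abundance = 50,
                        rrna_depletion = 0.99, lariat_base_abundance = 2,
                        decoy_base_abundance = 0.003,
                        ip_enrichment = 10, bg_ip_ratio = 9,
                        bio_dispersion = 0.05) {
  eff <- as.list(environment())
  mult <- c("lariat_fold_dbr1", "mirna_reduction", "occupancy_reduction",
            "gene_fold", "ip_enrichment", "rrna_abundance",
            "lariat_base_abundance", "decoy_base_abundance",
            "premrna_fraction", "bg_ip_ratio", "bio_dispersion")
  for (m in mult) assert_that(eff[[m]] >= 0, sprintf("%s must be >= 0", m))
  prob <- c("escape_fraction", "survival_circular", "survival_linear",
            "lariat_fraction", "decoy_fraction", "deregulated_fraction",
            "rrna_depletion")
  for (p in prob) assert_that(eff[[p]] >= 0 && eff[[p]] <= 1,
                              sprintf("%s must be in [0,1]", p))
  structure(eff, class = "sim_effects")
}

#' Simulate the transcript pool of one genotype
#'
#' Generates the species pool the library preparation then samples from:
#' spliced mRNA and unspliced pre-mRNA per gene, circular lariat loops
#' (branch point to intron 5' end) and linear debranched-intron decoys per
#' planted intron, pre-miRNA hairpins, mature miRNAs and rRNA. Base
#' abundances are Gamma-distributed across features (shape 0.6) and are a
#' function of `(genome, seed)` only, so the two genotypes of one experiment
#' share base abundances and differ exactly by the planted effects:
#'
#' * lariat loops: wild type carries `base` for escapee introns and 0
#'   otherwise; the mutant carries `base * lariat_fold_dbr1` for every
#'   planted lariat intron.
#' * linear decoys: 0 in wild type, `base * lariat_fold_dbr1` in the mutant.
#' * mature miRNA: mutant abundance is wild type times `mirna_reduction`.
#' * planted deregulated genes: mRNA times `gene_fold` in the mutant.
#'
#' @param genome a `GenomeModel`.
#' @param genotype `"Col0"` or `"dbr1_2"`.
#' @param effects a [sim_effects()] object.
#' @param seed RNG seed shared by both genotypes of an experiment.
#' @return a `data.frame` pool with one row per transcript species
#'   (`species_id`, `kind`, `topology`, `feature_id`, `chrom`, `strand`,
#'   `length`, `abundance`, `branch_pos`, and a `blocks` list-column of
#'   genomic intervals in transcript order), with the planted truth in
#'   `attr(pool, "truth")`.
#' @export
simulate_pool <- function(genome, genotype = c("Col0", "dbr1_2"),
                          effects = sim_effects(), seed = 1L) {
  if (!genotype[1] %in% c("Col0", "dbr1_2"))
    stop(sprintf("unknown genotype '%s'", genotype[1]), call. = FALSE)
  genotype <- genotype[1]
  base <- pool_base(genome, effects, seed)
  mut <- genotype == "dbr1_2"

  sp <- base$species
  ab <- sp$base_abundance
  ab[sp$kind == "mRNA" & sp$planted_dereg & mut] <-
    ab[sp$kind == "mRNA" & sp$planted_dereg & mut] * effects$gene_fold
  is_lar <- sp$kind == "lariat_circle"
  ab[is_lar] <- if (mut) ab[is_lar] * effects$lariat_fold_dbr1
                else ab[is_lar] * as.numeric(sp$escapee[is_lar])
  is_dec <- sp$kind == "debranched_intron"
  ab[is_dec] <- if (mut) ab[is_dec] * effects$lariat_fold_dbr1 else 0
  is_mat <- sp$kind == "mature_miRNA"
  if (mut) ab[is_mat] <- ab[is_mat] * effects$mirna_reduction
  # pre_mRNA tracks its gene's (possibly deregulated) mRNA level
  is_pre <- sp$kind == "pre_mRNA"
  ab[is_pre & sp$planted_dereg & mut] <-
    ab[is_pre & sp$planted_dereg & mut] * effects$gene_fold

  pool <- sp[, c("species_id", "kind", "topology", "feature_id", "chrom",
                 "strand", "length", "branch_pos")]
  pool$abundance <- ab
  pool$blocks <- sp$blocks
  pool$genotype <- genotype
  attr(pool, "truth") <- base$truth
  attr(pool, "effects") <- effects
  class(pool) <- c("transcript_pool", "data.frame")
  pool
}

# Genotype-independent species table + planted truth. Pure in (genome,
# effects, seed).
pool_base <- function(genome, effects, seed) {
  with_seed(derive_seed(seed, "pool"), {
    gam <- function(n, mean = 1) rgamma(n, shape = 0.6, rate = 0.6 / mean)
    g <- genome$genes; introns <- genome$introns; m <- genome$mirna
    n_in <- nrow(introns)

    n_lar <- round(effects$lariat_fraction * n_in)
    lar_idx <- if (n_lar > 0L) sort(sample.int(n_in, n_lar)) else integer(0)
    esc <- rep(FALSE, n_in)
    n_esc <- round(effects$escape_fraction * n_lar)
    if (n_esc > 0L) esc[lar_idx[sample.int(length(lar_idx), n_esc)]] <- TRUE
    rest <- setdiff(seq_len(n_in), lar_idx)
    n_dec <- min(round(effects$decoy_fraction * n_in), length(rest))
    dec_idx <- if (n_dec > 0L) sort(rest[sample.int(length(rest), n_dec)])
               else integer(0)

    n_dereg <- round(effects$deregulated_fraction * nrow(g))
    dereg_genes <- if (n_dereg > 0L)
      g$gene_id[sort(sample.int(nrow(g), n_dereg))] else character(0)

    rows <- list()
    add <- function(df) rows[[length(rows) + 1L]] <<- df

    # spliced mRNA: exon blocks in transcript order
    mrna_ab <- gam(nrow(g))
    ex_by_gene <- split(genome$exons, genome$exons$gene_id)
    mk_blocks <- function(ex) {
      ex <- ex[order(ex$start, decreasing = ex$strand[1] == "-"), ]
      cbind(start = ex$start, end = ex$end)
    }
    gene_blocks <- lapply(g$gene_id, function(id) mk_blocks(ex_by_gene[[id]]))
    add(data.frame(
      species_id = paste0(g$gene_id, "_mRNA"), kind = "mRNA",
      topology = "linear", feature_id = g$gene_id, chrom = g$chrom,
      strand = g$strand,
      length = vapply(gene_blocks, function(b) sum(b[, 2] - b[, 1] + 1L), 0),
      base_abundance = mrna_ab, branch_pos = NA_integer_,
      planted_dereg = g$gene_id %in% dereg_genes,
      escapee = FALSE, stringsAsFactors = FALSE))
    rows[[length(rows)]]$blocks <- lapply(gene_blocks, identity)

    # unspliced pre-mRNA: whole gene span
    add(data.frame(
      species_id = paste0(g$gene_id, "_premRNA"), kind = "pre_mRNA",
      topology = "linear", feature_id = g$gene_id, chrom = g$chrom,
      strand = g$strand, length = g$end - g$start + 1L,
      base_abundance = effects$premrna_fraction * mrna_ab,
      branch_pos = NA_integer_,
      planted_dereg = g$gene_id %in% dereg_genes,
      escapee = FALSE, stringsAsFactors = FALSE))
    rows[[length(rows)]]$blocks <- lapply(seq_len(nrow(g)), function(i)
      cbind(start = g$start[i], end = g$end[i]))

    # planted classes use a tighter abundance law (shape 3) than the
    # expression-like gamma (shape 0.6): the planted effect strength is a
    # controlled study condition, not free biological variation
    lar_ab <- rgamma(n_in, shape = 3,
                     rate = 3 / effects$lariat_base_abundance)
    dec_ab <- rgamma(n_in, shape = 3,
                     rate = 3 / effects$decoy_base_abundance)
    if (length(lar_idx)) {
      li <- introns[lar_idx, ]
      # loop spans intron 5' end to branch point
      loop_s <- ifelse(li$strand == "+", li$start, li$branch_pos)
      loop_e <- ifelse(li$strand == "+", li$branch_pos, li$end)
      add(data.frame(
        species_id = paste0(li$intron_id, "_lariat"), kind = "lariat_circle",
        topology = "circular", feature_id = li$intron_id, chrom = li$chrom,
        strand = li$strand, length = loop_e - loop_s + 1L,
        base_abundance = lar_ab[lar_idx], branch_pos = li$branch_pos,
        planted_dereg = FALSE, escapee = esc[lar_idx],
        stringsAsFactors = FALSE))
      rows[[length(rows)]]$blocks <- lapply(seq_len(nrow(li)), function(i)
        cbind(start = loop_s[i], end = loop_e[i]))
    }
    if (length(dec_idx)) {
      di <- introns[dec_idx, ]
      add(data.frame(
        species_id = paste0(di$intron_id, "_linear"),
        kind = "debranched_intron", topology = "linear",
        feature_id = di$intron_id, chrom = di$chrom, strand = di$strand,
        length = di$end - di$start + 1L, base_abundance = dec_ab[dec_idx],
        branch_pos = NA_integer_, planted_dereg = FALSE, escapee = FALSE,
        stringsAsFactors = FALSE))
      rows[[length(rows)]]$blocks <- lapply(seq_len(nrow(di)), function(i)
        cbind(start = di$start[i], end = di$end[i]))
    }

    if (nrow(m)) {
      # miRNA genes are constitutively expressed: tighter spread (shape 3)
      pre_ab <- rgamma(nrow(m), shape = 3, rate = 3)
      mat_ab <- gam(nrow(m))
      add(data.frame(
        species_id = paste0(m$mirna_id, "_pre"), kind = "pre_miRNA",
        topology = "linear", feature_id = m$mirna_id, chrom = m$chrom,
        strand = m$strand, length = m$pre_end - m$pre_start + 1L,
        base_abundance = pre_ab, branch_pos = NA_integer_,
        planted_dereg = FALSE, escapee = FALSE, stringsAsFactors = FALSE))
      rows[[length(rows)]]$blocks <- lapply(seq_len(nrow(m)), function(i)
        cbind(start = m$pre_start[i], end = m$pre_end[i]))
      add(data.frame(
        species_id = paste0(m$mirna_id, "_mature"), kind = "mature_miRNA",
        topology = "linear", feature_id = m$mirna_id, chrom = m$chrom,
        strand = m$strand, length = m$mature_end - m$mature_start + 1L,
        base_abundance = mat_ab, branch_pos = NA_integer_,
        planted_dereg = FALSE, escapee = FALSE, stringsAsFactors = FALSE))
      rows[[length(rows)]]$blocks <- lapply(seq_len(nrow(m)), function(i)
        cbind(start = m$mature_start[i], end = m$mature_end[i]))
    }

    r <- genome$rrna
    if (nrow(r)) {
      add(data.frame(
        species_id = r$rrna_id, kind = "rRNA", topology = "linear",
        feature_id = r$rrna_id, chrom = r$chrom, strand = r$strand,
        length = r$end - r$start + 1L,
        base_abundance = rep(effects$rrna_abundance, nrow(r)),
        branch_pos = NA_integer_, planted_dereg = FALSE, escapee = FALSE,
        stringsAsFactors = FALSE))
      rows[[length(rows)]]$blocks <- lapply(seq_len(nrow(r)), function(i)
        cbind(start = r$start[i], end = r$end[i]))
    }

    species <- do.call(rbind, rows)
    rownames(species) <- NULL
    truth <- list(
      lariat_introns = introns$intron_id[lar_idx],
      escapee_introns = introns$intron_id[lar_idx][esc[lar_idx]],
      decoy_introns = introns$intron_id[dec_idx],
      deregulated_genes = dereg_genes,
      branch_points = if (length(lar_idx))
        setNames(introns$branch_pos[lar_idx], introns$intron_id[lar_idx])
        else integer(0),
      mirna_reduction = effects$mirna_reduction,
      occupancy_reduction = effects$occupancy_reduction)
    list(species = species, truth = truth)
  })
}

#' Apply in-vitro RNase R digestion to a pool
#'
#' RNase R is a 3'->5' exoribonuclease: it degrades linear RNA but cannot
#' attack the closed loop of a lariat (or any circular RNA). Abundances of
#' linear species are multiplied by `survival_linear`, circular species by
#' `survival_circular`; species identity and order are preserved.
#'
#' @param pool a pool from [simulate_pool()].
#' @param survival_circular,survival_linear survival probabilities in `[0,1]`.
#' @return the pool with digested abundances.
#' @export
apply_rnase_r <- function(pool, survival_circular = 0.9,
                          survival_linear = 0.01) {
  assert_that(survival_circular >= 0 && survival_circular <= 1 &&
              survival_linear >= 0 && survival_linear <= 1,
              "survival probabilities must be in [0,1]")
  circ <- pool$topology == "circular"
  pool$abundance[circ] <- pool$abundance[circ] * survival_circular
  pool$abundance[!circ] <- pool$abundance[!circ] * survival_linear
  pool
}

#' Deplete rRNA from a pool (ribo-depletion step)
#'
#' Models the ribosomal RNA depletion performed before library construction;
#' rRNA species abundances are multiplied by `1 - efficiency`.
#'
#' @param pool a pool from [simulate_pool()].
#' @param efficiency depletion efficiency in `[0,1]`.
#' @return the pool with depleted rRNA.
#' @export
deplete_rrna <- function(pool, efficiency = 0.99) {
  assert_that(efficiency >= 0 && efficiency <= 1,
              "efficiency must be in [0,1]")
  is_r <- pool$kind == "rRNA"
  pool$abundance[is_r] <- pool$abundance[is_r] * (1 - efficiency)
  pool
}
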