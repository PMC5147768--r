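#' Library specification
#'
#' Describes one sequencing library of the simulated experiment.
#'
#' @param library_id unique identifier.
#' @param genotype `"Col0"` or `"dbr1_2"`.
#' @param treatment `"RNaseR_minus"`, `"RNaseR_plus"` or `"none"`.
#' @param assay `"RNAseq"`, `"sRNAseq"`, `"RIP_DCL1"` or `"RIP_HYL1"`.
#' @param replicate replicate index.
#' @param depth number of reads to emit.
#' @param read_length read length in bp.
#' @param p_junction probability that a lariat-derived read crosses the
#'   2'-5' branch junction.
#' @param seed RNG seed for this library's read sampling.
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(library_id, genotype = c("Col0", "dbr1_2"),
                         treatment = c("RNaseR_minus", "RNaseR_plus", "none"),
                         assay = c("RNAseq", "sRNAseq", "RIP_DCL1",
                                   "RIP_HYL1"),
                         replicate = 1L, depth = 2e5, read_length = 50L,
                         p_junction = 0.15, seed = 1L) {
  genotype <- match.arg(genotype); treatment <- match.arg(treatment)
  assay <- match.arg(assay)
  assert_that(depth > 0, "depth must be > 0")
  assert_that(read_length > 0, "read_length must be > 0")
  assert_that(p_junction >= 0 && p_junction <= 1,
              "p_junction must be in [0,1]")
  structure(list(library_id = library_id, genotype = genotype,
                 treatment = treatment, assay = assay,
                 replicate = as.integer(replicate), depth = as.integer(depth),
                 read_length = as.integer(read_length),
                 p_junction = p_junction, seed = as.integer(seed)),
            class = "library_spec")
}

# Map transcript windows [s,e] (1-based, transcript coordinates) through a
# species' genomic blocks (transcript order). Returns one row per genomic
# segment with the originating window index.
map_transcript_windows <- function(blocks, strand, s, e) {
  w <- blocks[, 2] - blocks[, 1] + 1L
  off <- cumsum(c(0L, w))[seq_len(nrow(blocks))]
  out_idx <- integer(0); out_s <- integer(0); out_e <- integer(0)
  for (j in seq_len(nrow(blocks))) {
    ts <- off[j] + 1L; te <- off[j] + w[j]
    os <- pmax(s, ts); oe <- pmin(e, te)
    hit <- which(os <= oe)
    if (!length(hit)) next
    if (strand == "+") {
      gs <- blocks[j, 1] + (os[hit] - ts)
      ge <- blocks[j, 1] + (oe[hit] - ts)
    } else {
      gs <- blocks[j, 2] - (oe[hit] - ts)
      ge <- blocks[j, 2] - (os[hit] - ts)
    }
    out_idx <- c(out_idx, hit); out_s <- c(out_s, gs); out_e <- c(out_e, ge)
  }
  list(idx = out_idx, start = out_s, end = out_e)
}

#' Generate aligned reads for an RNA-seq or RIP-seq library
#'
#' Reads are drawn multinomially across species with weight
#' `abundance x length` (molar abundance times sampleable positions); in IP
#' assays pre-miRNA species are over-sampled by `ip_enrichment x
#' occupancy_factor`. Reads from circular lariat loops cross the branch
#' junction with probability `p_junction` and are emitted as two-segment
#' records: one segment ends at the branch point and the other starts at the
#' intron 5' end, mirroring how reverse transcription runs across the 2'-5'
#' junction (the branch adenosine reads as T in cDNA). Spliced mRNA reads
#' spanning exon boundaries become multi-segment records too. The output is
#' a pure function of `(pool, libspec, genome)`.
#'
#' Mature miRNA species are not sampled here (they are below the library
#' insert-size floor); use [generate_small_rna_reads()] for small-RNA
#' libraries.
#'
#' @param pool a pool from [simulate_pool()] (after [deplete_rrna()] /
#'   [apply_rnase_r()] as appropriate).
#' @param libspec a [library_spec()] with assay `RNAseq`, `RIP_DCL1` or
#'   `RIP_HYL1`.
#' @param genome the `GenomeModel`.
#' @param occupancy_factor attenuation of IP enrichment (use the planted
#'   `occupancy_reduction` for mutant IP libraries).
#' @param min_fragment_length species shorter than this are not sampled.
#' @param bio_dispersion replicate-level biological dispersion: each
#'   species' sampling weight gets an independent Gamma factor of this
#'   squared CV, so replicate libraries have NB count marginals.
#' @return an alignment `GRanges` (see [alignment_set()]); junction-read
#'   ground truth in `attr(, "junction_truth")` and per-species read counts
#'   in `attr(, "species_counts")`.
#' @export
generate_alignments <- function(pool, libspec, genome,
                                occupancy_factor = 1,
                                min_fragment_length = 60L,
                                bio_dispersion = 0) {
  assert_that(libspec$assay %in% c("RNAseq", "RIP_DCL1", "RIP_HYL1"),
              "assay must be RNAseq or RIP for aligned-read generation")
  assert_that(nrow(pool) > 0L, "pool is empty")
  rl <- libspec$read_length
  w <- pool$abundance * pool$length
  w[pool$kind == "mature_miRNA" | pool$length < min_fragment_length] <- 0
  if (libspec$assay %in% c("RIP_DCL1", "RIP_HYL1")) {
    eff <- attr(pool, "effects")
    ip <- if (is.null(eff)) 10 else eff$ip_enrichment
    bg_ratio <- if (is.null(eff)) 9 else eff$bg_ip_ratio %||% 9
    is_pre <- pool$kind == "pre_miRNA"
    # nonspecific carry-over: fixed mass relative to the full (unreduced)
    # IP weight, identical across genotypes, anchoring the comparison
    w_ip_full <- ip * sum(w[is_pre])
    w_bg <- sum(w[!is_pre])
    if (w_bg > 0 && w_ip_full > 0)
      w[!is_pre] <- w[!is_pre] * (bg_ratio * w_ip_full / w_bg)
    w[is_pre] <- w[is_pre] * ip * occupancy_factor
  }
  if (sum(w) <= 0) stop("pool has zero total abundance", call. = FALSE)

  with_seed(derive_seed(libspec$seed, libspec$library_id), {
    if (bio_dispersion > 0)
      w <- w * rgamma(length(w), shape = 1 / bio_dispersion,
                      rate = 1 / bio_dispersion)
    n_per <- as.integer(rmultinom(1L, libspec$depth, w))
    keep <- which(n_per > 0L)
    acc <- vector("list", length(keep) * 3L)
    ai <- 0L
    push <- function(m, rids, chrom, strand) {
      ai <<- ai + 1L
      acc[[ai]] <<- list(chrom = rep(chrom, length(m$idx)),
                         start = m$start, end = m$end,
                         strand = rep(strand, length(m$idx)),
                         read_id = rids[m$idx])
    }
    jt <- list()
    read_counter <- 0L
    for (si in keep) {
      n <- n_per[si]
      blocks <- pool$blocks[[si]]
      strand <- pool$strand[si]
      L <- pool$length[si]
      ids <- sprintf("%s_r%08d", libspec$library_id,
                     read_counter + seq_len(n))
      read_counter <- read_counter + n
      if (pool$topology[si] == "circular") {
        rle_ <- min(rl, L)
        can_cross <- rle_ >= 2L && L > rle_
        cross <- if (can_cross) runif(n) < libspec$p_junction
                 else rep(FALSE, n)
        n_c <- sum(cross); n_nc <- n - n_c
        if (n_nc > 0L) {
          s <- runif_int(n_nc, 1L, L - rle_ + 1L)
          push(map_transcript_windows(blocks, strand, s, s + rle_ - 1L),
               ids[!cross], pool$chrom[si], strand)
        }
        if (n_c > 0L) {
          s <- runif_int(n_c, L - rle_ + 2L, L)
          ov <- s + rle_ - 1L - L
          cids <- ids[cross]
          push(map_transcript_windows(blocks, strand, s, rep(L, n_c)),
               cids, pool$chrom[si], strand)
          push(map_transcript_windows(blocks, strand, rep(1L, n_c), ov),
               cids, pool$chrom[si], strand)
          jt[[length(jt) + 1L]] <- data.frame(
            read_id = cids, intron_id = pool$feature_id[si],
            branch_pos = pool$branch_pos[si], stringsAsFactors = FALSE)
        }
      } else {
        if (L <= rl) {
          s <- rep(1L, n); e <- rep(L, n)
        } else {
          s <- runif_int(n, 1L, L - rl + 1L); e <- s + rl - 1L
        }
        push(map_transcript_windows(blocks, strand, s, e),
             ids, pool$chrom[si], strand)
      }
    }
    acc <- acc[seq_len(ai)]
    pull <- function(fld) unlist(lapply(acc, `[[`, fld), use.names = FALSE)
    gr <- GenomicRanges::GRanges(
      seqnames = pull("chrom"),
      ranges = IRanges::IRanges(start = pull("start"), end = pull("end")),
      strand = pull("strand"), read_id = pull("read_id"),
      seqinfo = genome$seqinfo)
    aln <- alignment_set(gr, library_id = libspec$library_id,
                         read_length = rl)
    attr(aln, "junction_truth") <- if (length(jt)) do.call(rbind, jt) else
      data.frame(read_id = character(), intron_id = character(),
                 branch_pos = integer(), stringsAsFactors = FALSE)
    attr(aln, "species_counts") <-
      setNames(n_per, pool$species_id)
    aln
  })
}

#' Generate a small-RNA FASTQ library
#'
#' Emits mature miRNA sequences with the 3' sequencing adapter appended,
#' padded/truncated to the library read length, with per-base quality
#' strings. A configurable fraction of reads carries more than five bases
#' below Q20 so the downstream quality filter has work to do. In exhaustive
#' mode each mature species is emitted exactly `round(abundance)` times
#' (the planted counts); otherwise `depth` reads are drawn multinomially by
#' abundance. Deterministic given the library seed.
#'
#' @param pool a pool from [simulate_pool()].
#' @param libspec a [library_spec()] with assay `sRNAseq`.
#' @param genome the `GenomeModel` (source of mature sequences).
#' @param adapter 3' adapter sequence (non-empty).
#' @param low_quality_fraction fraction of reads given 7 bases at Q2.
#' @param noise_fraction fraction of additional random-sequence reads.
#' @param background optional genotype-stable small-RNA background from
#'   [simulate_srna_background()] (`data.frame` with `seq`, `abundance`);
#'   without a stable background a uniform miRNA reduction is invisible to
#'   depth normalization, since sequencing is compositional.
#' @param bio_dispersion replicate-level Gamma weight noise (squared CV).
#' @param exhaustive emit exact planted counts instead of sampling.
#' @return a `data.frame` with `read_id`, `mirna_id` (NA for
#'   background/noise reads), `seq`, `qual`; planted miRNA counts in
#'   `attr(, "truth_counts")`.
#' @export
generate_small_rna_reads <- function(pool, libspec, genome,
                                     adapter = "TGGAATTCTCGGGTGCCAAGG",
                                     low_quality_fraction = 0,
                                     noise_fraction = 0,
                                     background = NULL,
                                     bio_dispersion = 0,
                                     exhaustive = FALSE) {
  assert_that(libspec$assay == "sRNAseq", "assay must be sRNAseq")
  assert_that(is.character(adapter) && nzchar(adapter),
              "adapter must be a non-empty sequence")
  mat <- pool[pool$kind == "mature_miRNA", ]
  assert_that(nrow(mat) > 0L, "pool has no mature miRNA species")
  gr <- GenomicRanges::GRanges(
    seqnames = mat$chrom,
    ranges = IRanges::IRanges(
      start = vapply(mat$blocks, function(b) as.integer(b[1, 1]), 0L),
      end = vapply(mat$blocks, function(b) as.integer(b[1, 2]), 0L)),
    strand = mat$strand, seqinfo = genome$seqinfo)
  inserts <- as.character(feature_seq(genome, gr))
  species_seq <- c(inserts, background$seq)
  species_id <- c(mat$feature_id, rep(NA_character_,
                                      length(background$seq)))
  species_ab <- c(mat$abundance, background$abundance)

  with_seed(derive_seed(libspec$seed, libspec$library_id), {
    counts <- if (exhaustive) as.integer(round(species_ab))
              else if (sum(species_ab) > 0) {
                wts <- species_ab
                if (bio_dispersion > 0)
                  wts <- wts * rgamma(length(wts),
                                      shape = 1 / bio_dispersion,
                                      rate = 1 / bio_dispersion)
                as.integer(rmultinom(1L, libspec$depth, wts))
              } else stop("pool has zero total small-RNA abundance",
                          call. = FALSE)
    rl <- libspec$read_length
    seqs <- rep(species_seq, counts)
    ids  <- rep(species_id, counts)
    n_noise <- floor(noise_fraction * sum(counts))
    if (n_noise > 0L) {
      noise <- vapply(seq_len(n_noise), function(i)
        paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE),
              collapse = ""), "")
      seqs <- c(seqs, noise); ids <- c(ids, rep(NA_character_, n_noise))
    }
    full <- paste0(seqs, adapter)
    full <- ifelse(nchar(full) >= rl, substr(full, 1L, rl),
                   paste0(full, strrep("A", rl)))
    full <- substr(full, 1L, rl)
    qual <- strrep("I", rl)  # Q40
    quals <- rep(qual, length(full))
    n_low <- floor(low_quality_fraction * length(full))
    if (n_low > 0L) {
      low_idx <- sample.int(length(full), n_low)
      # 7 bases below Q20 (Q2, '#') in positions 2..8
      for (i in low_idx) {
        q <- quals[i]
        substr(q, 2L, 8L) <- strrep("#", 7L)
        quals[i] <- q
      }
    }
    ord <- sample.int(length(full))  # shuffle library order
    out <- data.frame(
      read_id = sprintf("%s_s%08d", libspec$library_id,
                        seq_along(full)),
      mirna_id = ids[ord], seq = full[ord], qual = quals[ord],
      stringsAsFactors = FALSE)
    attr(out, "truth_counts") <- setNames(counts[seq_len(nrow(mat))],
                                          mat$feature_id)
    out
  })
}

#' Genotype-stable small-RNA background
#'
#' Simulates the non-miRNA small-RNA complement of a plant library
#' (heterochromatic siRNAs, tRNA fragments, degradation products): random
#' 21-24 nt sequences with Gamma abundances, identical in both genotypes.
#' Plant small-RNA libraries are dominated by this class; it is what makes
#' a genome-wide miRNA reduction measurable after depth normalization.
#'
#' @param genome a `GenomeModel` (only for id scoping; sequences are
#'   random).
#' @param n number of background species.
#' @param total_abundance summed abundance on the pool scale (mature miRNA
#'   mean abundance is 1 per locus).
#' @param seed RNG seed.
#' @return `data.frame` with `seq`, `abundance`.
#' @export
simulate_srna_background <- function(genome, n = 300L,
                                     total_abundance = 345,
                                     seed = 1L) {
  with_seed(derive_seed(seed, "srna_background"), {
    len <- runif_int(n, 21L, 24L)
    seqs <- vapply(len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
    ab <- rgamma(n, shape = 0.6, rate = 0.6)
    data.frame(seq = seqs, abundance = ab * total_abundance / sum(ab),
               stringsAsFactors = FALSE)
  })
}
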