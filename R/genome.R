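#' Synthetic genome and annotation model
#'
#' A `GenomeModel` is the coordinate frame for the whole pipeline: chromosome
#' lengths, multi-exon gene models (introns derived as the gaps between
#' consecutive exons), miRNA loci (pri/pre/mature/star intervals) and rRNA
#' loci, plus the genome sequence itself. All internal coordinates are
#' 1-based closed intervals on the forward strand, the R/Bioconductor
#' convention; BED and bedGraph adapters convert at the file boundary.
#'
#' Branch points are placed uniformly within the final 10--50 bp of each
#' intron (canonical plant branch-point positioning); the genome sequence is
#' patched so each intron starts with GU (GT in DNA) and carries an A at its
#' branch point, on the annotated strand.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (recycled).
#' @param n_genes total number of protein-coding gene models.
#' @param exons_per_gene scalar or length-2 range for exon count per gene.
#' @param exon_length,intron_length length-2 ranges (bp).
#' @param n_mirna number of miRNA loci.
#' @param n_rrna number of rRNA loci.
#' @param mirna_pri_length,rrna_length locus lengths (bp).
#' @param intergenic_min minimum gap between placed features (bp).
#' @param seed RNG seed; the model is a pure function of the configuration
#'   and this seed.
#' @return an object of class `GenomeModel`.
#' @export
build_genome <- function(n_chrom = 2L, chrom_length = 1e5, n_genes = 20L,
                         exons_per_gene = c(2L, 5L),
                         exon_length = c(100L, 200L),
                         intron_length = c(200L, 400L),
                         n_mirna = 5L, n_rrna = 2L,
                         mirna_pri_length = 500L, rrna_length = 2000L,
                         intergenic_min = 100L, seed = 1L) {
  assert_that(n_chrom >= 1L, "need at least one chromosome")
  assert_that(n_genes >= 1L, "need at least one gene")
  chrom_length <- rep_len(as.integer(chrom_length), n_chrom)
  chroms <- paste0("chr", seq_len(n_chrom))

  with_seed(seed, {
    rng <- function(n, r) if (length(r) == 1L) rep(as.integer(r), n)
                          else runif_int(n, r[1], r[2])
    n_ex  <- rng(n_genes, exons_per_gene)
    exlen <- lapply(n_ex, function(k) rng(k, exon_length))
    inlen <- lapply(n_ex, function(k) if (k > 1) rng(k - 1L, intron_length)
                                      else integer(0))
    gene_len <- vapply(seq_len(n_genes),
                       function(i) sum(exlen[[i]]) + sum(inlen[[i]]), 0)

    # Units to place: genes, then miRNA loci, then rRNA loci, assigned
    # round-robin across chromosomes and laid out left to right with
    # random gaps (deterministic under the seed).
    unit_len  <- c(gene_len, rep(mirna_pri_length, n_mirna),
                   rep(rrna_length, n_rrna))
    unit_kind <- rep(c("gene", "mirna", "rrna"), c(n_genes, n_mirna, n_rrna))
    n_units <- length(unit_len)
    unit_chrom <- rep_len(seq_len(n_chrom), n_units)

    unit_start <- integer(n_units)
    for (ci in seq_len(n_chrom)) {
      idx <- which(unit_chrom == ci)
      need <- sum(unit_len[idx]) + (length(idx) + 1L) * intergenic_min
      if (need > chrom_length[ci])
        stop(sprintf(paste0("configuration requests %d feature bp on %s ",
                            "but only %d bp are available"),
                     need, chroms[ci], chrom_length[ci]), call. = FALSE)
      slack <- chrom_length[ci] - need
      # split the slack into length(idx)+1 random gaps
      cuts <- sort(runif_int(length(idx), 0, slack))
      gaps <- diff(c(0L, cuts)) + intergenic_min
      pos <- cumsum(gaps + c(0L, unit_len[idx][-length(idx)]))
      unit_start[idx] <- pos + 1L
    }

    strand_pool <- ifelse(runif(n_units) < 0.5, "+", "-")

    ## gene models
    g_idx <- which(unit_kind == "gene")
    gene_id <- sprintf("AT%dG%05d", unit_chrom[g_idx], seq_len(n_genes) * 10L)
    ex_rows <- list(); in_rows <- list()
    for (i in seq_len(n_genes)) {
      u <- g_idx[i]
      lens <- exlen[[i]]; ilens <- inlen[[i]]
      k <- length(lens)
      starts <- integer(k); ends <- integer(k)
      pos <- unit_start[u]
      for (j in seq_len(k)) {
        starts[j] <- pos; ends[j] <- pos + lens[j] - 1L
        pos <- ends[j] + 1L + if (j < k) ilens[j] else 0L
      }
      ex_rows[[i]] <- data.frame(
        gene_id = gene_id[i], chrom = chroms[unit_chrom[u]],
        strand = strand_pool[u], start = starts, end = ends,
        exon_rank = if (strand_pool[u] == "+") seq_len(k) else rev(seq_len(k)),
        stringsAsFactors = FALSE)
      if (k > 1L) {
        istarts <- ends[-k] + 1L
        iends   <- starts[-1L] - 1L
        ni <- k - 1L
        rank <- if (strand_pool[u] == "+") seq_len(ni) else rev(seq_len(ni))
        # branch point: 10-50 bp upstream of the intron 3' end
        d <- pmin(runif_int(ni, 10L, 50L), iends - istarts)
        branch <- if (strand_pool[u] == "+") iends - d else istarts + d
        in_rows[[i]] <- data.frame(
          gene_id = gene_id[i], chrom = chroms[unit_chrom[u]],
          strand = strand_pool[u], start = istarts, end = iends,
          intron_rank = rank,
          intron_id = paste0(gene_id[i], "I", rank),
          branch_pos = as.integer(branch), stringsAsFactors = FALSE)
      }
    }
    exons <- do.call(rbind, ex_rows)
    introns <- if (length(in_rows)) do.call(rbind, in_rows) else
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 intron_rank = integer(), intron_id = character(),
                 branch_pos = integer(), stringsAsFactors = FALSE)

    genes <- data.frame(
      gene_id = gene_id, chrom = chroms[unit_chrom[g_idx]],
      strand = strand_pool[g_idx], start = unit_start[g_idx],
      end = unit_start[g_idx] + gene_len - 1L, n_exons = n_ex,
      stringsAsFactors = FALSE)

    ## miRNA loci: mature near the 5' arm of the hairpin, star on the 3' arm
    m_idx <- which(unit_kind == "mirna")
    mirna <- NULL
    if (n_mirna > 0L) {
      pri_s <- unit_start[m_idx]; pri_e <- pri_s + mirna_pri_length - 1L
      pre_len <- runif_int(n_mirna, 100L, 160L)
      pre_off <- runif_int(n_mirna, 50L, mirna_pri_length - 160L - 50L)
      pre_s <- pri_s + pre_off; pre_e <- pre_s + pre_len - 1L
      mat_len <- runif_int(n_mirna, 20L, 24L)
      mat_s <- pre_s + 10L; mat_e <- mat_s + mat_len - 1L
      star_e <- pre_e - 10L; star_s <- star_e - mat_len + 1L
      str <- strand_pool[m_idx]
      # on the minus strand the 5' arm is the right-hand side
      flip <- str == "-"
      tmp_s <- mat_s; tmp_e <- mat_e
      mat_s[flip] <- star_s[flip]; mat_e[flip] <- star_e[flip]
      star_s[flip] <- tmp_s[flip]; star_e[flip] <- tmp_e[flip]
      mirna <- data.frame(
        mirna_id = sprintf("miR-S%03d", seq_len(n_mirna)),
        chrom = chroms[unit_chrom[m_idx]], strand = str,
        pri_start = pri_s, pri_end = pri_e,
        pre_start = pre_s, pre_end = pre_e,
        mature_start = mat_s, mature_end = mat_e,
        star_start = star_s, star_end = star_e,
        stringsAsFactors = FALSE)
    } else {
      mirna <- data.frame(mirna_id = character(), chrom = character(),
                          strand = character(), pri_start = integer(),
                          pri_end = integer(), pre_start = integer(),
                          pre_end = integer(), mature_start = integer(),
                          mature_end = integer(), star_start = integer(),
                          star_end = integer(), stringsAsFactors = FALSE)
    }

    r_idx <- which(unit_kind == "rrna")
    rrna <- data.frame(
      rrna_id = if (n_rrna > 0L) sprintf("rRNA%d", seq_len(n_rrna)) else character(),
      chrom = chroms[unit_chrom[r_idx]], strand = strand_pool[r_idx],
      start = unit_start[r_idx], end = unit_start[r_idx] + rrna_length - 1L,
      stringsAsFactors = FALSE)

    ## genome sequence with GT donor and branch-point A bookkeeping
    seqs <- vapply(chrom_length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.32, 0.18, 0.18, 0.32)), collapse = ""), "")
    names(seqs) <- chroms
    seqs <- Biostrings::DNAStringSet(seqs)
    if (nrow(introns)) {
      for (ci in chroms) {
        ii <- introns[introns$chrom == ci, ]
        if (!nrow(ii)) next
        s <- as.character(seqs[[ci]])
        plus <- ii$strand == "+"
        for (r in which(plus)) {
          substr(s, ii$start[r], ii$start[r] + 1L) <- "GT"
          substr(s, ii$branch_pos[r], ii$branch_pos[r]) <- "A"
        }
        for (r in which(!plus)) {
          substr(s, ii$end[r] - 1L, ii$end[r]) <- "AC"
          substr(s, ii$branch_pos[r], ii$branch_pos[r]) <- "T"
        }
        seqs[[ci]] <- Biostrings::DNAString(s)
      }
    }

    model <- structure(list(
      seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms,
                                      seqlengths = chrom_length),
      seq = seqs, genes = genes, exons = exons, introns = introns,
      mirna = mirna, rrna = rrna), class = "GenomeModel")
    validate_genome(model)
    model
  })
}

#' Validate a GenomeModel
#'
#' Checks the structural invariants: features inside chromosome bounds,
#' non-overlapping ordered exons per gene, introns exactly the inter-exon
#' gaps, branch points inside their intron.
#'
#' @param model a `GenomeModel`.
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_genome <- function(model) {
  sl <- GenomeInfoDb::seqlengths(model$seqinfo)
  chk_bounds <- function(df, what) {
    if (!nrow(df)) return()
    bad <- df$start < 1L | df$end > sl[df$chrom] | df$start > df$end
    assert_that(!any(bad), sprintf("%s outside chromosome bounds", what))
  }
  chk_bounds(model$exons, "exon")
  chk_bounds(model$introns, "intron")
  chk_bounds(model$rrna, "rRNA locus")
  for (g in split(model$exons, model$exons$gene_id)) {
    o <- order(g$start)
    assert_that(all(g$start[o][-1L] > g$end[o][-nrow(g)]),
                sprintf("overlapping exons in gene %s", g$gene_id[1]))
  }
  if (nrow(model$introns)) {
    derived <- derive_introns(model$exons)
    key <- function(d) paste(d$gene_id, d$start, d$end)
    assert_that(setequal(key(derived), key(model$introns)),
                "introns are not the gaps between consecutive exons")
    with_br <- model$introns
    assert_that(all(with_br$branch_pos >= with_br$start &
                    with_br$branch_pos <= with_br$end),
                "branch point outside its intron")
  }
  if (nrow(model$mirna)) {
    m <- model$mirna
    assert_that(all(m$pre_start >= m$pri_start & m$pre_end <= m$pri_end &
                    m$mature_start >= m$pre_start & m$mature_end <= m$pre_end),
                "miRNA intervals are not nested mature < pre < pri")
    len <- m$mature_end - m$mature_start + 1L
    assert_that(all(len >= 20L & len <= 24L), "mature miRNA length not 20-24 nt")
  }
  invisible(model)
}

# Derive introns as the gaps between consecutive exons of each gene.
derive_introns <- function(exons) {
  out <- lapply(split(exons, exons$gene_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    g <- g[order(g$start), ]
    ni <- nrow(g) - 1L
    rank <- if (g$strand[1] == "+") seq_len(ni) else rev(seq_len(ni))
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1],
               start = g$end[-nrow(g)] + 1L, end = g$start[-1L] - 1L,
               intron_rank = rank,
               intron_id = paste0(g$gene_id[1], "I", rank),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), intron_rank = integer(),
                      intron_id = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature intervals as GRanges
#'
#' Accessors turning parts of a `GenomeModel` into `GRanges` on the model's
#' seqinfo: annotated introns (with `intron_id`, `branch_pos`), gene spans,
#' pre-miRNA hairpins and mature miRNA intervals.
#'
#' @param model a `GenomeModel`.
#' @return a `GRanges` with feature ids in its metadata columns.
#' @export
intron_ranges <- function(model) {
  df_to_granges(model$introns, model,
                keep = c("gene_id", "intron_id", "intron_rank", "branch_pos"))
}

#' @rdname intron_ranges
#' @export
gene_ranges <- function(model) {
  df_to_granges(model$genes, model, keep = c("gene_id", "n_exons"))
}

#' @rdname intron_ranges
#' @export
premirna_ranges <- function(model) {
  m <- model$mirna
  df_to_granges(data.frame(chrom = m$chrom, strand = m$strand,
                           start = m$pre_start, end = m$pre_end,
                           mirna_id = m$mirna_id, stringsAsFactors = FALSE),
                model, keep = "mirna_id")
}

#' @rdname intron_ranges
#' @export
mature_ranges <- function(model) {
  m <- model$mirna
  df_to_granges(data.frame(chrom = m$chrom, strand = m$strand,
                           start = m$mature_start, end = m$mature_end,
                           mirna_id = m$mirna_id, stringsAsFactors = FALSE),
                model, keep = "mirna_id")
}

df_to_granges <- function(df, model, keep = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, seqinfo = model$seqinfo)
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

#' Extract feature sequences
#'
#' Strand-aware sequence of a set of intervals from the model's genome
#' sequence (reverse-complemented on the minus strand).
#'
#' @param model a `GenomeModel`.
#' @param gr a `GRanges` of features.
#' @return a `DNAStringSet`, one entry per range.
#' @export
feature_seq <- function(model, gr) {
  assert_that(!is.null(model$seq), "model carries no sequence")
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(model$seq[[chrom[i]]],
                                    BiocGenerics::start(gr)[i],
                                    BiocGenerics::end(gr)[i])), ""))
  minus <- as.character(BiocGenerics::strand(gr)) == "-"
  if (any(minus))
    out[minus] <- Biostrings::reverseComplement(out[minus])
  out
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf(
    "GenomeModel: %d chromosome(s), %d gene(s), %d intron(s), %d miRNA locus/loci, %d rRNA locus/loci\n",
    length(GenomeInfoDb::seqnames(x$seqinfo)), nrow(x$genes),
    nrow(x$introns), nrow(x$mirna), nrow(x$rrna)))
  invisible(x)
}
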