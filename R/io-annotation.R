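#' Write a GenomeModel annotation to GFF3
#'
#' Emits gene, exon, intron (with `branch_pos` attribute), rRNA and miRNA
#' features (pri as `miRNA_primary_transcript`, hairpin as `pre_miRNA`,
#' `miRNA` and `miRNA_star` children). GFF3 is 1-based closed, the same as
#' the internal convention, so no coordinate shift happens here. Output is
#' byte-for-byte deterministic for a given model.
#'
#' @param model a `GenomeModel`.
#' @param path output file path (`.gff3`).
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(model, path) {
  rows <- character()
  fmt <- function(chrom, src, type, start, end, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, start, end, strand, attrs)
  g <- model$genes
  for (i in seq_len(nrow(g))) {
    rows <- c(rows, fmt(g$chrom[i], "lariatseq", "gene", g$start[i], g$end[i],
                        g$strand[i], sprintf("ID=%s", g$gene_id[i])))
    ex <- model$exons[model$exons$gene_id == g$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex)))
      rows <- c(rows, fmt(ex$chrom[j], "lariatseq", "exon",
                          ex$start[j], ex$end[j], ex$strand[j],
                          sprintf("Parent=%s;exon_rank=%d",
                                  ex$gene_id[j], ex$exon_rank[j])))
    ii <- model$introns[model$introns$gene_id == g$gene_id[i], ]
    if (nrow(ii)) {
      ii <- ii[order(ii$start), ]
      for (j in seq_len(nrow(ii)))
        rows <- c(rows, fmt(ii$chrom[j], "lariatseq", "intron",
                            ii$start[j], ii$end[j], ii$strand[j],
                            sprintf("ID=%s;Parent=%s;branch_pos=%d",
                                    ii$intron_id[j], ii$gene_id[j],
                                    ii$branch_pos[j])))
    }
  }
  m <- model$mirna
  for (i in seq_len(nrow(m))) {
    rows <- c(rows,
      fmt(m$chrom[i], "lariatseq", "miRNA_primary_transcript",
          m$pri_start[i], m$pri_end[i], m$strand[i],
          sprintf("ID=%s_pri;Name=%s", m$mirna_id[i], m$mirna_id[i])),
      fmt(m$chrom[i], "lariatseq", "pre_miRNA",
          m$pre_start[i], m$pre_end[i], m$strand[i],
          sprintf("ID=%s_pre;Parent=%s_pri", m$mirna_id[i], m$mirna_id[i])),
      fmt(m$chrom[i], "lariatseq", "miRNA",
          m$mature_start[i], m$mature_end[i], m$strand[i],
          sprintf("ID=%s;Parent=%s_pre", m$mirna_id[i], m$mirna_id[i])),
      fmt(m$chrom[i], "lariatseq", "miRNA_star",
          m$star_start[i], m$star_end[i], m$strand[i],
          sprintf("ID=%s_star;Parent=%s_pre", m$mirna_id[i], m$mirna_id[i])))
  }
  r <- model$rrna
  for (i in seq_len(nrow(r)))
    rows <- c(rows, fmt(r$chrom[i], "lariatseq", "rRNA",
                        r$start[i], r$end[i], r$strand[i],
                        sprintf("ID=%s", r$rrna_id[i])))
  sl <- GenomeInfoDb::seqlengths(model$seqinfo)
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", names(sl), sl))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a GFF3 annotation into a GenomeModel
#'
#' Parses gene/exon (and optional intron, miRNA, rRNA) features via
#' [rtracklayer::import.gff3()]. Introns are always re-derived as the gaps
#' between consecutive exons of each gene; if the file also carries intron
#' features with a `branch_pos` attribute (as written by
#' [write_annotation_gff3()]), branch points are attached to the derived
#' introns. Overlapping exons within one gene are an error.
#'
#' @param path GFF3 file.
#' @param seq optional `DNAStringSet` genome sequence to attach.
#' @return a `GenomeModel` (without sequence unless `seq` is given).
#' @export
read_annotation <- function(path, seq = NULL) {
  assert_that(file.exists(path), sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  first_chr <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v[[1]]) else NA_character_, "")
  parent <- if (!is.null(mc$Parent)) first_chr(mc$Parent) else
    rep(NA_character_, length(gr))
  id <- if (!is.null(mc$ID)) as.character(mc$ID) else
    rep(NA_character_, length(gr))

  as_df <- function(sel) data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr))[sel],
    strand = as.character(BiocGenerics::strand(gr))[sel],
    start = BiocGenerics::start(gr)[sel], end = BiocGenerics::end(gr)[sel],
    stringsAsFactors = FALSE)

  gsel <- typ == "gene"
  genes <- as_df(gsel)
  genes$gene_id <- id[gsel]
  esel <- typ == "exon"
  exons <- as_df(esel)
  exons$gene_id <- parent[esel]
  assert_that(!anyNA(exons$gene_id), "exon feature without Parent gene")
  exons <- exons[order(exons$gene_id, exons$start), ]
  rownames(exons) <- NULL
  for (gg in split(exons, exons$gene_id))
    assert_that(all(gg$start[-1L] > gg$end[-nrow(gg)]) || nrow(gg) == 1L,
                sprintf("overlapping exons within gene %s", gg$gene_id[1]))
  exons$exon_rank <- unlist(lapply(split(exons, exons$gene_id), function(gg)
    if (gg$strand[1] == "+") seq_len(nrow(gg)) else rev(seq_len(nrow(gg)))),
    use.names = FALSE)

  introns <- derive_introns(exons)
  introns$branch_pos <- NA_integer_
  isel <- typ == "intron"
  if (any(isel) && !is.null(mc$branch_pos)) {
    bp <- as.integer(mc$branch_pos[isel])
    key <- paste(as.character(GenomeInfoDb::seqnames(gr))[isel],
                 BiocGenerics::start(gr)[isel], BiocGenerics::end(gr)[isel])
    mkey <- paste(introns$chrom, introns$start, introns$end)
    introns$branch_pos <- bp[match(mkey, key)]
  }

  genes2 <- do.call(rbind, lapply(split(exons, exons$gene_id), function(gg)
    data.frame(gene_id = gg$gene_id[1], chrom = gg$chrom[1],
               strand = gg$strand[1], start = min(gg$start),
               end = max(gg$end), n_exons = nrow(gg),
               stringsAsFactors = FALSE)))
  rownames(genes2) <- NULL

  mir_pri <- typ == "miRNA_primary_transcript"
  mirna <- data.frame(mirna_id = character(), chrom = character(),
                      strand = character(), pri_start = integer(),
                      pri_end = integer(), pre_start = integer(),
                      pre_end = integer(), mature_start = integer(),
                      mature_end = integer(), star_start = integer(),
                      star_end = integer(), stringsAsFactors = FALSE)
  if (any(mir_pri)) {
    pri <- as_df(mir_pri); pri$pid <- id[mir_pri]
    pre <- as_df(typ == "pre_miRNA"); pre$parent <- parent[typ == "pre_miRNA"]
    mat <- as_df(typ == "miRNA"); mat$mid <- id[typ == "miRNA"]
    mat$parent <- parent[typ == "miRNA"]
    star <- as_df(typ == "miRNA_star"); star$parent <- parent[typ == "miRNA_star"]
    mid <- sub("_pri$", "", pri$pid)
    pre_i <- match(paste0(mid, "_pri"), pre$parent)
    mat_i <- match(paste0(mid, "_pre"), mat$parent)
    star_i <- match(paste0(mid, "_pre"), star$parent)
    mirna <- data.frame(
      mirna_id = mid, chrom = pri$chrom, strand = pri$strand,
      pri_start = pri$start, pri_end = pri$end,
      pre_start = pre$start[pre_i], pre_end = pre$end[pre_i],
      mature_start = mat$start[mat_i], mature_end = mat$end[mat_i],
      star_start = star$start[star_i], star_end = star$end[star_i],
      stringsAsFactors = FALSE)
  }

  rsel <- typ == "rRNA"
  rrna <- as_df(rsel)
  rrna$rrna_id <- if (any(rsel)) id[rsel] else character()
  rrna <- rrna[, c("rrna_id", "chrom", "strand", "start", "end")]

  sl <- GenomeInfoDb::seqlengths(gr)
  if (anyNA(sl)) {
    mx <- tapply(c(genes2$end, mirna$pri_end, rrna$end),
                 c(genes2$chrom, mirna$chrom, rrna$chrom), max)
    sl[is.na(sl)] <- mx[names(sl)[is.na(sl)]] + 1000L
  }
  model <- structure(list(
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(sl),
                                    seqlengths = as.integer(sl)),
    seq = seq,
    genes = genes2[match(genes$gene_id, genes2$gene_id), ],
    exons = exons[, c("gene_id", "chrom", "strand", "start", "end",
                      "exon_rank")],
    introns = introns[, c("gene_id", "chrom", "strand", "start", "end",
                          "intron_rank", "intron_id", "branch_pos")],
    mirna = mirna, rrna = rrna), class = "GenomeModel")
  rownames(model$genes) <- NULL
  model
}

#' Write / read the genome sequence as FASTA
#'
#' @param model a `GenomeModel` with sequence.
#' @param path FASTA path.
#' @return `path` invisibly (writer); a `DNAStringSet` (reader).
#' @export
write_genome_fasta <- function(model, path) {
  assert_that(!is.null(model$seq), "model carries no sequence")
  Biostrings::writeXStringSet(model$seq, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
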