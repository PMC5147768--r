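#' Per-base genome coverage for one library
#'
#' Every alignment segment increments the depth of every base it covers on
#' its strand (the `bedtools genomecov` convention). The track is the basis
#' of all RPKM/TP10M quantities downstream.
#'
#' @param aln an alignment `GRanges` (see [alignment_set()]).
#' @param genome a `GenomeModel` (declares chromosomes and bounds).
#' @param stranded keep the two strands separate (default); unstranded
#'   tracks pool them under `"*"`.
#' @return a `CoverageTrack`: per-strand `RleList` of depths plus
#'   `total_tags` (number of distinct reads) and `read_length`.
#' @export
compute_coverage <- function(aln, genome, stranded = TRUE) {
  sl <- GenomeInfoDb::seqlengths(genome$seqinfo)
  chroms <- as.character(GenomeInfoDb::seqnames(aln))
  unknown <- setdiff(unique(chroms), names(sl))
  assert_that(length(unknown) == 0L,
              sprintf("record on unknown chromosome: %s",
                      paste(unknown, collapse = ", ")))
  assert_that(all(BiocGenerics::start(aln) >= 1L) &&
              all(BiocGenerics::end(aln) <= sl[chroms]),
              "alignment segment outside chromosome bounds")
  gr <- aln
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  cov <- if (stranded) {
    list("+" = GenomicRanges::coverage(gr[BiocGenerics::strand(gr) == "+"]),
         "-" = GenomicRanges::coverage(gr[BiocGenerics::strand(gr) == "-"]))
  } else {
    list("*" = GenomicRanges::coverage(gr))
  }
  structure(list(cov = cov, total_tags = n_tags(aln),
                 read_length = aln_read_length(aln),
                 library_id = aln_library_id(aln), stranded = stranded),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %s, %d tags, read length %d\n",
              x$library_id, if (x$stranded) "stranded" else "unstranded",
              x$total_tags, x$read_length))
  invisible(x)
}

# Sum of per-base coverage over each region, strand-aware.
region_coverage_sum <- function(track, regions) {
  assert_that(inherits(track, "CoverageTrack"), "need a CoverageTrack")
  n <- length(regions)
  out <- numeric(n)
  str <- as.character(BiocGenerics::strand(regions))
  if (!track$stranded) str[] <- "*"
  str[str == "*" & track$stranded] <- NA  # ambiguous region on stranded track
  assert_that(!anyNA(str),
              "unstranded region queried against a stranded track")
  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  for (s in unique(str)) {
    rl <- track$cov[[s]]
    sel <- which(str == s)
    for (ch in unique(chroms[sel])) {
      i <- sel[chroms[sel] == ch]
      v <- IRanges::Views(rl[[ch]],
                          start = BiocGenerics::start(regions)[i],
                          end = BiocGenerics::end(regions)[i])
      out[i] <- IRanges::viewSums(v)
    }
  }
  out
}

#' Read equivalents of a region from coverage
#'
#' Bridges per-base coverage back to read counts: the summed depth over the
#' region divided by the read length. For reads fully contained in the
#' region this equals the read count exactly; reads straddling a boundary
#' contribute fractionally.
#'
#' @param track a `CoverageTrack`.
#' @param regions a `GRanges` of regions (strand-matched on stranded
#'   tracks).
#' @return numeric vector of read equivalents, one per region.
#' @export
region_read_equivalents <- function(track, regions) {
  assert_that(length(regions) > 0L &&
              all(BiocGenerics::width(regions) > 0L), "empty region")
  region_coverage_sum(track, regions) / track$read_length
}

#' RPKM: reads per kilobase of feature per million sequencing tags
#'
#' @param read_equivalents read (equivalent) counts per feature.
#' @param region_length_bp feature lengths in bp.
#' @param total_tags library size in reads.
#' @return numeric RPKM values (attribute `unit` = `"RPKM"`).
#' @export
rpkm <- function(read_equivalents, region_length_bp, total_tags) {
  assert_that(all(region_length_bp > 0), "region length must be > 0")
  assert_that(total_tags > 0, "total_tags must be > 0")
  structure(read_equivalents * 1e9 / (region_length_bp * total_tags),
            unit = "RPKM")
}

#' RPTM: reads per ten million sequencing tags
#'
#' The small-RNA normalization: raw counts scaled to a ten-million-tag
#' library.
#'
#' @param count raw counts.
#' @param total_tags library size in reads.
#' @return numeric RPTM values (attribute `unit` = `"RPTM"`).
#' @export
rptm <- function(count, total_tags) {
  assert_that(total_tags > 0, "total_tags must be > 0")
  structure(count * 1e7 / total_tags, unit = "RPTM")
}

#' TP10M-normalize a coverage track
#'
#' Scales every per-base depth by `1e7 / total_tags` so tracks of different
#' sequencing depth are directly comparable.
#'
#' @param track a `CoverageTrack`.
#' @return the track with normalized (numeric) coverage and attribute
#'   `unit` = `"TP10M"`.
#' @export
tp10m <- function(track) {
  assert_that(track$total_tags > 0, "total_tags must be > 0")
  f <- 1e7 / track$total_tags
  track$cov <- lapply(track$cov, function(rl) rl * f)
  track$unit <- "TP10M"
  track
}

#' Restrict alignments to reads contained in single features
#'
#' The "uniquely mapped intronic reads" rule: a read contributes to a
#' feature only if *every* one of its segments lies entirely within that
#' one feature, on the matching strand. `mode = "overlap"` relaxes this to
#' any-segment overlap.
#'
#' @param aln an alignment `GRanges`.
#' @param features a `GRanges` of features (e.g. introns).
#' @param mode `"within"` (strict containment, default) or `"overlap"`.
#' @param stranded require matching strand.
#' @param id_col metadata column of `features` holding feature ids
#'   (default: the first one).
#' @return a list: `aln` (the filtered alignment set) and `assignment`
#'   (`data.frame` of `read_id`, feature index and id).
#' @export
filter_reads_in_features <- function(aln, features,
                                     mode = c("within", "overlap"),
                                     stranded = TRUE, id_col = NULL) {
  mode <- match.arg(mode)
  fid_col <- id_col %||% names(S4Vectors::mcols(features))[1]
  fid <- if (!is.null(fid_col))
    as.character(S4Vectors::mcols(features)[[fid_col]])
    else as.character(seq_along(features))
  ov <- GenomicRanges::findOverlaps(
    aln, features, type = if (mode == "within") "within" else "any",
    ignore.strand = !stranded)
  rid <- S4Vectors::mcols(aln)$read_id
  seg_per_read <- table(rid)
  # several ranges may share one feature id (e.g. the exons of one gene):
  # a segment counts once per feature id it lands in
  hit <- unique(data.frame(
    seg = S4Vectors::queryHits(ov),
    read_id = rid[S4Vectors::queryHits(ov)],
    feature_id = fid[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  seg_in <- table(paste(hit$read_id, hit$feature_id, sep = "\r"))
  hit_df <- unique(hit[c("read_id", "feature_id")])
  key <- paste(hit_df$read_id, hit_df$feature_id, sep = "\r")
  hit_df$n_seg_in <- as.integer(seg_in[key])
  hit_df$n_seg <- as.integer(seg_per_read[hit_df$read_id])
  ok <- hit_df[hit_df$n_seg_in == hit_df$n_seg, , drop = FALSE]
  # a read assigned to more than one feature is not uniquely placed
  dup <- ok$read_id[duplicated(ok$read_id)]
  ok <- ok[!ok$read_id %in% dup, , drop = FALSE]
  keep <- rid %in% ok$read_id
  sub <- aln[keep]
  S4Vectors::metadata(sub) <- S4Vectors::metadata(aln)
  list(aln = sub,
       assignment = data.frame(
         read_id = ok$read_id,
         feature_id = ok$feature_id,
         stringsAsFactors = FALSE))
}

#' Export a coverage track as bedGraph
#'
#' Writes one bedGraph per strand (suffixes `.plus`/`.minus` on stranded
#' tracks), 0-based half-open as the format requires.
#'
#' @param track a `CoverageTrack`.
#' @param path base output path.
#' @return character vector of files written, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  files <- character(0)
  for (s in names(track$cov)) {
    suffix <- switch(s, "+" = ".plus.bedgraph", "-" = ".minus.bedgraph",
                     ".bedgraph")
    f <- paste0(sub("\\.bedgraph$", "", path), suffix)
    lines <- character(0)
    rl <- track$cov[[s]]
    for (ch in names(rl)) {
      r <- rl[[ch]]
      v <- S4Vectors::runValue(r); w <- S4Vectors::runLength(r)
      ends <- cumsum(w); starts <- ends - w  # already 0-based half-open
      nz <- v != 0
      if (any(nz))
        lines <- c(lines, sprintf("%s\t%d\t%d\t%g", ch, starts[nz],
                                  ends[nz], v[nz]))
    }
    writeLines(lines, f)
    files <- c(files, f)
  }
  invisible(files)
}
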