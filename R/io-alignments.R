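#' Alignment records
#'
#' Aligned reads are represented as a `GRanges` of *segments*: each row is
#' one genomic interval of one read, and split reads (spliced reads, or
#' lariat branch-junction reads) own several rows sharing a `read_id`
#' metadata column. Coordinates are 1-based closed internally; the BED12
#' adapter converts to/from 0-based half-open at the file boundary. The
#' `GRanges` metadata list carries `library_id` and `read_length`.
#'
#' @param segments a `GRanges` with a `read_id` metadata column.
#' @param library_id library identifier.
#' @param read_length read length in bp.
#' @return a `GRanges` alignment set.
#' @export
alignment_set <- function(segments, library_id = "lib", read_length = 50L) {
  assert_that(!is.null(S4Vectors::mcols(segments)$read_id),
              "segments need a read_id metadata column")
  S4Vectors::metadata(segments)$library_id <- library_id
  S4Vectors::metadata(segments)$read_length <- as.integer(read_length)
  segments
}

aln_read_length <- function(aln) {
  S4Vectors::metadata(aln)$read_length %||%
    stop("alignment set carries no read_length", call. = FALSE)
}

aln_library_id <- function(aln) S4Vectors::metadata(aln)$library_id %||% "lib"

#' Number of aligned reads (sequencing tags) in an alignment set
#'
#' A junction read with several segments counts once.
#'
#' @param aln an alignment `GRanges`.
#' @return integer count of distinct reads.
#' @export
n_tags <- function(aln) length(unique(S4Vectors::mcols(aln)$read_id))

#' Write alignments as BED12
#'
#' One line per read; the read's segments become blocks (sorted by genomic
#' start, as BED12 requires). Converts to 0-based half-open.
#'
#' @param aln an alignment `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(aln, path) {
  if (length(aln) == 0L) { writeLines(character(), path); return(invisible(path)) }
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(aln)),
                   start = BiocGenerics::start(aln),
                   end = BiocGenerics::end(aln),
                   strand = as.character(BiocGenerics::strand(aln)),
                   read_id = S4Vectors::mcols(aln)$read_id,
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$read_id, unique(df$read_id)), df$start), ]
  sp <- split(df, factor(df$read_id, levels = unique(df$read_id)))
  lines <- vapply(sp, function(r) {
    cs <- min(r$start) - 1L; ce <- max(r$end)
    sizes <- r$end - r$start + 1L
    offs <- r$start - 1L - cs
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            r$chrom[1], cs, ce, r$read_id[1], r$strand[1], cs, ce,
            nrow(r), paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(offs, collapse = ","), ","))
  }, "", USE.NAMES = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Split reads are encoded with `N` gaps in the CIGAR; minus-strand reads get
#' FLAG 16. Sequence and quality are written as `*`.
#'
#' @param aln an alignment `GRanges`.
#' @param path output path.
#' @param genome a `GenomeModel` supplying `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, genome) {
  sl <- GenomeInfoDb::seqlengths(genome$seqinfo)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  lines <- character(0)
  if (length(aln)) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(aln)),
                     start = BiocGenerics::start(aln),
                     end = BiocGenerics::end(aln),
                     strand = as.character(BiocGenerics::strand(aln)),
                     read_id = S4Vectors::mcols(aln)$read_id,
                     stringsAsFactors = FALSE)
    df <- df[order(match(df$read_id, unique(df$read_id)), df$start), ]
    sp <- split(df, factor(df$read_id, levels = unique(df$read_id)))
    lines <- vapply(sp, function(r) {
      cig <- character(0)
      for (j in seq_len(nrow(r))) {
        if (j > 1L) cig <- c(cig, sprintf("%dN", r$start[j] - r$end[j - 1L] - 1L))
        cig <- c(cig, sprintf("%dM", r$end[j] - r$start[j] + 1L))
      }
      sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
              r$read_id[1], if (r$strand[1] == "-") 16L else 0L,
              r$chrom[1], min(r$start), paste(cig, collapse = ""))
    }, "", USE.NAMES = FALSE)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read alignments from BED12 or SAM
#'
#' Coordinates are normalized to the internal 1-based closed convention
#' regardless of dialect; split records (BED blocks, CIGAR `N` gaps) become
#' multi-segment reads. Malformed lines raise an error naming the line
#' number; a record outside the declared chromosome bounds is an error when
#' `genome` is supplied.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"bed12"` or `"sam"`.
#' @param genome optional `GenomeModel` for bounds checking and seqinfo.
#' @param library_id,read_length metadata attached to the result.
#' @return an alignment `GRanges` (see [alignment_set()]).
#' @export
read_alignments <- function(path, dialect = c("auto", "bed12", "sam"),
                            genome = NULL, library_id = NULL,
                            read_length = 50L) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), sprintf("alignment file not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "sam") "sam" else "bed12"
  }
  library_id <- library_id %||% sub("\\.[^.]*$", "", basename(path))
  parsed <- if (dialect == "sam") parse_sam(path) else parse_bed12(path)
  if (!is.null(genome)) {
    sl <- GenomeInfoDb::seqlengths(genome$seqinfo)
    unknown <- setdiff(unique(parsed$chrom), names(sl))
    assert_that(length(unknown) == 0L,
                sprintf("record on unknown chromosome: %s",
                        paste(unknown, collapse = ", ")))
    bad <- parsed$start < 1L | parsed$end > sl[parsed$chrom]
    assert_that(!any(bad), sprintf(
      "coordinate outside declared chromosome for read(s): %s",
      paste(utils::head(unique(parsed$read_id[bad]), 3L), collapse = ", ")))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = if (is.null(genome)) parsed$chrom else
      factor(parsed$chrom,
             levels = GenomeInfoDb::seqnames(genome$seqinfo)),
    ranges = IRanges::IRanges(start = parsed$start, end = parsed$end),
    strand = parsed$strand,
    read_id = parsed$read_id,
    seqinfo = if (is.null(genome)) NULL else genome$seqinfo)
  alignment_set(gr, library_id = library_id, read_length = read_length)
}

parse_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      read_id = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad))
    stop(sprintf("malformed BED12 line %d: expected 12 fields, got %d",
                 bad[1], nf[bad[1]]), call. = FALSE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    cs <- suppressWarnings(as.integer(f[2]))
    nb <- suppressWarnings(as.integer(f[10]))
    if (is.na(cs) || is.na(nb))
      stop(sprintf("malformed BED12 line %d: non-numeric coordinates", i),
           call. = FALSE)
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    offs  <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (length(sizes) != nb || length(offs) != nb || anyNA(sizes) || anyNA(offs))
      stop(sprintf("malformed BED12 line %d: blockCount=%d but %d sizes / %d starts",
                   i, nb, length(sizes), length(offs)), call. = FALSE)
    out[[i]] <- data.frame(
      chrom = f[1], start = cs + offs + 1L, end = cs + offs + sizes,
      strand = f[6], read_id = f[4], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

parse_sam <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  out <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop(sprintf("malformed SAM line %d: fewer than 11 fields", i),
           call. = FALSE)
    flag <- suppressWarnings(as.integer(f[2]))
    pos  <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      stop(sprintf("malformed SAM line %d: non-numeric FLAG/POS", i),
           call. = FALSE)
    if (bitwAnd(flag, 4L) == 4L) next  # unmapped
    segs <- cigar_segments(f[6], pos)
    if (is.null(segs))
      stop(sprintf("malformed SAM line %d: bad CIGAR '%s'", i, f[6]),
           call. = FALSE)
    out[[k]] <- data.frame(
      chrom = f[3], start = segs$start, end = segs$end,
      strand = if (bitwAnd(flag, 16L) == 16L) "-" else "+",
      read_id = f[1], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      read_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Split a CIGAR into reference segments; N opens a new segment, M/=/X/D
# consume reference, I/S/H/P do not. POS is 1-based (SAM), kept as is.
cigar_segments <- function(cigar, pos) {
  if (cigar == "*") return(NULL)
  ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  if (ops[1] == -1L) return(NULL)
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  kinds <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(kinds)) return(NULL)
  starts <- integer(0); ends <- integer(0)
  cur_start <- pos; cur <- pos
  open <- FALSE
  for (j in seq_along(kinds)) {
    k <- kinds[j]; L <- lens[j]
    if (k %in% c("M", "=", "X", "D")) {
      if (!open) { cur_start <- cur; open <- TRUE }
      cur <- cur + L
    } else if (k == "N") {
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L) }
      cur <- cur + L
      open <- FALSE
    }
    # I, S, H, P: no reference consumption
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L) }
  if (!length(starts)) return(NULL)
  list(start = starts, end = ends)
}
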