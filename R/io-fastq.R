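#' Write / read small-RNA reads as FASTQ
#'
#' The working representation of a small-RNA library is a `data.frame` with
#' `read_id`, `seq` and `qual` (Phred+33) columns; these adapters move it
#' through FASTQ via Biostrings.
#'
#' @param reads a `data.frame` with `read_id`, `seq`, `qual`.
#' @param path FASTQ path.
#' @return `path` invisibly (writer); a reads `data.frame` (reader).
#' @export
write_fastq <- function(reads, path) {
  assert_that(all(c("read_id", "seq", "qual") %in% names(reads)),
              "reads need read_id, seq and qual columns")
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  assert_that(file.exists(path), sprintf("FASTQ file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
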