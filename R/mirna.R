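#' Quality-filter small-RNA reads
#'
#' Removes a read iff it has more than `max_below` bases with Phred quality
#' below `min_q` (default: more than 5 bases under Q20).
#'
#' @param reads `data.frame` with `seq` and `qual` (Phred+33).
#' @param min_q quality threshold.
#' @param max_below maximum tolerated bases below `min_q`.
#' @return the filtered `data.frame`; removed count in
#'   `attr(, "n_removed")`.
#' @export
quality_filter <- function(reads, min_q = 20L, max_below = 5L) {
  assert_that(all(nchar(reads$qual) == nchar(reads$seq)),
              "malformed quality string: length differs from sequence")
  n_below <- vapply(reads$qual, function(q) {
    ph <- as.integer(charToRaw(q)) - 33L
    if (any(ph < 0L | ph > 60L))
      stop("malformed quality string: character outside Phred+33 range",
           call. = FALSE)
    sum(ph < min_q)
  }, 0L, USE.NAMES = FALSE)
  keep <- n_below <= max_below
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trim the 3' adapter and extract small-RNA inserts
#'
#' The insert is the sequence before the first occurrence of the adapter's
#' first `k` bases (exact match). Reads without an adapter match, or whose
#' insert length falls outside `[min_len, max_len]`, are dropped.
#'
#' @param reads `data.frame` with `seq` (or a character vector).
#' @param adapter adapter sequence, length >= 8.
#' @param k length of the adapter prefix matched.
#' @param min_len,max_len retained insert length window (nt).
#' @return character vector of inserts; dropped-read accounting in
#'   `attr(, "n_no_adapter")` and `attr(, "n_bad_length")`.
#' @export
trim_adapter <- function(reads, adapter, k = 8L, min_len = 18L,
                         max_len = 30L) {
  assert_that(nchar(adapter) >= 8L, "adapter must be at least 8 nt")
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  key <- substr(adapter, 1L, k)
  pos <- regexpr(key, seqs, fixed = TRUE)
  has <- pos > 0L
  insert <- substr(seqs[has], 1L, pos[has] - 1L)
  len_ok <- nchar(insert) >= min_len & nchar(insert) <= max_len
  out <- insert[len_ok]
  attr(out, "n_no_adapter") <- sum(!has)
  attr(out, "n_bad_length") <- sum(!len_ok)
  out
}

#' Collapse redundant small-RNA sequences
#'
#' Unique sequences with their multiplicities, in lexicographic order.
#'
#' @param sequences character vector of inserts.
#' @return `data.frame` with `seq`, `count`.
#' @export
collapse_unique <- function(sequences) {
  if (!length(sequences))
    return(data.frame(seq = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(sequences)  # levels are sorted, giving lexicographic order
  data.frame(seq = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Assign unique small RNAs to mature miRNAs
#'
#' Exact sequence matching against the mature reference by default. With
#' `precursors` supplied, a non-exact read is also accepted when it is a
#' substring of a hairpin precursor, overlaps the mature sequence within
#' it, and differs from the mature length by at most 2 nt (end
#' trimming/extension). A unique sequence matching several reference
#' entries splits its count equally among them.
#'
#' @param unique_tab `data.frame` from [collapse_unique()].
#' @param mature named character vector (or `DNAStringSet`) of mature
#'   sequences; names are miRNA ids and must be unique.
#' @param precursors optional named character vector of precursor
#'   sequences (same id namespace).
#' @param exact_only disable the near-exact precursor mode.
#' @return `data.frame` with `mirna_id`, `count` (fractional when split);
#'   unassigned read count in `attr(, "n_unassigned")`.
#' @export
assign_mirnas <- function(unique_tab, mature, precursors = NULL,
                          exact_only = TRUE) {
  mature <- setNames(as.character(mature), names(mature))
  assert_that(!anyDuplicated(names(mature)),
              "duplicate ids in mature reference")
  counts <- setNames(numeric(length(mature)), names(mature))
  unassigned <- 0
  for (i in seq_len(nrow(unique_tab))) {
    s <- unique_tab$seq[i]; n <- unique_tab$count[i]
    hits <- names(mature)[mature == s]
    if (!length(hits) && !exact_only && !is.null(precursors)) {
      for (id in names(precursors)) {
        p <- regexpr(s, precursors[[id]], fixed = TRUE)
        if (p < 0L || is.na(mature[id])) next
        m <- regexpr(mature[[id]], precursors[[id]], fixed = TRUE)
        if (m < 0L) next
        s_end <- p + nchar(s) - 1L; m_end <- m + nchar(mature[[id]]) - 1L
        if (p <= m_end && s_end >= m &&
            abs(nchar(s) - nchar(mature[[id]])) <= 2L)
          hits <- c(hits, id)
      }
    }
    if (length(hits)) counts[hits] <- counts[hits] + n / length(hits)
    else unassigned <- unassigned + n
  }
  out <- data.frame(mirna_id = names(counts), count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- unassigned
  out
}

#' Small-RNA processing pipeline for one library
#'
#' Quality filter, adapter trim, collapse, miRNA assignment; total tags for
#' RPTM normalization are the trimmed small-RNA reads (assigned plus
#' unassigned).
#'
#' @param reads FASTQ `data.frame` (see [read_fastq()]).
#' @param mature mature reference (named sequences).
#' @param adapter 3' adapter.
#' @param ... passed to [trim_adapter()] / [assign_mirnas()].
#' @return list with `counts` (per miRNA), `total_tags`, and the
#'   conservation accounting `n_in`, `n_removed_quality`,
#'   `n_dropped_trim`, `n_collapsed`.
#' @export
mirna_count_pipeline <- function(reads, mature,
                                 adapter = "TGGAATTCTCGGGTGCCAAGG", ...) {
  n_in <- nrow(reads)
  q <- quality_filter(reads)
  ins <- trim_adapter(q, adapter, ...)
  uniq <- collapse_unique(ins)
  asg <- assign_mirnas(uniq, mature)
  list(counts = setNames(asg$count, asg$mirna_id),
       total_tags = sum(uniq$count),
       n_in = n_in,
       n_removed_quality = attr(q, "n_removed"),
       n_dropped_trim = attr(ins, "n_no_adapter") + attr(ins, "n_bad_length"),
       n_collapsed = sum(uniq$count),
       n_unassigned = attr(asg, "n_unassigned"))
}

#' Per-replicate miRNA fold-change table
#'
#' RPTM-normalizes per-library counts and, for each replicate pair
#' (wild-type vs mutant), keeps miRNAs reaching `rptm_min` RPTM in either
#' genotype and reports the log2 mutant/wild-type RPTM ratio (defined only
#' when both RPTMs are positive).
#'
#' @param counts named list: `counts[[library_id]]` = named count vector.
#' @param total_tags named vector of library sizes (small-RNA tags).
#' @param manifest `data.frame` with `library_id`, `genotype`, `replicate`.
#' @param config an [analysis_config()] (uses `rptm_min`).
#' @return `data.frame` with one row per miRNA x replicate:
#'   `mirna_id`, `replicate`, `rptm_col0`, `rptm_dbr1`, `log2_ratio`,
#'   `passes_expression_filter`.
#' @export
fold_change_table <- function(counts, total_tags, manifest,
                              config = analysis_config()) {
  assert_that(all(total_tags > 0), "zero total tags in a library")
  reps <- sort(unique(manifest$replicate))
  out <- list()
  for (r in reps) {
    lib_c <- manifest$library_id[manifest$genotype == "Col0" &
                                 manifest$replicate == r]
    lib_d <- manifest$library_id[manifest$genotype == "dbr1_2" &
                                 manifest$replicate == r]
    assert_that(length(lib_c) == 1L && length(lib_d) == 1L,
                sprintf("replicate %s needs one library per genotype", r))
    ids <- union(names(counts[[lib_c]]), names(counts[[lib_d]]))
    cc <- counts[[lib_c]][ids]; cc[is.na(cc)] <- 0
    cd <- counts[[lib_d]][ids]; cd[is.na(cd)] <- 0
    r_c <- as.numeric(rptm(cc, total_tags[[lib_c]]))
    r_d <- as.numeric(rptm(cd, total_tags[[lib_d]]))
    passes <- pmax(r_c, r_d) >= config$rptm_min
    lr <- ifelse(r_c > 0 & r_d > 0, log2(r_d / r_c), NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = ids, replicate = r, rptm_col0 = r_c, rptm_dbr1 = r_d,
      log2_ratio = ifelse(passes, lr, NA_real_),
      passes_expression_filter = passes,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' miRNAs commonly reduced across two replicates
#'
#' Intersects the ids called reduced in each replicate table. The default
#' rule flags `log2_ratio < 0` among miRNAs passing the expression filter;
#' any rule function mapping a table to a logical vector can be supplied,
#' and pre-labelled id vectors are intersected directly.
#'
#' @param table_rep1,table_rep2 per-replicate tables from
#'   [fold_change_table()] (or character id vectors).
#' @param rule function(table) -> logical, marking reduced rows.
#' @return character vector of commonly reduced miRNA ids (sorted).
#' @export
intersect_reduced <- function(table_rep1, table_rep2,
                              rule = function(t)
                                t$passes_expression_filter &
                                !is.na(t$log2_ratio) & t$log2_ratio < 0) {
  pick <- function(t) if (is.character(t)) t else t$mirna_id[rule(t)]
  sort(intersect(pick(table_rep1), pick(table_rep2)))
}
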