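#' Read one sheet of a supplementary table
#'
#' Accepts `.xlsx` (sheet-indexed, requires the readxl package), `.csv` or
#' `.tsv`/`.txt` exports of a spreadsheet sheet.
#'
#' @param path spreadsheet or delimited-text file.
#' @param sheet sheet index or name (xlsx only).
#' @return a `data.frame`.
#' @export
read_table_sheet <- function(path, sheet = 1L) {
  assert_that(file.exists(path), sprintf("table file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    assert_that(requireNamespace("readxl", quietly = TRUE),
                "reading .xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

# Columns of `df` whose names match any of the patterns (case-insensitive).
match_columns <- function(df, patterns) {
  hits <- unique(unlist(lapply(patterns, grep, x = names(df),
                               ignore.case = TRUE, value = TRUE)))
  assert_that(length(hits) > 0L,
              sprintf("no columns matching: %s",
                      paste(patterns, collapse = ", ")))
  hits
}

#' Re-apply the lariat catalog nesting filters to an intron table
#'
#' Given the full table of differential introns (sheet 1 of a lariat
#' catalog), re-derives the nested subsets: introns whose mean RPKM across
#' the mutant RNase R(+) libraries reaches `rpkm_min` (the RNase-R-stable
#' sheet), and among those, introns whose mean RPKM across the wild-type
#' RNase R(-) libraries reaches `rpkm_min` (the wild-type escapee sheet).
#'
#' @param sheet1 `data.frame` of all differential introns.
#' @param dbr1_rplus_cols,col0_rminus_cols column names (or regex patterns)
#'   of the per-library RPKM columns of each class.
#' @param id_col intron id column name.
#' @param rpkm_min threshold (inclusive).
#' @return list with `n_total`, `n_stable`, `n_escapee`, the id vectors,
#'   and `escapee_pct` (the escapee percentage among stable lariats,
#'   rounded to the nearest percent).
#' @export
supp_intron_nesting <- function(sheet1, dbr1_rplus_cols, col0_rminus_cols,
                                id_col = 1L, rpkm_min = 5) {
  dp <- match_columns(sheet1, dbr1_rplus_cols)
  cm <- match_columns(sheet1, col0_rminus_cols)
  ids <- as.character(sheet1[[id_col]])
  stable <- rowMeans(as.matrix(sheet1[dp])) >= rpkm_min
  escapee <- stable & rowMeans(as.matrix(sheet1[cm])) >= rpkm_min
  list(n_total = nrow(sheet1),
       n_stable = sum(stable), stable_ids = ids[stable],
       n_escapee = sum(escapee), escapee_ids = ids[escapee],
       escapee_pct = escapee_percentage(sum(escapee), sum(stable)))
}

#' Wild-type escapee percentage
#'
#' The share of RNase-R-stable lariats that are also expressed in wild
#' type, as a rounded percentage.
#'
#' @param n_escapee,n_stable category counts (escapee subset of stable).
#' @return integer percentage.
#' @export
escapee_percentage <- function(n_escapee, n_stable) {
  assert_that(n_stable > 0, "n_stable must be positive")
  assert_that(n_escapee <= n_stable, "escapees must be a subset of stable")
  round(100 * n_escapee / n_stable)
}

#' Count deregulated entries of a RIP occupancy sheet
#'
#' Recomputes, from a sheet's own log2-ratio column, how many entries are
#' deregulated (`|log2 ratio| > cut`) and how many of those are reduced
#' (`log2 ratio < -cut`); both comparisons strict.
#'
#' @param sheet occupancy `data.frame`.
#' @param ratio_col log2-ratio column name or regex.
#' @param cut fold-change cut on the log2 scale.
#' @return list with `n_deregulated`, `n_down`, `n_up`.
#' @export
supp_occupancy_counts <- function(sheet, ratio_col = "log2", cut = 1) {
  col <- match_columns(sheet, ratio_col)[1]
  lr <- suppressWarnings(as.numeric(sheet[[col]]))
  lr <- lr[!is.na(lr)]
  list(n_deregulated = sum(abs(lr) > cut),
       n_down = sum(lr < -cut), n_up = sum(lr > cut))
}

#' Intersect the id columns of two per-replicate sheets
#'
#' @param sheet1,sheet2 `data.frame`s (or id character vectors).
#' @param id_col id column name or index.
#' @return sorted character vector of common ids.
#' @export
supp_common_ids <- function(sheet1, sheet2, id_col = 1L) {
  pick <- function(s) if (is.character(s)) s else as.character(s[[id_col]])
  sort(intersect(pick(sheet1), pick(sheet2)))
}
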