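#' Conditional negative-binomial exact test for two groups
#'
#' Two-sided exact test of equal means between two groups of count
#' replicates, conditional on the total count — the test family used for
#' small-count differential abundance in RNA-seq. Counts are first scaled
#' to a common effective library size (the geometric mean of all library
#' sizes) and rounded; scaled counts are then summed within each group.
#' Under the null the group-A sum, given the total `n`, follows a negative
#' hypergeometric law with shape `r_a/phi` and `r_b/phi` (replicate counts
#' over the dispersion); the two-sided p-value sums the probabilities of
#' all outcomes whose mass does not exceed the observed outcome's mass.
#' With `dispersion = 0` this reduces to the exact binomial test.
#'
#' @param counts_a,counts_b non-negative integer counts per replicate.
#' @param lib_sizes_a,lib_sizes_b library sizes (positive), recycled to the
#'   replicate counts.
#' @param dispersion NB dispersion `phi >= 0` (0 = Poisson).
#' @return two-sided p-value in `[0,1]`; 1 when all counts are zero.
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_sizes_a = 1,
                          lib_sizes_b = 1, dispersion = 0.1) {
  assert_that(all(counts_a >= 0) && all(counts_b >= 0),
              "counts must be non-negative")
  assert_that(all(lib_sizes_a > 0) && all(lib_sizes_b > 0),
              "library sizes must be positive")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  lib_sizes_a <- rep_len(lib_sizes_a, length(counts_a))
  lib_sizes_b <- rep_len(lib_sizes_b, length(counts_b))
  common <- exp(mean(log(c(lib_sizes_a, lib_sizes_b))))
  ya <- round(sum(counts_a * common / lib_sizes_a))
  yb <- round(sum(counts_b * common / lib_sizes_b))
  n <- ya + yb
  if (n == 0) return(1)
  ra <- length(counts_a); rb <- length(counts_b)
  k <- 0:n
  logp <- if (dispersion == 0) {
    dbinom(k, n, ra / (ra + rb), log = TRUE)
  } else {
    sa <- ra / dispersion; sb <- rb / dispersion
    lp <- lgamma(k + sa) - lgamma(k + 1) + lgamma(n - k + sb) -
      lgamma(n - k + 1)
    lp - max(lp) - log(sum(exp(lp - max(lp))))
  }
  obs <- logp[ya + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-12])))
}

#' Common NB dispersion by method of moments
#'
#' Counts are scaled to the geometric-mean library size; for each feature
#' and group with replication the moment estimate `(s^2 - mu) / mu^2` is
#' computed and clamped at zero, and the estimates are averaged across
#' features weighted by abundance (`mu`): a feature with a handful of
#' reads carries essentially no information about the squared biological
#' CV and would otherwise dominate the average with pure sampling noise.
#' Without replication in any group the configured default is returned
#' with a warning.
#'
#' @param count_matrix features x libraries matrix of counts.
#' @param lib_sizes library sizes, one per column.
#' @param groups group labels, one per column.
#' @param default returned when no group has >= 2 replicates.
#' @return non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(count_matrix, lib_sizes, groups,
                                       default = 0.1) {
  count_matrix <- as.matrix(count_matrix)
  assert_that(nrow(count_matrix) >= 2L, "need at least 2 features")
  assert_that(length(lib_sizes) == ncol(count_matrix) &&
              length(groups) == ncol(count_matrix),
              "lib_sizes/groups must match the number of libraries")
  groups <- as.character(groups)
  if (!any(table(groups) >= 2L)) {
    warning("no replication in any group; returning default dispersion ",
            default)
    return(default)
  }
  common <- exp(mean(log(lib_sizes)))
  scaled <- sweep(count_matrix, 2L, common / lib_sizes, `*`)
  ests <- c(); wts <- c()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) next
    mu <- rowMeans(scaled[, cols, drop = FALSE])
    s2 <- apply(scaled[, cols, drop = FALSE], 1L, var)
    ok <- mu > 0
    ests <- c(ests, pmax(0, (s2[ok] - mu[ok]) / mu[ok]^2))
    wts <- c(wts, mu[ok])
  }
  if (!length(ests)) return(default)
  sum(ests * wts) / sum(wts)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]); NaN
#' or out-of-range p-values are an error rather than silently propagated.
#'
#' @param p_values p-values in `[0,1]`.
#' @return FDR (q) values in input order.
#' @export
bh_fdr <- function(p_values) {
  assert_that(!anyNA(p_values), "NaN/NA p-values are not allowed")
  assert_that(all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Segregation goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of an observed mutant count
#' against an expected segregation fraction (1:1 by default, the F1 test
#' for allelism of a recessive mutation crossed to a heterozygous carrier).
#'
#' @param n_mutant observed mutant count.
#' @param n_total total scored.
#' @param expected_fraction expected mutant fraction under the model.
#' @return list with `chi2`, `df` and `p`.
#' @export
segregation_test <- function(n_mutant, n_total, expected_fraction = 0.5) {
  assert_that(n_total >= 1, "n_total must be >= 1")
  assert_that(n_mutant >= 0 && n_mutant <= n_total,
              "n_mutant must lie in [0, n_total]")
  e1 <- n_total * expected_fraction
  e2 <- n_total * (1 - expected_fraction)
  chi2 <- (n_mutant - e1)^2 / e1 + ((n_total - n_mutant) - e2)^2 / e2
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Effective library sizes by median-of-ratios
#'
#' Composition-robust library-size estimate: each library's size factor is
#' the median ratio of its counts to the per-feature geometric mean across
#' libraries (computed on features with all-positive counts). Used for
#' gene-level testing, where a large class-specific RNA load (the mutant's
#' lariat burden) would otherwise masquerade as global deregulation.
#'
#' @param count_matrix features x libraries count matrix.
#' @param lib_sizes nominal sizes (returned unchanged if fewer than 10
#'   features have all-positive counts).
#' @return numeric effective sizes, scaled to the same total as
#'   `lib_sizes`.
#' @export
effective_library_sizes <- function(count_matrix, lib_sizes) {
  count_matrix <- as.matrix(count_matrix)
  pos <- rowSums(count_matrix > 0) == ncol(count_matrix)
  if (sum(pos) < 10L) return(lib_sizes)
  lm <- log(count_matrix[pos, , drop = FALSE])
  ref <- rowMeans(lm)
  sf <- exp(apply(lm - ref, 2L, median))
  eff <- lib_sizes[1] * sf  # arbitrary scale; rescale to nominal total
  eff * sum(lib_sizes) / sum(eff)
}

#' Differential count test table
#'
#' Runs [nb_exact_test()] on every row of a count matrix (group A vs group
#' B), with a shared dispersion estimated by
#' [estimate_common_dispersion()] unless supplied, and reports the fields
#' of a standard exact-test table: log2 fold change (B over A, with a 0.5
#' pseudo-count on CPM), average log2 CPM, p-value and BH FDR.
#'
#' @param count_matrix features x libraries matrix (rownames = feature ids).
#' @param lib_sizes library sizes per column.
#' @param groups two-level group labels per column; fold change is
#'   `level2 / level1` in the order given by `ref` and `alt`.
#' @param ref,alt group labels of the reference (denominator) and
#'   alternative (numerator).
#' @param dispersion optional fixed dispersion.
#' @return `data.frame` with `feature_id`, `logFC`, `logCPM`, `p_value`,
#'   `fdr`.
#' @export
exact_test_table <- function(count_matrix, lib_sizes, groups, ref, alt,
                             dispersion = NULL) {
  count_matrix <- as.matrix(count_matrix)
  assert_that(all(c(ref, alt) %in% groups),
              sprintf("missing library group: %s",
                      paste(setdiff(c(ref, alt), groups), collapse = ", ")))
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(count_matrix, lib_sizes, groups)
  a <- which(groups == ref); b <- which(groups == alt)
  cpm <- sweep(count_matrix, 2L, 1e6 / lib_sizes, `*`)
  mean_a <- rowMeans(cpm[, a, drop = FALSE])
  mean_b <- rowMeans(cpm[, b, drop = FALSE])
  p <- vapply(seq_len(nrow(count_matrix)), function(i)
    nb_exact_test(count_matrix[i, a], count_matrix[i, b],
                  lib_sizes[a], lib_sizes[b], dispersion), 0)
  data.frame(
    feature_id = rownames(count_matrix) %||%
      as.character(seq_len(nrow(count_matrix))),
    logFC = log2((mean_b + 0.5) / (mean_a + 0.5)),
    logCPM = log2((mean_a + mean_b) / 2 + 0.5),
    p_value = p, fdr = bh_fdr(p),
    row.names = NULL, stringsAsFactors = FALSE)
}
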