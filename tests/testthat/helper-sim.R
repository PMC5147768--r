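# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A compact genome for fast unit tests.
small_genome <- function(seed = 7L) {
  cached(paste0("genome", seed), function()
    build_genome(n_chrom = 2L, chrom_length = 6e4, n_genes = 30L,
                 exons_per_gene = 3L, n_mirna = 8L, n_rrna = 1L,
                 seed = seed))
}

# A quick full experiment at reduced depth.
small_sim <- function() {
  cached("small_sim", function()
    simulate_experiment(genome = small_genome(), seed = 11L,
                        depth_rnaseq = 2e4, depth_srna = 2e4,
                        depth_rip = 1e4))
}

# The default study-condition experiment (the scale every recovery
# property is stated at) and its analyses; built lazily, reused across
# test files and the acceptance suite.
default_sim <- function() {
  cached("default_sim", function() simulate_experiment(seed = 42L))
}

default_lariat <- function() {
  cached("default_lariat", function() run_lariat_analysis(default_sim()))
}

default_mirna <- function() {
  cached("default_mirna", function() run_mirna_analysis(default_sim()))
}

default_rip <- function() {
  cached("default_rip", function() run_rip_analysis(default_sim()))
}

# Hand-build an intron quantification object for boundary tests.
fake_iq <- function(rpkm_dbr1_rminus, rpkm_dbr1_rplus, rpkm_col0_rminus,
                    counts_col0, counts_dbr1, lib_size = 1e6) {
  n <- length(rpkm_dbr1_rminus)
  ids <- sprintf("G%dI1", seq_len(n))
  man <- data.frame(
    library_id = c("c1", "c2", "d1", "d2", "dp1", "dp2", "cp1"),
    genotype = c("Col0", "Col0", "dbr1_2", "dbr1_2", "dbr1_2", "dbr1_2",
                 "Col0"),
    treatment = c("RNaseR_minus", "RNaseR_minus", "RNaseR_minus",
                  "RNaseR_minus", "RNaseR_plus", "RNaseR_plus",
                  "RNaseR_plus"),
    replicate = c(1, 2, 1, 2, 1, 2, 1), stringsAsFactors = FALSE)
  rpkm <- cbind(c1 = rpkm_col0_rminus, c2 = rpkm_col0_rminus,
                d1 = rpkm_dbr1_rminus, d2 = rpkm_dbr1_rminus,
                dp1 = rpkm_dbr1_rplus, dp2 = rpkm_dbr1_rplus,
                cp1 = rpkm_col0_rminus)
  counts <- cbind(c1 = counts_col0, c2 = counts_col0,
                  d1 = counts_dbr1, d2 = counts_dbr1,
                  dp1 = counts_dbr1, dp2 = counts_dbr1,
                  cp1 = counts_col0)
  rownames(rpkm) <- rownames(counts) <- ids
  list(info = data.frame(intron_id = ids, gene_id = sub("I1", "", ids),
                         chrom = "chr1", start = seq_len(n) * 1000L,
                         end = seq_len(n) * 1000L + 300L, strand = "+",
                         stringsAsFactors = FALSE),
       rpkm = rpkm, counts = counts,
       lib_sizes = setNames(rep(lib_size, 7), man$library_id),
       manifest = man)
}
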