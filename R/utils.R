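#' @importFrom stats rgamma rpois rbinom runif rmultinom rnbinom pchisq
#'   p.adjust dnbinom dbinom setNames median quantile var
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed: keeps derived seeds inside 32-bit integer range.
derive_seed <- function(seed, salt) {
  salt_num <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.double(seed) * 48271 + salt_num) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Sample integers between lo and hi inclusive (scalar-safe, unlike sample()).
runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))
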