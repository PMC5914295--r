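#' @import data.table
#' @importFrom stats rbinom runif pchisq pnorm pf qlogis plogis dbinom
#' @importFrom utils head tail
NULL

# Run code with a temporary RNG state; the caller's .Random.seed is restored
# afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-sample seed from (master seed, sample_id): a small
# polynomial string hash folded into [0, 2^31 - 2].  Independent of sample
# order, so per-sample streams are reproducible under parallel generation.
derive_seed <- function(seed, sample_id) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(sample_id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  chartr("ACGTNacgtn", "TGCANtgcan", b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
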