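#' Derive a reproducible substream seed
#'
#' Folds a root seed and an arbitrary sequence of labels (integers or
#' strings) into a single integer seed below 2^31, so that each pipeline
#' stage and each participant draws from its own deterministic stream.
#' Adding participants or stages never reshuffles existing streams.
#'
#' @param root Integer root seed.
#' @param ... Labels (character or numeric) identifying the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(20220414, "cohort", 3)
substream_seed <- function(root, ...) {
  parts <- list(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(as.integer(root)) %% m
  for (p in parts) {
    v <- if (is.character(p)) unlist(lapply(p, utf8ToInt)) else as.double(p)
    for (x in v) {
      # 69069 * (2^31) < 2^53: exact in double arithmetic
      h <- (h * 69069 + as.double(x) + 1) %% m
    }
  }
  as.integer(h)
}

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
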