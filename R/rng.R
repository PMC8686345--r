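#' Derive a deterministic substream seed
#'
#' Hashes a master seed together with an arbitrary set of labels (FNV-1a over
#' the concatenated key) into a 31-bit integer suitable for [set.seed()].
#' Every stochastic operation in the package draws its randomness from a named
#' substream of the experiment seed, so e.g. adding subjects to a cohort or
#' cells to an experiment grid does not perturb draws made for earlier ones.
#'
#' @param seed Integer master seed.
#' @param ... Further labels (coerced to character) naming the substream.
#' @return A single integer in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(1, "cohort", 5)
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483629)
}
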