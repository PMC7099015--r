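# Shared internal helpers.

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage seeds its RNG with `derive_seed(master, tag)` so that
#' adding or reordering stages never perturbs another stage's random stream.
#' The result is a deterministic 31-bit integer.
#'
#' @param master integer master seed.
#' @param tag character stage name.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(tag))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(tag)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Rank of each value with average ties, NA kept NA.
.rank_avg <- function(x) rank(x, ties.method = "average", na.last = "keep")

# Column means ignoring NA, guarding empty columns.
.col_freq <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  p
}
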