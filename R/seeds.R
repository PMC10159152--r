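#' Derive a per-stage seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' (site selection, simulation, each sampler chain, Monte Carlo summaries)
#' uses a seed derived deterministically by hashing the master seed together
#' with the stage name (32-bit FNV-1a, reduced modulo 2^31 - 1), which keeps
#' stages on distinct, uncoupled random streams.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' stage_seed(1, "simulate")
#' @export
stage_seed <- function(master, stage) {
  s <- paste0(format(master, scientific = FALSE), ":", stage)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b)
    h <- mulmod32(h, 16777619)
  }
  as.integer(h %% (2^31 - 1) + 1)
}

# xor of doubles holding 32-bit values (bitwXor needs ints < 2^31)
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 2^16; lo_a <- a %% 2^16
  hi_b <- b %/% 2^16; lo_b <- b %% 2^16
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^16 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

# (a * b) mod 2^32 without losing precision past 2^53
mulmod32 <- function(a, b) {
  hi <- ((a %/% 2^16) * b) %% 2^16
  lo <- (a %% 2^16) * b
  (hi * 2^16 + lo) %% 2^32
}
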