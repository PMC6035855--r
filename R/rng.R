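# Named random substreams.
#
# Every stochastic element of a replication (arrivals, need profiles, each
# activity's service times and offsets) draws from its own substream whose
# seed is a deterministic hash of (root seed, replication, stream name).
# Scenarios that leave an activity untouched therefore reuse exactly the
# same draws as the baseline: common random numbers fall out of the keying,
# and a scenario with no overrides reproduces the baseline records
# bit-for-bit.

MERSENNE31 <- 2147483647  # 2^31 - 1

stream_seed <- function(seed, rep, name) {
  h <- as.numeric(seed) %% MERSENNE31
  h <- (h * 31 + as.numeric(rep)) %% MERSENNE31
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% MERSENNE31
  as.integer(h %% 2147483646) + 1L  # in [1, 2^31 - 1]
}

# evaluate expr with the RNG seeded for one substream, restoring the
# caller's RNG state afterwards
with_stream <- function(seed, rep, name, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(stream_seed(seed, rep, name))
  expr
}
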