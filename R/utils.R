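# internal helpers

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

stop_data <- function(msg) {
  stop(msg, call. = FALSE)
}

# Deterministic per-stratum seed derived from a base seed and small integer
# indices, kept below 2^31 so it is a valid R seed. Streams for distinct
# strata are independent of how many strata are generated, so adding
# replicates never perturbs earlier draws.
stream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
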