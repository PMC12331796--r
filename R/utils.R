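# internal helpers shared across modules

# Seed the RNG for a pipeline stage. One master seed expands into
# stage-specific seeds via a fixed offset table so that replicate counts in one
# stage never shift the draws of another.
.stage_offsets <- c(design = 11L, simulate = 23L, permutation = 37L,
                    bootstrap = 53L, chance_null = 71L, analysis = 89L)

stage_seed <- function(seed, stage) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) * 101 + off) %% 2147483647)
}

local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

clip01 <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

# small stable polynomial hash of a character scalar, for config provenance;
# returned as 8-digit hex (exact in doubles: intermediate < 2^53)
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
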