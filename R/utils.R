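# Internal helpers shared across the pipeline.

# Evaluate `code` under a deterministic RNG state without disturbing the
# caller's random-number stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Dense, tie-aware descending rank: the largest value gets rank 1 and equal
# values share a rank, with no gaps.
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

# Derive a per-stage substream seed from one global seed, kept within the
# 32-bit integer range.
substream_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, split = 211L, model = 307L, noise = 401L, factor = 503L
  )
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 7L + off) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

RESPONDER <- "responder"
NON_RESPONDER <- "non-responder"
GROUP_LEVELS <- c(RESPONDER, NON_RESPONDER)
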