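# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb the
# user's random stream. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# round-half-up to the nearest multiple of `to` (base round() is half-even)
round_half_up <- function(x, to = 100) floor(x / to + 0.5) * to

# largest-remainder apportionment: integer counts summing exactly to n,
# proportional to `p` (which must sum to 1)
apportion <- function(p, n) {
  raw <- p * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }
  as.integer(cnt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
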