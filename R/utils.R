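# Internal helpers: seeded RNG scoping, clamping, condition constructors.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All package randomness goes through
# this so that library calls elsewhere never perturb reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_skullmark("invalid_config", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Counter scheme for deriving independent sub-seeds from a master seed.
# Documented contract: stream i of master seed s is (s * 1000003 + i)
# reduced mod 2^31 - 1, so datasets are extensible without reshuffling.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_skullmark <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("skullmark_", class), "skullmark_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Channel-axis concatenation / split for (H, W, C, N) arrays.
concat_channels <- function(xs) {
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(z) dim(z)[3L], integer(1))
  out <- array(0, c(d[1L], d[2L], sum(cs), d[4L]))
  off <- 0L
  for (z in xs) {
    out[, , off + seq_len(dim(z)[3L]), ] <- z
    off <- off + dim(z)[3L]
  }
  out
}

split_channels <- function(x, sizes) {
  off <- 0L
  lapply(sizes, function(s) {
    idx <- off + seq_len(s)
    off <<- off + s
    x[, , idx, , drop = FALSE]
  })
}
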