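# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library functions that consume randomness do not
#' perturb (or get perturbed by) the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed and a stage tag, deterministically
# and within 32-bit integer range. FNV-1a over the tag, folded with the seed.
derive_seed <- function(master_seed, tag) {
  h <- fnv1a(paste0(tag, ":", as.integer(master_seed)))
  as.integer(h %% 2147483587) + 1L
}

# FNV-1a hash of a string, done in double precision modulo 2^31 - 1 to stay
# exact (all intermediates < 2^53).
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  m <- 2147483647
  h <- 2166136261 %% m
  for (b in bytes) {
    h <- ((h %% 65536) * 16777619 + bitwXor(as.integer(h %% 65536), b) -
            h %% 65536) %% m
    # xor on the low byte then multiply; keep arithmetic exact
    h <- (xor_low(h, b) * (16777619 %% m)) %% m
  }
  h
}

xor_low <- function(h, b) {
  lo <- h %% 256
  h - lo + bitwXor(as.integer(lo), as.integer(b))
}

# Short hexadecimal digest of an R object for config fingerprinting.
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15,
                                              vec.len = 1e6)), collapse = "\n")
  sprintf("%08x", fnv1a(s))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
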