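# Internal helpers: seeding, hashing, validation.

# FNV-1a 32-bit hash, exact in double arithmetic: the xor touches only the
# low 16 bits (bytes < 256) and the multiplication is split into 16-bit
# halves to stay under 2^53.
.fnv_fold <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(lo, b)
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

fnv1a <- function(s) .fnv_fold(utf8ToInt(s))

# Hash an arbitrary R object (used for split-plan fingerprints).
object_fingerprint <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- .fnv_fold(as.integer(raw))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Named substream: derive a child seed from a root seed and a stream name so
# that modules can be re-run independently yet reproducibly.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  as.integer((abs(seed) + fnv1a(as.character(stream))) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scale a vector of effects to an exact sample variance (n-1 denominator),
# preserving mean zero; a zero target returns exact zeros.
scale_to_var <- function(x, target_var) {
  x <- x - mean(x)
  if (target_var <= 0) return(x * 0)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) stop_("cannot rescale a constant vector to positive variance")
  x * sqrt(target_var) / s
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == floor(x)
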