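# Internal helpers: seed handling, provenance, small validations.

# Evaluate expr under a local RNG stream; the caller's .Random.seed is
# untouched. A NULL/NA seed means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
    return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-stage child seeds from one master seed, kept inside the
# 32-bit integer range so downstream set.seed() is portable.
childSeed <- function(seed, k) {
  if (is.null(seed) || is.na(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1000003 * k) %% .Machine$integer.max)
}

# FNV-1a hash of a deparsed object; used to stamp configurations into reports.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

stopIfNot01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a single value in [0, 1]", name), call. = FALSE)
}

# Symmetric zero-diagonal matrix -> dist with a kind label.
asKindDist <- function(m, kind) {
  d <- stats::as.dist(m)
  attr(d, "kind") <- kind
  d
}

distKind <- function(d) attr(d, "kind")
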