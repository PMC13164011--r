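# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never perturb the
#' caller's random stream.
#' @noRd
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Row-wise softmax with max subtraction for numerical stability.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# FNV-1a 32-bit hash of a character scalar; used to stamp outputs with a
# provenance hash of their configuration (no external digest dependency).
# Arithmetic is kept below 2^53 by splitting the 32-bit state into 16-bit
# halves for the modular multiply; the byte xor only touches the low 8 bits.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(cfg) {
  fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE))
}

class_levels <- function() c("normal", "frost_damaged")
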