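# Small internal helpers shared across modules.

# Deterministic child seeds: derive a stream of 32-bit seeds from one integer
# so each stage/replicate consumes its own seed without correlated streams.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(charToRaw(digest_string(key)), 4)
  val <- sum(as.integer(raw) * 256^(0:3))
  as.integer(val %% 2147483647L)
}

# Tiny stable string hash (FNV-1a, hex); avoids external digest dependency.
digest_string <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  paste0(format(as.hexmode(as.integer(h)), width = 8),
         format(as.hexmode(as.integer((h * 31 + sum(bytes)) %% 2^31)), width = 8))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

spectral_radius <- function(B) {
  if (length(B) == 1L) return(abs(as.numeric(B)))
  max(Mod(eigen(B, only.values = TRUE)$values))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x[!is.na(x)]))) {
    abort(sprintf("non-finite values in %s", what), class = "panelnets_validation_error")
  }
}

sym_part <- function(m) (m + t(m)) / 2

# Partial correlations from a precision matrix; zero diagonal.
precision_to_pcor <- function(K) {
  d <- sqrt(diag(K))
  pc <- -K / tcrossprod(d)
  diag(pc) <- 0
  sym_part(pc)
}
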