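# internal helpers shared across modules

# Round half away from zero to `digits` decimals. base::round() rounds half to
# even, which would print 0.25 -> 0.2; reported percentages use the
# half-away-from-zero convention (98 -> 98.0, not 97.9/98.1 artifacts).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps all package randomness reproducible without leaking global state.
with_seed <- function(seed, expr) {
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
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Reverse complement of a character vector of single bases.
revcomp_chars <- function(x) {
  rev(comp_base(x))
}

revcomp_string <- function(s) {
  paste(revcomp_chars(strsplit(s, "")[[1]]), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
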