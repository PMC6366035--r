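# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Normalize a nucleotide string to DNA upper case; error on anything
# outside {A,C,G,T,U,N}.
as_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("u", "U", toupper(x))
  s <- chartr("U", "T", s)
  if (nchar(s) > 0L && grepl("[^ACGTN]", s)) {
    stop_invalid("invalid characters in %s (expected A/C/G/T/U)", what)
  }
  s
}

reverse_complement <- function(x) {
  s <- as_dna(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Fraction of G/C characters, as a percentage in [0, 100].
gc_percent <- function(x) {
  s <- as_dna(x)
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  100 * (nchar(gsub("[^GC]", "", s))) / n
}
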