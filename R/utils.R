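# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; keeps results < 2^31 for R's RNG.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

# Encode an upper-case DNA string as integers 1=A 2=C 3=G 4=T 5=N.
encode_dna <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  code <- match(chars, c(DNA_BASES, "N"))
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("invalid DNA character(s): ", paste(bad, collapse = ", "),
         " (alphabet is A/C/G/T plus ambiguity code N)")
  }
  code
}

# Reverse complement of an integer-encoded sequence (N stays N).
revcomp_encoded <- function(code) {
  rev(c(4L, 3L, 2L, 1L, 5L)[code])
}

reverse_complement <- function(sequence) {
  comp <- chartr("ACGTN", "TGCAN", sequence)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
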