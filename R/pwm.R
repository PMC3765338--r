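#' Convert a position frequency matrix to a position weight matrix
#'
#' Normalizes a 4 x W matrix of per-position base counts (rows A, C, G, T)
#' into per-position frequencies with a background-weighted pseudocount,
#' and precomputes the log2-odds scores used for scanning:
#' \deqn{f_j(b) = \frac{n_j(b) + s\,\pi(b)}{\sum_b n_j(b) + s}}
#' where \eqn{s} is the pseudocount and \eqn{\pi} the background
#' distribution. With \eqn{s > 0} every frequency is strictly positive, so
#' log-odds scores are finite.
#'
#' @param counts numeric 4 x W matrix of non-negative base counts; rows are
#'   taken in A, C, G, T order (row names, if present, must be a permutation
#'   of those and are honoured).
#' @param pseudocount non-negative smoothing mass added per column (default
#'   0.8, split by the background distribution).
#' @param background base background frequencies (A, C, G, T); default
#'   uniform 0.25.
#' @param id motif identifier carried through scan results.
#' @param name optional human-readable motif name.
#' @return An object of class `"pwm"`: a list with the frequency matrix
#'   (`mat`), raw `counts`, `logodds` matrix, motif `width`, per-column
#'   score extrema and the parameters used.
#' @examples
#' pwm <- normalize_pfm(matrix(c(8, 0, 0, 0), 4, 1,
#'                             dimnames = list(c("A", "C", "G", "T"), NULL)),
#'                      pseudocount = 0, id = "A1")
#' pwm$mat[, 1]
#' @export
normalize_pfm <- function(counts, pseudocount = 0.8,
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          id = "motif", name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("a PFM needs exactly 4 rows (A, C, G, T); got ", nrow(counts))
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES))
      stop("PFM row names must be A, C, G, T")
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else {
    rownames(counts) <- DNA_BASES
  }
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("PFM counts must be finite and non-negative")
  if (ncol(counts) < 1L) stop("PFM must have width >= 1")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("PFM column(s) ", paste(which(totals == 0), collapse = ", "),
         " are all zero")
  if (length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 positive frequencies summing to 1")
  background <- background / sum(background)

  freq <- sweep(counts, 1L, background * pseudocount, `+`)
  freq <- sweep(freq, 2L, totals + pseudocount, `/`)
  logodds <- log2(sweep(freq, 1L, background, `/`))
  col_max <- apply(logodds, 2L, max)
  col_min <- apply(logodds, 2L, min)
  structure(list(
    id = as.character(id),
    name = as.character(name),
    counts = counts,
    mat = freq,
    logodds = logodds,
    width = ncol(counts),
    pseudocount = pseudocount,
    background = stats::setNames(background, DNA_BASES),
    max_score = sum(col_max),
    min_score = sum(col_min)
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix '%s' (width %d)\n", x$id, x$width))
  cat("  consensus:  ", pwm_consensus(x), "\n", sep = "")
  cat(sprintf("  score range: [%.3f, %.3f] bits (pseudocount %.2f)\n",
              x$min_score, x$max_score, x$pseudocount))
  invisible(x)
}

#' Consensus sequence of a PWM (per-column most frequent base)
#'
#' @param pwm a `"pwm"` object.
#' @return A character string of length equal to the motif width.
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  paste(DNA_BASES[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Per-column information content of a PWM, in bits
#'
#' Computed from the pseudocount-free count frequencies when counts are
#' available, relative to a uniform background: \eqn{2 + \sum_b f \log_2 f}.
#'
#' @param pwm a `"pwm"` object.
#' @return Numeric vector, one value per motif position.
#' @export
pwm_information <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  freq <- sweep(pwm$counts, 2L, colSums(pwm$counts), `/`)
  apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' Build a high-information PWM from a consensus string
#'
#' Utility for constructing synthetic binding models: each column gives
#' `dominance` of the count mass to the consensus base and splits the rest
#' evenly. Used for the package's synthetic CREB-like and E2F1-like motifs
#' and in tests.
#'
#' @param consensus DNA string over A/C/G/T.
#' @param id motif identifier.
#' @param dominance fraction of counts on the consensus base per column,
#'   in (0.25, 1].
#' @param total total counts per column.
#' @param ... passed to [normalize_pfm()] (e.g. `pseudocount`).
#' @return A `"pwm"` object.
#' @export
consensus_pwm <- function(consensus, id = consensus, dominance = 0.97,
                          total = 1000, ...) {
  consensus <- toupper(consensus)
  bases <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  if (!all(bases %in% DNA_BASES)) stop("consensus must be over A/C/G/T")
  if (dominance <= 0.25 || dominance > 1)
    stop("dominance must lie in (0.25, 1]")
  main <- round(total * dominance)
  rest <- total - main
  counts <- vapply(bases, function(b) {
    col <- rep(rest %/% 3, 4L)
    col[match(b, DNA_BASES)] <- main + (rest - 3 * (rest %/% 3))
    col
  }, numeric(4L))
  dimnames(counts) <- list(DNA_BASES, NULL)
  normalize_pfm(counts, id = id, ...)
}

#' Synthetic CREB-like and E2F1-like binding models
#'
#' The package ships no third-party motif database. These are synthetic
#' high-information 12-bp models embedding the canonical CRE palindrome
#' (TGACGTCA) and the E2F core (TTTCGCGC) respectively; real JASPAR
#' matrices can be supplied instead via [read_pfm()].
#'
#' @param dominance per-column consensus dominance; see [consensus_pwm()].
#' @return Named list with `"pwm"` objects `creb_like` and `e2f1_like`.
#' @export
focal_pwms <- function(dominance = 0.97) {
  list(
    creb_like = consensus_pwm("TTGACGTCAGCT", id = "creb_like",
                              dominance = dominance),
    e2f1_like = consensus_pwm("GCTTTCGCGCCA", id = "e2f1_like",
                              dominance = dominance)
  )
}

#' Score a single window under a PWM
#'
#' Raw score is the summed log2-odds \eqn{\sum_j \log_2 f_j(b_j)/\pi(b_j)};
#' the relative score rescales it by the best and worst achievable scores,
#' \eqn{(raw - min)/(max - min)}, giving a value in \[0, 1\] — the quantity
#' thresholded (conventionally at 0.85) during promoter scanning. `N` bases
#' contribute zero log-odds. A degenerate matrix whose best and worst scores
#' coincide scores 1 by convention.
#'
#' @param pwm a `"pwm"` object.
#' @param kmer DNA string of length exactly `pwm$width`.
#' @return Named numeric vector with elements `raw` and `relative`.
#' @export
score_window <- function(pwm, kmer) {
  stopifnot(inherits(pwm, "pwm"))
  kmer <- toupper(kmer)
  code <- encode_dna(kmer)
  if (length(code) != pwm$width)
    stop("window length ", length(code), " does not match motif width ",
         pwm$width)
  lo <- rbind(pwm$logodds, N = 0)
  raw <- sum(lo[cbind(code, seq_len(pwm$width))])
  span <- pwm$max_score - pwm$min_score
  rel <- if (span > 0) (raw - pwm$min_score) / span else 1
  c(raw = raw, relative = rel)
}
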