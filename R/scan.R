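#' Scan a sequence for PWM matches above a relative-score threshold
#'
#' Slides the motif over every window of the sequence (and, by default, of
#' its reverse complement) and keeps windows whose min–max-normalized
#' log-odds score reaches the threshold. Coordinates are 0-based starts on
#' the supplied sequence, which is expected to be a promoter already
#' oriented 5'->3' upstream of the TSS; minus-strand hits are reported at
#' the window they occupy on that same coordinate frame.
#'
#' @param pwm a `"pwm"` object from [normalize_pfm()].
#' @param sequence DNA string (A/C/G/T plus N).
#' @param threshold relative score cut-off in \[0, 1\]; default 0.85, the
#'   conventional promoter-scanning matrix-similarity cut-off.
#' @param both_strands scan the reverse complement as well (default TRUE).
#' @param gene optional gene id attached to the hits.
#' @return A data frame with columns `gene`, `motif`, `start` (0-based),
#'   `strand` (`"+"`/`"-"`), `raw` and `relative`, sorted by (start, strand).
#'   Zero rows if the sequence is shorter than the motif.
#' @examples
#' pwm <- consensus_pwm("ACGT", dominance = 1, pseudocount = 0.25)
#' scan_sequence(pwm, "ACGTACGT", threshold = 1)
#' @export
scan_sequence <- function(pwm, sequence, threshold = 0.85,
                          both_strands = TRUE, gene = NA_character_) {
  stopifnot(inherits(pwm, "pwm"))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  sequence <- toupper(sequence)
  code <- encode_dna(sequence)
  W <- pwm$width
  L <- length(code)
  empty <- data.frame(gene = character(), motif = character(),
                      start = integer(), strand = character(),
                      raw = numeric(), relative = numeric(),
                      stringsAsFactors = FALSE)
  if (L < W) return(empty)

  lo5 <- rbind(pwm$logodds, N = 0)
  span <- pwm$max_score - pwm$min_score

  relativize <- function(raw) {
    if (span > 0) (raw - pwm$min_score) / span else rep(1, length(raw))
  }
  # tiny slack so that e.g. threshold 1.0 retains exact-consensus windows
  # despite floating-point summation order
  keep_at <- function(rel) which(rel >= threshold - 1e-9)

  raw_f <- pwm_window_scores(code, lo5)
  rel_f <- relativize(raw_f)
  idx_f <- keep_at(rel_f)

  out <- data.frame(gene = rep(gene, length(idx_f)),
                    motif = rep(pwm$id, length(idx_f)),
                    start = idx_f - 1L,
                    strand = rep("+", length(idx_f)),
                    raw = raw_f[idx_f], relative = rel_f[idx_f],
                    stringsAsFactors = FALSE)

  if (both_strands) {
    rc <- revcomp_encoded(code)
    raw_r <- pwm_window_scores(rc, lo5)
    rel_r <- relativize(raw_r)
    idx_r <- keep_at(rel_r)
    # window i (1-based) on the reverse complement covers original
    # positions [L - W - i + 1, L - i + 1), i.e. 0-based start L - W - i + 1
    out_r <- data.frame(gene = rep(gene, length(idx_r)),
                        motif = rep(pwm$id, length(idx_r)),
                        start = L - W - idx_r + 1L,
                        strand = rep("-", length(idx_r)),
                        raw = raw_r[idx_r], relative = rel_r[idx_r],
                        stringsAsFactors = FALSE)
    out <- rbind(out, out_r)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count PWM hits in a sequence
#'
#' Number of windows (both strands) whose relative score reaches the
#' threshold; the site-occurrence count used for focal-TFBS analyses.
#'
#' @inheritParams scan_sequence
#' @return Non-negative integer.
#' @export
count_sites <- function(pwm, sequence, threshold = 0.85) {
  nrow(scan_sequence(pwm, sequence, threshold = threshold,
                     both_strands = TRUE))
}

# Fast internal hit counter used by the matrix builder: same scoring path
# as scan_sequence but skips hit-record construction.
count_hits_encoded <- function(lo5, min_score, span, code, rc, threshold,
                               both_strands = TRUE) {
  thr <- threshold - 1e-9
  n <- 0L
  raw <- pwm_window_scores(code, lo5)
  if (length(raw)) {
    rel <- if (span > 0) (raw - min_score) / span else rep(1, length(raw))
    n <- n + sum(rel >= thr)
  }
  if (both_strands) {
    raw <- pwm_window_scores(rc, lo5)
    if (length(raw)) {
      rel <- if (span > 0) (raw - min_score) / span else rep(1, length(raw))
      n <- n + sum(rel >= thr)
    }
  }
  as.integer(n)
}

#' Build the motif/gene matrix from promoter scans
#'
#' Scans every promoter with every motif and records, per (gene, motif),
#' either binary presence (>= 1 hit) or the hit count. This genes x motifs
#' table is the object consumed by co-inertia and representation analyses.
#'
#' @param promoters named character vector of promoter sequences (names are
#'   gene ids, e.g. from [read_fasta()]).
#' @param pwms list of `"pwm"` objects (a motif library).
#' @param threshold relative-score cut-off, default 0.85.
#' @param mode `"binary"` (presence/absence) or `"count"`.
#' @param both_strands scan both strands (default TRUE).
#' @param genes optional gene ids to include; genes without a promoter
#'   sequence are dropped with a warning rather than imputed as zero.
#' @return Integer matrix (genes x motifs) with dimnames, `mode` and
#'   `threshold` attached as attributes.
#' @export
build_motif_gene_matrix <- function(promoters, pwms, threshold = 0.85,
                                    mode = c("binary", "count"),
                                    both_strands = TRUE, genes = NULL) {
  mode <- match.arg(mode)
  if (length(promoters) == 0L) stop("no promoter sequences supplied")
  if (is.null(names(promoters)) || anyNA(names(promoters)) ||
      any(names(promoters) == ""))
    stop("promoters must be named by gene id")
  if (anyDuplicated(names(promoters)))
    stop("duplicated gene ids in promoters")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  ids <- vapply(pwms, function(p) p$id, character(1L))
  if (anyDuplicated(ids)) stop("duplicated motif ids in library")

  if (!is.null(genes)) {
    missing <- setdiff(genes, names(promoters))
    if (length(missing)) {
      warning(length(missing), " gene(s) have no promoter sequence and ",
              "were dropped: ", paste(utils::head(missing, 5L), collapse = ", "),
              if (length(missing) > 5L) ", ...")
      genes <- setdiff(genes, missing)
    }
    promoters <- promoters[genes]
    if (length(promoters) == 0L)
      stop("no requested gene has a promoter sequence")
  }

  enc <- lapply(promoters, function(s) encode_dna(toupper(s)))
  enc_rc <- lapply(enc, revcomp_encoded)

  mat <- matrix(0L, nrow = length(promoters), ncol = length(pwms),
                dimnames = list(names(promoters), ids))
  for (m in seq_along(pwms)) {
    p <- pwms[[m]]
    lo5 <- rbind(p$logodds, N = 0)
    span <- p$max_score - p$min_score
    for (g in seq_along(enc)) {
      mat[g, m] <- count_hits_encoded(lo5, p$min_score, span,
                                      enc[[g]], enc_rc[[g]], threshold,
                                      both_strands)
    }
  }
  if (mode == "binary") mat <- (mat > 0L) + 0L
  attr(mat, "mode") <- mode
  attr(mat, "threshold") <- threshold
  mat
}
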