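# Focal-TFBS stratification: select a GO-defined gene subset, count
# CREB-like and E2F1-like sites in the long upstream window, order genes
# by co-treatment fold change and test whether site counts track
# expression direction.

#' Select genes carrying an annotation term
#'
#' Case-insensitive substring match against the annotation's term text by
#' default (mirroring a free-text GO annotation search); `mode = "exact"`
#' requires term equality.
#'
#' @param universe gene ids eligible for selection.
#' @param annotation data frame with columns `gene` and `term` (one row
#'   per pair; genes may repeat).
#' @param term non-empty query string (e.g. `"actin"`).
#' @param mode `"substring"` (default) or `"exact"`.
#' @return Sorted character vector of matching genes, a subset of
#'   `universe`.
#' @export
subset_by_go <- function(universe, annotation, term,
                         mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  if (!is.character(term) || length(term) != 1L || !nzchar(term))
    stop("term must be a non-empty string")
  if (!all(c("gene", "term") %in% names(annotation)))
    stop("annotation needs columns 'gene' and 'term'")
  hit <- if (mode == "substring")
    grepl(tolower(term), tolower(annotation$term), fixed = TRUE)
  else annotation$term == term
  sort(intersect(unique(annotation$gene[hit]), universe))
}

#' Count focal binding sites per gene in long promoter windows
#'
#' Counts hits of each focal motif (both strands, relative-score
#' threshold) in each gene's long upstream window. Genes without a
#' promoter sequence are dropped with a warning; promoters shorter than a
#' motif yield a zero count.
#'
#' @param gene_set gene ids to count.
#' @param promoters named character vector of long-window promoter
#'   sequences.
#' @param pwms named list of `"pwm"` objects (typically CREB-like and
#'   E2F1-like; see [focal_pwms()]).
#' @param threshold relative-score cut-off, default 0.85.
#' @return Data frame: `gene` plus one `<motif>_count` column per motif.
#' @export
count_focal_sites <- function(gene_set, promoters, pwms, threshold = 0.85) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  missing <- setdiff(gene_set, names(promoters))
  if (length(missing)) {
    warning(length(missing), " gene(s) without promoter sequence dropped")
    gene_set <- setdiff(gene_set, missing)
  }
  if (!length(gene_set)) stop("no gene in the set has a promoter")
  counts <- vapply(pwms, function(p) {
    vapply(gene_set, function(g)
      count_sites(p, promoters[[g]], threshold = threshold), integer(1L))
  }, integer(length(gene_set)))
  counts <- matrix(counts, nrow = length(gene_set),
                   dimnames = list(NULL, paste0(
                     vapply(pwms, function(p) p$id, character(1L)),
                     "_count")))
  data.frame(gene = gene_set, counts, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Test whether site counts stratify with expression fold change
#'
#' Orders genes by descending log2 fold change (ties broken by gene id)
#' and quantifies, per motif: (i) the Spearman rank correlation between
#' site count and fold change, with a permutation p-value obtained by
#' shuffling the fold-change labels; (ii) the difference in mean site
#' count between up- (FC > 0) and down-regulated (FC < 0) genes, with a
#' label-permutation p-value; genes with FC exactly 0 are excluded from
#' (ii). Both p-values are two-sided with add-one smoothing. A motif whose
#' counts are all identical is flagged degenerate and reported as rho = 0,
#' p = 1.
#'
#' @param counts data frame from [count_focal_sites()].
#' @param fold_changes named numeric vector gene -> log2FC covering the
#'   counted genes.
#' @param n_perm number of permutations (default 1999).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return An object of class `"stratification"`: `table` (gene, log2fc
#'   and counts, ordered by descending FC), `stats` (per motif: `rho`,
#'   `p_rho`, `mean_diff`, `p_diff`, `degenerate`, significance flags),
#'   plus the parameters used.
#' @export
stratify <- function(counts, fold_changes, n_perm = 1999, alpha = 0.05,
                     seed = 1) {
  if (!all(counts$gene %in% names(fold_changes)))
    stop("fold changes missing for some counted genes")
  fc <- unname(fold_changes[counts$gene])
  motif_cols <- setdiff(names(counts), "gene")
  if (!length(motif_cols)) stop("no count columns")
  up <- fc > 0; down <- fc < 0
  if (sum(up) < 3L || sum(down) < 3L)
    stop("need >= 3 genes on each side of FC = 0 for the two-group test")

  ord <- order(-fc, counts$gene)
  tab <- data.frame(gene = counts$gene, log2fc = fc,
                    counts[motif_cols], stringsAsFactors = FALSE,
                    check.names = FALSE)[ord, , drop = FALSE]
  rownames(tab) <- NULL

  n <- length(fc)
  rf <- rank(fc)
  stats_rows <- lapply(motif_cols, function(cl) {
    x <- counts[[cl]]
    degenerate <- length(unique(x)) == 1L
    if (degenerate) {
      return(data.frame(motif = sub("_count$", "", cl), rho = 0,
                        p_rho = 1, mean_diff = 0, p_diff = 1,
                        degenerate = TRUE, sig_rho = FALSE,
                        sig_diff = FALSE, stringsAsFactors = FALSE))
    }
    rx <- rank(x)
    rho <- cor(rx, rf)
    md <- mean(x[up]) - mean(x[down])
    res <- with_seed(child_seed(seed, match(cl, motif_cols)), {
      rho_perm <- vapply(seq_len(n_perm), function(b)
        cor(rx, rf[sample.int(n)]), numeric(1L))
      lab <- which(up | down)
      n_up <- sum(up)
      md_perm <- vapply(seq_len(n_perm), function(b) {
        pu <- sample(lab, n_up)
        mean(x[pu]) - mean(x[setdiff(lab, pu)])
      }, numeric(1L))
      list(rho_perm = rho_perm, md_perm = md_perm)
    })
    two_sided <- function(obs, perm) {
      ge <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
      le <- (1 + sum(perm <= obs + 1e-12)) / (n_perm + 1)
      min(1, 2 * min(ge, le))
    }
    p_rho <- two_sided(rho, res$rho_perm)
    p_diff <- two_sided(md, res$md_perm)
    data.frame(motif = sub("_count$", "", cl), rho = rho, p_rho = p_rho,
               mean_diff = md, p_diff = p_diff, degenerate = FALSE,
               sig_rho = p_rho < alpha, sig_diff = p_diff < alpha,
               stringsAsFactors = FALSE)
  })
  structure(list(
    table = tab,
    stats = do.call(rbind, stats_rows),
    alpha = alpha, n_perm = n_perm, seed = seed
  ), class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("TFBS count / fold-change stratification\n")
  cat(sprintf("  %d genes (%d up, %d down), %d permutations\n",
              nrow(x$table), sum(x$table$log2fc > 0),
              sum(x$table$log2fc < 0), x$n_perm))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x a `"stratification"` object.
#' @param ... passed to [graphics::barplot()].
#' @describeIn stratify plot per-gene site counts as bars ordered by
#'   descending fold change (one panel per motif) over the fold-change
#'   profile.
#' @export
plot.stratification <- function(x, ...) {
  motif_cols <- setdiff(names(x$table), c("gene", "log2fc"))
  old <- graphics::par(mfrow = c(length(motif_cols) + 1L, 1L),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(x$table$log2fc, border = NA, col = "grey50",
                    ylab = "log2 FC", main = "genes by fold change")
  for (cl in motif_cols) {
    graphics::barplot(x$table[[cl]], border = NA, col = "steelblue",
                      ylab = cl, ...)
  }
  invisible(x)
}
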