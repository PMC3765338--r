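# Treatment-defined gene sets: per-contrast t-tests with BH control,
# the three-set Venn partition and fold-change tables.

#' Benjamini–Hochberg adjustment
#'
#' Step-up FDR adjustment across one family of p-values, returned in input
#' order. Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Per-gene differential expression for one contrast
#'
#' Two-sample t-test of each gene between a treatment condition and the
#' control on log2 expression, with Benjamini–Hochberg control across all
#' genes of the contrast. The default is the Welch test; the `"moderated"`
#' mode shrinks each gene's pooled variance toward the mean pooled
#' variance across genes with a fixed prior degree-of-freedom weight,
#' stabilising small-replicate designs.
#'
#' @param expression numeric matrix, genes x samples, log2 scale.
#' @param conditions named character vector sample -> condition covering
#'   `colnames(expression)`.
#' @param contrast length-2 character vector `c(treatment, control)`.
#' @param alpha BH significance level (default 0.05).
#' @param var_mode `"welch"` (default) or `"moderated"`.
#' @param prior_df prior degrees of freedom for the moderated mode.
#' @return Data frame with one row per gene: `gene`, `contrast`, `log2fc`,
#'   `t`, `df`, `p`, `p_adj`, `direction` (`"up"`/`"down"`; zero fold
#'   change classifies as up), `significant` (`p_adj < alpha`).
#' @export
differential_expression <- function(expression, conditions, contrast,
                                    alpha = 0.05,
                                    var_mode = c("welch", "moderated"),
                                    prior_df = 4) {
  var_mode <- match.arg(var_mode)
  if (length(contrast) != 2L)
    stop("contrast must be c(treatment, control)")
  missing <- setdiff(contrast, conditions)
  if (length(missing))
    stop("condition(s) not present: ", paste(missing, collapse = ", "))
  conditions <- conditions[colnames(expression)]
  g1 <- expression[, names(conditions)[conditions == contrast[1]],
                   drop = FALSE]
  g0 <- expression[, names(conditions)[conditions == contrast[2]],
                   drop = FALSE]
  n1 <- ncol(g1); n0 <- ncol(g0)
  if (n1 < 2L || n0 < 2L)
    stop("need >= 2 replicates per condition (got ", n1, " and ", n0, ")")

  m1 <- rowMeans(g1); m0 <- rowMeans(g0)
  v1 <- apply(g1, 1L, var); v0 <- apply(g0, 1L, var)
  fc <- m1 - m0

  if (var_mode == "welch") {
    se2 <- v1 / n1 + v0 / n0
    # epsilon fallback: noiseless but separated groups must come out
    # significant rather than 0/0
    zero <- se2 == 0
    se2[zero & fc != 0] <- 1e-24
    tstat <- ifelse(se2 > 0, fc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (pmax((v1 / n1)^2 / (n1 - 1) +
                               (v0 / n0)^2 / (n0 - 1), 1e-300)),
                 n1 + n0 - 2)
    df <- pmin(pmax(df, 1), n1 + n0 - 2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    s0 <- mean(sp2)
    shrunk <- (prior_df * s0 + (n1 + n0 - 2) * sp2) / (prior_df + n1 + n0 - 2)
    zero <- shrunk == 0
    shrunk[zero & fc != 0] <- 1e-24
    se2 <- shrunk * (1 / n1 + 1 / n0)
    tstat <- ifelse(se2 > 0, fc / sqrt(se2), 0)
    df <- rep(n1 + n0 - 2 + prior_df, length(fc))
  }
  p <- ifelse(tstat == 0 & fc == 0, 1, 2 * pt(-abs(tstat), df))
  p <- pmin(p, 1)
  p_adj <- benjamini_hochberg(p)
  data.frame(gene = rownames(expression),
             contrast = paste(contrast[1], "vs", contrast[2]),
             log2fc = fc, t = tstat, df = df, p = p, p_adj = p_adj,
             direction = ifelse(fc < 0, "down", "up"),
             significant = p_adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Three-set Venn partition of treatment-regulated gene sets
#'
#' Splits the union of the three per-treatment significant sets into the
#' seven disjoint Venn regions; the region unique to the co-treatment
#' (genes regulated by the combination but by neither factor alone) is the
#' partition's key output.
#'
#' @param setA,setB,setAB character vectors of gene ids (e.g. significant
#'   genes per contrast).
#' @param universe optional background universe; defaults to the union.
#' @return A list of class `"gene_set_collection"`: the three input sets,
#'   the seven regions (`only_A`, `only_B`, `only_AB`, `A_B`, `A_AB`,
#'   `B_AB`, `A_B_AB`) and the `universe`.
#' @export
venn_partition <- function(setA, setB, setAB, universe = NULL) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  setAB <- unique(as.character(setAB))
  all_genes <- union(union(setA, setB), setAB)
  if (is.null(universe)) universe <- all_genes
  if (!all(all_genes %in% universe))
    stop("input sets contain genes outside the universe")
  inA <- all_genes %in% setA
  inB <- all_genes %in% setB
  inAB <- all_genes %in% setAB
  region <- function(a, b, ab)
    sort(all_genes[inA == a & inB == b & inAB == ab])
  structure(list(
    sets = list(A = setA, B = setB, AB = setAB),
    regions = list(
      only_A = region(TRUE, FALSE, FALSE),
      only_B = region(FALSE, TRUE, FALSE),
      only_AB = region(FALSE, FALSE, TRUE),
      A_B = region(TRUE, TRUE, FALSE),
      A_AB = region(TRUE, FALSE, TRUE),
      B_AB = region(FALSE, TRUE, TRUE),
      A_B_AB = region(TRUE, TRUE, TRUE)),
    universe = universe
  ), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set Venn partition\n")
  cat(sprintf("  |A| = %d, |B| = %d, |AB| = %d (universe %d)\n",
              length(x$sets$A), length(x$sets$B), length(x$sets$AB),
              length(x$universe)))
  sizes <- vapply(x$regions, length, integer(1L))
  for (r in names(sizes)) cat(sprintf("  %-8s %d\n", r, sizes[[r]]))
  invisible(x)
}

#' Per-gene log2 fold change for a contrast
#'
#' Difference of condition mean log2 expression (treatment minus control).
#'
#' @inheritParams differential_expression
#' @param decreasing if TRUE (default) the result is ordered by descending
#'   fold change, ties broken lexicographically by gene id.
#' @return Named numeric vector of log2 fold changes keyed by gene id.
#' @export
fold_change_table <- function(expression, conditions, contrast,
                              decreasing = TRUE) {
  if (length(contrast) != 2L)
    stop("contrast must be c(treatment, control)")
  missing <- setdiff(contrast, conditions)
  if (length(missing))
    stop("condition(s) not present: ", paste(missing, collapse = ", "))
  conditions <- conditions[colnames(expression)]
  m1 <- rowMeans(expression[, names(conditions)[conditions == contrast[1]],
                            drop = FALSE])
  m0 <- rowMeans(expression[, names(conditions)[conditions == contrast[2]],
                            drop = FALSE])
  fc <- m1 - m0
  ord <- order(if (decreasing) -fc else fc, names(fc))
  fc[ord]
}
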