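# Two-table co-inertia analysis, built from first principles: column
# centering with uniform row weights, SVD of the weighted cross-product,
# the RV coefficient, a row-permutation test of global association, and
# per-motif over/under-representation calls.

#' Column-center a pair of tables sharing rows
#'
#' Both tables are centered column-wise under uniform row weights; the
#' centering vectors are retained so new rows can be projected onto a
#' fitted ordination.
#'
#' @param x_raw,y_raw numeric matrices (or data frames) with identical row
#'   counts and, if row names are present, identical row order (gene ids).
#' @return A list of class `"table_pair"`: centered `x`, `y`, the
#'   centering vectors, the uniform `row_weights` and the shared
#'   `gene_ids`.
#' @export
center_tables <- function(x_raw, y_raw) {
  x <- as.matrix(x_raw); storage.mode(x) <- "double"
  y <- as.matrix(y_raw); storage.mode(y) <- "double"
  if (nrow(x) != nrow(y))
    stop("tables must share the same rows (", nrow(x), " vs ", nrow(y), ")")
  ids <- rownames(x) %||% rownames(y)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (anyDuplicated(rownames(x)) || anyDuplicated(rownames(y)))
      stop("duplicated gene ids")
    if (!identical(rownames(x), rownames(y)))
      stop("tables are misaligned: row names differ or are ordered differently")
  }
  if (nrow(x) < 2L) stop("need at least 2 rows")
  cx <- colMeans(x); cy <- colMeans(y)
  structure(list(
    x = sweep(x, 2L, cx),
    y = sweep(y, 2L, cy),
    x_center = cx, y_center = cy,
    row_weights = rep(1 / nrow(x), nrow(x)),
    gene_ids = ids
  ), class = "table_pair")
}

#' Co-inertia analysis of a centered table pair
#'
#' Decomposes the weighted cross-product \eqn{Z = X^\top D Y} (with
#' \eqn{D = \mathrm{diag}(1/n)}) by singular value decomposition. Each
#' singular value is the covariance attainable by the paired axes; the
#' total co-inertia \eqn{\sum_i \lambda_i^2} is the squared co-structure
#' between the tables. Row scores are the projections of each table onto
#' its loadings.
#'
#' @param pair a `"table_pair"` from [center_tables()].
#' @param n_axes number of axes to retain (truncated to the rank of `Z`
#'   with a message if it exceeds it).
#' @return An object of class `"coinertia"`: `singular_values` (all, in
#'   decreasing order), `total_coinertia`, `x_loadings`, `y_loadings`,
#'   `x_scores`, `y_scores`, `rv` (NA when either table has zero total
#'   variance) and `n_axes`.
#' @export
coinertia <- function(pair, n_axes = 2) {
  stopifnot(inherits(pair, "table_pair"))
  n <- nrow(pair$x)
  z <- crossprod(pair$x, pair$y) / n
  sv <- svd(z)
  d <- sv$d
  rank <- sum(d > max(d[1], .Machine$double.eps) * 1e-12)
  k <- min(n_axes, max(rank, 1L))
  if (n_axes > rank)
    message("n_axes = ", n_axes, " exceeds rank ", rank,
            "; truncated to ", k)
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(u) <- list(colnames(pair$x), paste0("Axis", seq_len(k)))
  dimnames(v) <- list(colnames(pair$y), paste0("Axis", seq_len(k)))
  rv <- tryCatch(rv_coefficient(pair), error = function(e) NA_real_)
  structure(list(
    singular_values = d,
    total_coinertia = sum(d^2),
    x_loadings = u, y_loadings = v,
    x_scores = pair$x %*% u, y_scores = pair$y %*% v,
    rv = rv, n_axes = k, n = n
  ), class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat("Co-inertia analysis\n")
  cat(sprintf("  %d rows; %d x-columns, %d y-columns; %d axes retained\n",
              x$n, nrow(x$x_loadings), nrow(x$y_loadings), x$n_axes))
  cat(sprintf("  total co-inertia: %.6g;  RV coefficient: %s\n",
              x$total_coinertia,
              if (is.na(x$rv)) "NA" else sprintf("%.4f", x$rv)))
  k <- min(5L, length(x$singular_values))
  cat("  leading singular values:",
      paste(sprintf("%.4g", x$singular_values[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.coinertia <- function(object, ...) {
  lam2 <- object$singular_values^2
  out <- list(
    singular_values = object$singular_values,
    inertia = lam2,
    proportion = if (sum(lam2) > 0) lam2 / sum(lam2) else lam2,
    total_coinertia = object$total_coinertia,
    rv = object$rv)
  class(out) <- "summary.coinertia"
  out
}

#' @export
print.summary.coinertia <- function(x, ...) {
  cat("Co-inertia decomposition\n")
  k <- min(10L, length(x$singular_values))
  tab <- data.frame(axis = seq_len(k),
                    singular_value = x$singular_values[seq_len(k)],
                    inertia = x$inertia[seq_len(k)],
                    proportion = x$proportion[seq_len(k)])
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("total co-inertia %.6g, RV %s\n", x$total_coinertia,
              if (is.na(x$rv)) "NA" else sprintf("%.4f", x$rv)))
  invisible(x)
}

#' @param x a `"coinertia"` object.
#' @param axes which two axes to display.
#' @param ... passed to [plot()].
#' @describeIn coinertia plot motif (x-table) loadings on two co-inertia
#'   axes, with y-table loadings overlaid as arrows.
#' @export
plot.coinertia <- function(x, axes = c(1, 2), ...) {
  k <- x$n_axes
  if (k < 2L) {
    graphics::plot(x$x_loadings[, 1L], rep(0, nrow(x$x_loadings)),
                   xlab = "Axis1", ylab = "", main = "Co-inertia loadings",
                   ...)
    return(invisible(x))
  }
  a <- axes[1]; b <- axes[2]
  graphics::plot(x$x_loadings[, a], x$x_loadings[, b],
                 xlab = colnames(x$x_loadings)[a],
                 ylab = colnames(x$x_loadings)[b],
                 main = "Co-inertia loadings", pch = 20, col = "grey40", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::arrows(0, 0, x$y_loadings[, a], x$y_loadings[, b],
                   length = 0.08, col = "firebrick")
  graphics::text(x$y_loadings[, a], x$y_loadings[, b],
                 rownames(x$y_loadings), pos = 3, col = "firebrick",
                 cex = 0.8)
  invisible(x)
}

#' RV coefficient of a centered table pair
#'
#' Matrix correlation in \[0, 1\]:
#' \deqn{RV = \frac{\mathrm{tr}(C_{xy} C_{yx})}
#'   {\sqrt{\mathrm{tr}(C_{xx}^2)\,\mathrm{tr}(C_{yy}^2)}}}
#' with \eqn{C_{xy} = X^\top D Y} etc. Invariant to orthogonal rotation
#' and global rescaling of either table.
#'
#' @param pair a `"table_pair"`.
#' @return A single number in \[0, 1\].
#' @export
rv_coefficient <- function(pair) {
  stopifnot(inherits(pair, "table_pair"))
  n <- nrow(pair$x)
  cxx <- crossprod(pair$x) / n
  cyy <- crossprod(pair$y) / n
  cxy <- crossprod(pair$x, pair$y) / n
  denom <- sqrt(sum(cxx^2) * sum(cyy^2))
  if (denom == 0)
    stop("RV undefined: a table has zero total variance after centering")
  sum(cxy^2) / denom
}

#' Global permutation test of co-structure
#'
#' Permutes the rows of the second table uniformly at random and compares
#' the observed RV coefficient against the permutation distribution with
#' add-one smoothing: \eqn{p = (1 + \#\{RV^* \ge RV\}) / (B + 1)}.
#'
#' @param pair a `"table_pair"`.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return An object of class `"htest"` with the RV statistic and the
#'   permutation p-value.
#' @export
permutation_test_global <- function(pair, n_perm = 999, seed = 1) {
  stopifnot(inherits(pair, "table_pair"))
  if (n_perm < 99) stop("n_perm must be >= 99")
  rv_obs <- rv_coefficient(pair)
  n <- nrow(pair$x)
  cxx <- crossprod(pair$x) / n
  cyy <- crossprod(pair$y) / n
  denom <- sqrt(sum(cxx^2) * sum(cyy^2))
  rv_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- pair$y[sample.int(n), , drop = FALSE]
    sum((crossprod(pair$x, yp) / n)^2) / denom
  }, numeric(1L)))
  p <- (1 + sum(rv_perm >= rv_obs - 1e-12)) / (n_perm + 1)
  structure(list(
    statistic = c(RV = rv_obs),
    p.value = p,
    parameter = c(n_perm = n_perm, seed = seed),
    method = "RV-coefficient row-permutation test of co-structure",
    data.name = sprintf("%d x %d and %d x %d tables", n, ncol(pair$x),
                        n, ncol(pair$y))
  ), class = "htest")
}

#' Per-motif over/under-representation in a gene set
#'
#' For every motif of a binary motif/gene matrix, compares its presence
#' rate inside a gene set against the rest of the universe. The observed
#' statistic is the difference in presence rates; inference is by
#' relabelling set membership (two-sided permutation p with add-one
#' smoothing, ties counted conservatively). An exact hypergeometric tail
#' p-value in the observed direction is reported as a cross-check, and BH
#' adjustment is applied across motifs.
#'
#' @param motif_gene_matrix binary genes x motifs matrix from
#'   [build_motif_gene_matrix()].
#' @param gene_set character vector of set gene ids (non-empty, strictly
#'   inside the universe).
#' @param universe background gene ids (default all matrix rows).
#' @param n_perm number of membership permutations (default 1999).
#' @param alpha significance level for the raw permutation p (default
#'   0.05).
#' @param seed integer seed.
#' @return Data frame, one row per motif: `motif`, `stat` (presence-rate
#'   difference), `direction` (`"over"`/`"under"`), `p_perm`, `p_hyper`,
#'   `p_bh` (BH-adjusted permutation p), `significant` (raw `p_perm <
#'   alpha`), `significant_bh`.
#' @export
motif_representation <- function(motif_gene_matrix, gene_set,
                                 universe = rownames(motif_gene_matrix),
                                 n_perm = 1999, alpha = 0.05, seed = 1) {
  m <- motif_gene_matrix
  if (is.null(rownames(m))) stop("matrix must have gene row names")
  if (!all(m %in% c(0, 1)))
    stop("representation calls need a binary-mode matrix")
  if (!all(universe %in% rownames(m)))
    stop("universe genes missing from the matrix")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene set must be a subset of the universe")
  comp <- setdiff(universe, gene_set)
  if (length(gene_set) == 0L || length(comp) == 0L)
    stop("gene set and its complement must both be non-empty")

  mu <- m[universe, , drop = FALSE]
  in_set <- rownames(mu) %in% gene_set
  n1 <- sum(in_set); n2 <- length(universe) - n1
  obs <- colMeans(mu[in_set, , drop = FALSE]) -
    colMeans(mu[!in_set, , drop = FALSE])

  # vectorized permutation: random membership indicators as a matrix
  # product; stat* = S/n1 - (T - S)/n2 with S the permuted set sums
  tot <- colSums(mu)
  perm_stats <- with_seed(seed, {
    ind <- matrix(0, nrow = n_perm, ncol = nrow(mu))
    for (b in seq_len(n_perm))
      ind[b, sample.int(nrow(mu), n1)] <- 1
    s <- ind %*% mu
    s / n1 - sweep(-s, 2L, tot, `+`) / n2
  })
  tol <- 1e-12
  p_ge <- (1 + colSums(perm_stats >= rep(obs, each = n_perm) - tol)) /
    (n_perm + 1)
  p_le <- (1 + colSums(perm_stats <= rep(obs, each = n_perm) + tol)) /
    (n_perm + 1)
  p_perm <- pmin(1, 2 * pmin(p_ge, p_le))

  k <- colSums(mu[in_set, , drop = FALSE])
  p_hyper <- ifelse(obs >= 0,
                    phyper(k - 1, tot, length(universe) - tot, n1,
                           lower.tail = FALSE),
                    phyper(k, tot, length(universe) - tot, n1))

  p_bh <- benjamini_hochberg(p_perm)
  data.frame(motif = colnames(mu),
             stat = unname(obs),
             direction = ifelse(obs < 0, "under", "over"),
             p_perm = unname(p_perm),
             p_hyper = unname(p_hyper),
             p_bh = unname(p_bh),
             significant = unname(p_perm < alpha),
             significant_bh = unname(p_bh < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}
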