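# Independent oracles used to validate the implementation paths.

# Naive per-position, per-strand PWM re-scorer. Recomputes log-odds from
# the frequency matrix and scores every window (and the reverse
# complement of every window) one at a time with base R.
naive_scan <- function(pwm, sequence, threshold, both_strands = TRUE) {
  bg <- pwm$background
  lo <- log2(sweep(pwm$mat, 1L, bg, `/`))
  lo5 <- rbind(lo, N = 0)
  W <- ncol(lo)
  mx <- sum(apply(lo, 2L, max))
  mn <- sum(apply(lo, 2L, min))
  span <- mx - mn
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  rc_char <- function(v) rev(c(A = "T", C = "G", G = "C", T = "A",
                               N = "N")[v])
  rows <- list()
  if (L >= W) {
    for (st in 0:(L - W)) {
      win <- chars[(st + 1):(st + W)]
      raw <- sum(lo5[cbind(match(win, c("A", "C", "G", "T", "N")),
                           seq_len(W))])
      rel <- if (span > 0) (raw - mn) / span else 1
      if (rel >= threshold - 1e-9)
        rows[[length(rows) + 1L]] <- list(start = st, strand = "+",
                                          raw = raw, relative = rel)
      if (both_strands) {
        rcw <- rc_char(win)
        raw <- sum(lo5[cbind(match(rcw, c("A", "C", "G", "T", "N")),
                             seq_len(W))])
        rel <- if (span > 0) (raw - mn) / span else 1
        if (rel >= threshold - 1e-9)
          rows[[length(rows) + 1L]] <- list(start = st, strand = "-",
                                            raw = raw, relative = rel)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), strand = character(),
                      raw = numeric(), relative = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hand-written Benjamini-Hochberg step-up: p(i) * n / i, then cumulative
# minimum from the largest rank, mapped back to input order.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force co-inertia singular values: dense weighted cross-product and
# an eigendecomposition of Z'Z (independent of svd()).
bf_coinertia_singular <- function(x_raw, y_raw) {
  x <- sweep(as.matrix(x_raw), 2L, colMeans(x_raw))
  y <- sweep(as.matrix(y_raw), 2L, colMeans(y_raw))
  n <- nrow(x)
  d <- diag(rep(1 / n, n))
  z <- t(x) %*% d %*% y
  ev <- eigen(t(z) %*% z, symmetric = TRUE)$values
  sv <- sort(sqrt(pmax(ev, 0)), decreasing = TRUE)
  sv[seq_len(min(ncol(x), ncol(y)))]
}

reverse_complement_test <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Random orthogonal matrix via QR of a Gaussian matrix.
random_orthogonal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}
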