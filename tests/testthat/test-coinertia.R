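# Co-inertia analysis, RV coefficient, permutation inference and
# representation calls.

test_that("centering subtracts column means and is idempotent", {
  x <- cbind(a = c(1, 0, 1, 0), b = c(2, 2, 2, 2))
  y <- cbind(c = 1:4)
  rownames(x) <- rownames(y) <- paste0("g", 1:4)
  pair <- center_tables(x, y)
  expect_equal(unname(pair$x[, "a"]), c(0.5, -0.5, 0.5, -0.5))
  expect_equal(unname(pair$x[, "b"]), rep(0, 4))
  expect_equal(unname(colSums(pair$x)), c(0, 0), tolerance = 1e-9)
  pair2 <- center_tables(pair$x, pair$y)
  expect_equal(pair2$x, pair$x, tolerance = 1e-12)

  y_bad <- y[c(2, 1, 3, 4), , drop = FALSE]
  expect_error(center_tables(x, y_bad), "misaligned")
  expect_error(center_tables(x, y[1:3, , drop = FALSE]), "same rows")
})

test_that("self-coupling recovers the PCA eigenvalues and RV = 1", {
  set.seed(31)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("g", 1:10), NULL))
  pair <- center_tables(x, x)
  fit <- suppressMessages(coinertia(pair, n_axes = 4))
  ev <- eigen(crossprod(pair$x) / nrow(x), symmetric = TRUE)$values
  expect_equal(fit$singular_values, ev, tolerance = 1e-10)
  expect_equal(fit$rv, 1, tolerance = 1e-12)
  expect_equal(rv_coefficient(pair), 1, tolerance = 1e-12)
})

test_that("a constant y column yields zero total co-inertia", {
  set.seed(32)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("g", 1:10), NULL))
  y <- matrix(1, 10, 1, dimnames = list(paste0("g", 1:10), NULL))
  fit <- suppressMessages(coinertia(center_tables(x, y)))
  expect_equal(fit$total_coinertia, 0, tolerance = 1e-12)
  expect_error(rv_coefficient(center_tables(x, y)), "zero total variance")
})

test_that("singular values match a dense brute-force decomposition", {
  set.seed(33)
  for (i in 1:5) {
    x <- matrix(rnorm(10 * 4), 10, 4)
    y <- matrix(rnorm(10 * 3), 10, 3)
    rownames(x) <- rownames(y) <- paste0("g", 1:10)
    fit <- suppressMessages(coinertia(center_tables(x, y), n_axes = 3))
    expect_equal(fit$singular_values, bf_coinertia_singular(x, y),
                 tolerance = 1e-8)
    expect_equal(fit$total_coinertia, sum(fit$singular_values^2),
                 tolerance = 1e-8)
  }
})

test_that("RV is invariant to rotation and scaling moves co-inertia by c^2", {
  set.seed(34)
  x <- matrix(rnorm(60), 12, 5)
  y <- matrix(rnorm(36), 12, 3)
  rownames(x) <- rownames(y) <- paste0("g", 1:12)
  pair <- center_tables(x, y)
  rv0 <- rv_coefficient(pair)
  total0 <- suppressMessages(coinertia(pair))$total_coinertia

  r <- random_orthogonal(5)
  pair_rot <- center_tables(x %*% r, y)
  expect_lt(abs(rv_coefficient(pair_rot) - rv0), 1e-9)
  # RV(X, X R) = 1 for orthogonal R
  expect_equal(rv_coefficient(center_tables(x, x %*% r)), 1,
               tolerance = 1e-9)

  pair_sc <- center_tables(3 * x, y)
  expect_lt(abs(rv_coefficient(pair_sc) - rv0), 1e-12)
  expect_equal(suppressMessages(coinertia(pair_sc))$total_coinertia,
               9 * total0, tolerance = 1e-8)
})

test_that("RV of independent high-dimensional tables is near zero", {
  rvs <- vapply(1:20, function(seed) {
    set.seed(seed + 300)
    x <- matrix(rnorm(1000 * 5), 1000, 5)
    y <- matrix(rnorm(1000 * 5), 1000, 5)
    rownames(x) <- rownames(y) <- paste0("g", 1:1000)
    rv_coefficient(center_tables(x, y))
  }, numeric(1))
  expect_true(all(rvs < 0.05))
})

test_that("the global permutation test is seeded and exact at RV = 1", {
  set.seed(35)
  x <- matrix(rnorm(48), 12, 4, dimnames = list(paste0("g", 1:12), NULL))
  pair <- center_tables(x, x)
  t1 <- permutation_test_global(pair, n_perm = 999, seed = 5)
  t2 <- permutation_test_global(pair, n_perm = 999, seed = 5)
  expect_identical(t1$p.value, t2$p.value)
  # no row permutation of a generic table can reach RV = 1
  expect_equal(t1$p.value, 1 / 1000)
  expect_error(permutation_test_global(pair, n_perm = 50), "99")
})

test_that("representation calls match the exact hypergeometric tail", {
  genes <- paste0("g", 1:20)
  present <- c(paste0("g", 1:8), paste0("g", 11:12))
  m <- matrix(as.numeric(genes %in% present), ncol = 1,
              dimnames = list(genes, "m1"))
  set_genes <- paste0("g", 1:10)
  res <- motif_representation(m, set_genes, n_perm = 1999, seed = 3)
  expect_equal(res$direction, "over")
  expect_equal(res$stat, 0.8 - 0.2)
  expect_equal(res$p_hyper, 2126 / 184756, tolerance = 1e-12)
  expect_lt(res$p_perm, 0.05)
  # the permutation p is close to the doubled exact tail
  expect_equal(res$p_perm, min(1, 2 * 2126 / 184756), tolerance = 0.5)
})

test_that("a motif present everywhere is non-discriminative", {
  genes <- paste0("g", 1:12)
  m <- matrix(1, 12, 1, dimnames = list(genes, "m1"))
  res <- motif_representation(m, genes[1:6], n_perm = 199, seed = 1)
  expect_equal(res$stat, 0)
  expect_equal(res$p_perm, 1)
  expect_equal(res$p_hyper, 1)
})

test_that("representation input contracts are enforced", {
  genes <- paste0("g", 1:10)
  m <- matrix(rbinom(20, 1, 0.5), 10, 2,
              dimnames = list(genes, c("m1", "m2")))
  expect_error(motif_representation(m, genes), "non-empty")
  expect_error(motif_representation(m, character()), "non-empty")
  expect_error(motif_representation(m, "gX"), "subset")
  mc <- m; mc[1, 1] <- 3
  expect_error(motif_representation(mc, genes[1:5]), "binary")
})

test_that("permutation and hypergeometric decisions usually agree", {
  set.seed(36)
  m <- matrix(rbinom(40 * 30, 1, runif(30, 0.1, 0.6)), nrow = 40,
              byrow = TRUE, dimnames = list(paste0("g", 1:40),
                                            paste0("m", 1:30)))
  res <- motif_representation(m, paste0("g", 1:15), n_perm = 2000,
                              seed = 7)
  agree <- (res$p_perm < 0.05) == (pmin(1, 2 * res$p_hyper) < 0.05)
  expect_gte(mean(agree), 0.95)
})
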