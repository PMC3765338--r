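# Differential expression, BH control, Venn partition and fold changes.

test_that("BH adjustment matches a hand step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(rep(0.2, 6)), rep(0.2, 6))
  set.seed(123)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_stepup(p))
    expect_true(all(adj >= p))
    expect_true(all(adj >= 0 & adj <= 1))
    # invariant under permutation of input order (modulo reordering back)
    o <- sample(length(p))
    expect_equal(benjamini_hochberg(p[o])[order(o)], adj)
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("identical groups give t = 0, p = 1, fold change 0", {
  expr <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  cond <- stats::setNames(rep(c("T", "control"), each = 3),
                          paste0("s", 1:6))
  colnames(expr) <- names(cond)
  res <- differential_expression(expr, cond, c("T", "control"))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)
})

test_that("noiseless separated groups are significant with exact log2FC", {
  expr <- rbind(g1 = c(10, 10, 10, 8, 8, 8))
  cond <- stats::setNames(rep(c("T", "control"), each = 3),
                          paste0("s", 1:6))
  colnames(expr) <- names(cond)
  res <- differential_expression(expr, cond, c("T", "control"))
  expect_equal(res$log2fc, 2)
  expect_true(res$significant)
  expect_equal(res$direction, "up")
  resm <- differential_expression(expr, cond, c("T", "control"),
                                  var_mode = "moderated")
  expect_equal(resm$log2fc, 2)
})

test_that("replicate and condition preconditions are enforced", {
  expr <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  cond <- stats::setNames(c("T", rep("control", 5)), paste0("s", 1:6))
  expect_error(differential_expression(expr, cond, c("T", "control")),
               ">= 2 replicates")
  expect_error(differential_expression(expr, cond, c("X", "control")),
               "not present")
})

test_that("planted up-regulated genes are recovered with high power", {
  flagged <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg <- study_config(n_genes = 250, n_up = 40, n_down = 0,
                        n_motifs = 0, planted_rates = list(),
                        noise_sd = 0.25, seed = seed)
    groups <- stats::setNames(
      rep(c("up_in_AB", "null"), c(40, 210)), sprintf("g%04d", 1:250))
    ex <- generate_expression(cfg, groups, seed = seed + 100)
    res <- differential_expression(ex$expression, ex$conditions,
                                   c("AB", "control"))
    flagged <- flagged + sum(res$significant[1:40] &
                               res$direction[1:40] == "up")
    total <- total + 40L
  }
  expect_gte(flagged / total, 0.9)
})

test_that("the BH false-positive fraction is controlled under the null", {
  frac <- vapply(1:50, function(seed) {
    set.seed(seed + 500)
    expr <- matrix(rnorm(300 * 6), 300, 6,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   paste0("s", 1:6)))
    cond <- stats::setNames(rep(c("T", "control"), each = 3),
                            paste0("s", 1:6))
    res <- differential_expression(expr, cond, c("T", "control"))
    mean(res$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 3 * sd(frac) / sqrt(50))
})

test_that("venn partition enumerates the seven disjoint regions", {
  v <- venn_partition(c("g1", "g2"), c("g2", "g3"), c("g2", "g3", "g4"))
  expect_equal(v$regions$only_AB, "g4")
  expect_equal(v$regions$only_A, "g1")
  expect_equal(v$regions$A_B_AB, "g2")
  expect_equal(v$regions$B_AB, "g3")
  expect_length(v$regions$A_B, 0L)

  # element conservation and disjointness
  all_members <- unlist(v$regions)
  expect_false(anyDuplicated(all_members) > 0)
  expect_setequal(all_members, union(union(v$sets$A, v$sets$B), v$sets$AB))

  v0 <- venn_partition(c("g1"), c("g1", "g2"), character())
  expect_length(v0$regions$only_AB, 0L)
  expect_length(v0$regions$A_AB, 0L)

  veq <- venn_partition(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_setequal(veq$regions$A_B_AB, c("a", "b"))
  expect_true(all(lengths(veq$regions[names(veq$regions) != "A_B_AB"]) == 0))

  expect_error(venn_partition("g1", "g2", "g3", universe = c("g1", "g2")),
               "universe")
})

test_that("fold changes equal differences of condition means, ordered", {
  expr <- rbind(g2 = c(5, 5, 4, 4), g1 = c(3, 3, 4, 4), g3 = c(9, 9, 4, 4))
  cond <- stats::setNames(rep(c("AB", "control"), each = 2),
                          paste0("s", 1:4))
  colnames(expr) <- names(cond)
  fc <- fold_change_table(expr, cond, c("AB", "control"))
  expect_equal(fc, c(g3 = 5, g2 = 1, g1 = -1))
  expect_error(fold_change_table(expr, cond, c("Z", "control")),
               "not present")
  # ties broken lexicographically by gene id
  expr2 <- rbind(gb = c(1, 1, 0, 0), ga = c(1, 1, 0, 0))
  colnames(expr2) <- names(cond)
  expect_equal(names(fold_change_table(expr2, cond, c("AB", "control"))),
               c("ga", "gb"))
})

test_that("fold changes recover the planted effect on average", {
  cfg <- study_config(n_genes = 300, n_up = 200, n_down = 0,
                      n_motifs = 0, planted_rates = list(), seed = 9)
  groups <- stats::setNames(rep(c("up_in_AB", "null"), c(200, 100)),
                            sprintf("g%04d", 1:300))
  ex <- generate_expression(cfg, groups, seed = 10)
  fc <- fold_change_table(ex$expression, ex$conditions, c("AB", "control"))
  expect_equal(mean(fc[names(groups)[groups == "up_in_AB"]]), 2,
               tolerance = 0.05)
})
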