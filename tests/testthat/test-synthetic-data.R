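# Synthetic-study generator: determinism, planted structure, base
# composition and expression effects.

test_that("PWM library generation respects size, width and information", {
  lib <- generate_pwm_library(8, length_range = c(6, 10),
                              information_range = c(0.8, 1.6), seed = 11)
  expect_length(lib, 8L)
  expect_false(anyDuplicated(vapply(lib, `[[`, "", "id")) > 0)
  for (p in lib) {
    expect_true(p$width >= 6 && p$width <= 10)
    expect_equal(unname(colSums(p$mat)), rep(1, p$width), tolerance = 1e-9)
    ic <- mean(pwm_information(p))
    expect_gte(ic, 0.8 - 0.05)
    expect_lte(ic, 1.6 + 0.05)
  }
})

test_that("maximum-information motifs are pure consensus columns", {
  lib <- generate_pwm_library(1, length_range = c(4, 4),
                              information_range = c(2, 2), seed = 5)
  freq <- sweep(lib[[1]]$counts, 2L, colSums(lib[[1]]$counts), `/`)
  expect_equal(unname(apply(freq, 2L, max)), rep(1, 4))
})

test_that("the emulated motif-library scale (1236 matrices) is supported", {
  lib <- generate_pwm_library(1236, seed = 2)
  expect_length(lib, 1236L)
  expect_false(anyDuplicated(names(lib)) > 0)
})

test_that("library generation is seed-deterministic and range-validated", {
  a <- generate_pwm_library(4, seed = 3)
  b <- generate_pwm_library(4, seed = 3)
  expect_identical(a, b)
  expect_error(generate_pwm_library(0), "n_motifs")
  expect_error(generate_pwm_library(2, length_range = c(2, 10)), "4, 30")
  expect_error(generate_pwm_library(2, information_range = c(1, 3)),
               "information_range")
})

test_that("promoter base composition converges to the GC parameter", {
  pr <- generate_promoters(paste0("g", 1:200), 5000, gc_content = 0.5,
                           seed = 21)
  expect_length(pr, 200L)
  expect_true(all(nchar(pr) == 5000L))
  pooled <- paste(pr, collapse = "")
  gc <- (lengths(regmatches(pooled, gregexpr("[GC]", pooled)))) /
    nchar(pooled)
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
})

test_that("promoter generation validates inputs and handles length 1", {
  expect_error(generate_promoters(c("a", "a"), 10), "duplicate")
  expect_error(generate_promoters("a", 0), "length")
  expect_error(generate_promoters("a", 10, gc_content = 1), "gc_content")
  one <- generate_promoters("a", 1, gc_content = 0.5, seed = 1)
  expect_match(unname(one), "^[ACGT]$")
})

test_that("planting at rate 1 leaves a rescannable site in every target", {
  pr <- generate_promoters(paste0("g", 1:30), 300, seed = 31)
  pwm <- hard_pwm("TTGACGTCAGCT")
  res <- plant_motifs(pr, pwm, names(pr), rate = 1, seed = 32)
  expect_equal(nrow(res$occurrences), 30L)
  for (g in names(pr))
    expect_gte(count_sites(pwm, res$promoters[[g]], threshold = 0.85), 1L)
  # occurrences recorded at the planted position, fully inside the promoter
  expect_true(all(res$occurrences$start >= 0))
  expect_true(all(res$occurrences$start + pwm$width <= 300))
  planted <- substr(res$promoters[res$occurrences$gene],
                    res$occurrences$start + 1,
                    res$occurrences$start + pwm$width)
  expect_equal(unname(planted), res$occurrences$site)
})

test_that("planting at rate 0 is a no-op and rate ~ binomial bounds hold", {
  pr <- generate_promoters(paste0("g", 1:200), 300, seed = 41)
  pwm <- hard_pwm("TTGACGTCAGCT")
  res0 <- plant_motifs(pr, pwm, names(pr), rate = 0, seed = 42)
  expect_identical(res0$promoters, pr)
  expect_equal(nrow(res0$occurrences), 0L)
  res5 <- plant_motifs(pr, pwm, names(pr), rate = 0.5, seed = 43)
  # central 99.9% interval of Binomial(200, 0.5)
  expect_gte(nrow(res5$occurrences), 77L)
  expect_lte(nrow(res5$occurrences), 123L)
})

test_that("planting rejects motifs that do not fit", {
  pr <- c(g1 = "ACGTACGT")
  expect_error(plant_motifs(pr, hard_pwm("TTGACGTCAGCT"), "g1", 1),
               "does not fit")
})

test_that("expression effects and noise behave as configured", {
  cfg <- study_config(n_genes = 400, n_up = 200, n_down = 0,
                      noise_sd = 0.25, seed = 51)
  groups <- stats::setNames(rep(c("up_in_AB", "null"), each = 200),
                            sprintf("g%04d", 1:400))
  ex <- generate_expression(cfg, groups, seed = 52)
  fc <- rowMeans(ex$expression[, ex$conditions == "AB"]) -
    rowMeans(ex$expression[, ex$conditions == "control"])
  expect_equal(mean(fc[1:200]), 2, tolerance = 0.05)
  expect_equal(mean(fc[201:400]), 0, tolerance = 0.05)

  cfg0 <- study_config(n_genes = 10, n_up = 2, n_down = 2, noise_sd = 0,
                       seed = 53)
  groups0 <- stats::setNames(rep("null", 10), sprintf("g%04d", 1:10))
  ex0 <- generate_expression(cfg0, groups0, seed = 54)
  ab <- ex0$expression[, ex0$conditions == "AB"]
  expect_true(all(ab[, 1] == ab[, 2] & ab[, 2] == ab[, 3]))
})

test_that("generate_study composes a consistent, deterministic bundle", {
  cfg <- small_study_config(seed = 61)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  s3 <- generate_study(small_study_config(seed = 62))
  expect_false(identical(s1$promoters_long, s3$promoters_long))

  expect_true(all(nchar(s1$promoters_long) == cfg$promoter_length_long))
  expect_true(all(nchar(s1$promoters_short) == cfg$promoter_length_short))
  # the short window is the TSS-proximal end of the long window
  expect_identical(unname(s1$promoters_short),
                   unname(substr(s1$promoters_long,
                                 cfg$promoter_length_long -
                                   cfg$promoter_length_short + 1,
                                 cfg$promoter_length_long)))
  # groups partition the genes
  expect_setequal(names(s1$truth$groups), rownames(s1$expression))
  expect_equal(sum(s1$truth$groups == "up_in_AB"), cfg$n_up)
  expect_equal(sum(s1$truth$groups == "down_in_AB"), cfg$n_down)
  # planted occurrences lie inside the short window of the long promoter
  occ <- s1$truth$occurrences
  expect_true(all(occ$start >= cfg$promoter_length_long -
                    cfg$promoter_length_short))
  w <- vapply(s1$pwms[occ$motif], `[[`, numeric(1), "width")
  expect_true(all(occ$start + w <= cfg$promoter_length_long))
  # actin tag spans every gene group and is recoverable from the annotation
  actin <- subset_by_go(rownames(s1$expression), s1$annotation, "actin")
  expect_setequal(actin, s1$truth$actin_genes)
  expect_setequal(unique(s1$truth$groups[s1$truth$actin_genes]),
                  c("up_in_AB", "down_in_AB", "null"))
})

test_that("the analysis consumes only observed study components", {
  study <- generate_study(small_study_config(seed = 71))
  study$truth <- NULL
  an <- suppressMessages(analyze_study(study, n_perm = 199,
                                       n_perm_global = 99, seed = 1))
  expect_s3_class(an, "signature_analysis")
})

test_that("study configuration invariants are enforced", {
  expect_error(study_config(n_replicates = 1), "n_replicates")
  expect_error(study_config(gc_content = 0), "gc_content")
  expect_error(study_config(n_genes = 100, n_up = 80, n_down = 30),
               "exceeds")
  expect_error(study_config(planted_rates = list(
    e2f1_like = list(group = "up_in_AB", target = 1.2, background = 0))),
    "rates")
})
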