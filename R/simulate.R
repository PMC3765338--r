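# Synthetic-study generator: promoters with planted motif occurrences,
# a four-condition expression matrix with planted effects, a decoy motif
# library and a GO-style annotation table, all determined by one seed.
# This is the ground-truth test bed for the analysis stages; the truth
# object it returns is never consumed by them.

#' Configuration of a synthetic promoter/expression study
#'
#' Defaults mirror the emulated study design: four treatment states
#' (control, A, B and the co-treatment AB, standing for control, TGF-beta,
#' CCN2 and both together), three replicate arrays per condition, 500 bp
#' and 5000 bp upstream promoter windows, 100 genes up- and 100 genes
#' down-regulated in the co-treatment by 2 log2 units over noise of sd
#' 0.25, an E2F1-like motif planted in the up group and a CREB-like motif
#' in the down group at rate 0.8 against a 0.1 background rate, 50 decoy
#' motifs, and a fifth of genes tagged with an "actin" annotation term.
#'
#' @param n_genes number of genes.
#' @param conditions ordered condition labels; the first is the control.
#' @param n_replicates replicates per condition (>= 2).
#' @param promoter_length_short,promoter_length_long upstream window sizes
#'   in bp; the short window is the TSS-proximal end of the long one.
#' @param gc_content background GC fraction in (0, 1).
#' @param n_motifs number of decoy motifs in the library.
#' @param n_up,n_down sizes of the up- and down-regulated gene groups.
#' @param effect_log2fc named list: gene group -> named vector of per-
#'   condition log2 effects.
#' @param planted_rates named list: motif id -> list(group, target,
#'   background) giving planting probabilities inside and outside the
#'   group; rates in \[0, 1\].
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log2 expression.
#' @param noise_sd replicate noise sd (log2 units).
#' @param actin_fraction fraction of genes tagged with the actin term,
#'   allocated across all gene groups.
#' @param seed integer seed that fully determines the study.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_genes = 1000,
                         conditions = c("control", "A", "B", "AB"),
                         n_replicates = 3,
                         promoter_length_short = 500,
                         promoter_length_long = 5000,
                         gc_content = 0.45,
                         n_motifs = 50,
                         n_up = 100, n_down = 100,
                         effect_log2fc = list(
                           up_in_AB = c(AB = 2),
                           down_in_AB = c(AB = -2)),
                         planted_rates = list(
                           e2f1_like = list(group = "up_in_AB",
                                            target = 0.8, background = 0.1),
                           creb_like = list(group = "down_in_AB",
                                            target = 0.8, background = 0.1)),
                         baseline_mean = 8, baseline_sd = 1.5,
                         noise_sd = 0.25,
                         actin_fraction = 0.2,
                         seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), conditions = conditions,
              n_replicates = as.integer(n_replicates),
              promoter_length_short = as.integer(promoter_length_short),
              promoter_length_long = as.integer(promoter_length_long),
              gc_content = gc_content, n_motifs = as.integer(n_motifs),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              effect_log2fc = effect_log2fc, planted_rates = planted_rates,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, actin_fraction = actin_fraction,
              seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("n_genes must be positive")
    if (length(conditions) < 2 || anyDuplicated(conditions))
      stop("need >= 2 distinct condition labels")
    if (n_replicates < 2) stop("n_replicates must be >= 2")
    if (promoter_length_short < 1 || promoter_length_long < promoter_length_short)
      stop("promoter windows must satisfy 1 <= short <= long")
    if (gc_content <= 0 || gc_content >= 1)
      stop("gc_content must lie strictly in (0, 1)")
    if (n_up + n_down > n_genes)
      stop("n_up + n_down exceeds n_genes")
    if (noise_sd < 0 || baseline_sd < 0) stop("sds must be non-negative")
    if (actin_fraction < 0 || actin_fraction > 1)
      stop("actin_fraction must lie in [0, 1]")
    for (m in names(planted_rates)) {
      pr <- planted_rates[[m]]
      if (!all(c("group", "target", "background") %in% names(pr)))
        stop("planted_rates entries need group, target, background")
      if (pr$target < 0 || pr$target > 1 ||
          pr$background < 0 || pr$background > 1)
        stop("planting rates must lie in [0, 1]")
    }
    for (g in names(effect_log2fc)) {
      eff <- effect_log2fc[[g]]
      if (!all(names(eff) %in% conditions))
        stop("effect_log2fc names must be condition labels")
    }
  })
  invisible(cfg)
}

# Information content (bits, uniform background) of a column with one
# dominant base at frequency p and the rest split evenly.
ic_of_dominance <- function(p) {
  if (p >= 1) return(2)
  q <- (1 - p) / 3
  2 + p * log2(p) + ifelse(q > 0, 3 * q * log2(q), 0)
}

dominance_for_ic <- function(ic) {
  if (ic >= 2) return(1)
  if (ic <= 0) return(0.25)
  stats::uniroot(function(p) ic_of_dominance(p) - ic,
                 lower = 0.25 + 1e-9, upper = 1 - 1e-12,
                 tol = 1e-10)$root
}

#' Generate a library of random position weight matrices
#'
#' Each motif has a width drawn uniformly from `length_range` and, per
#' column, one dominant base whose frequency is tuned so that the column's
#' information content matches a draw from `information_range` (bits,
#' uniform background). Counts are expressed out of 1000 per column so the
#' library round-trips exactly through PFM text.
#'
#' @param n_motifs library size (>= 1).
#' @param length_range integer bounds for the motif width, within \[4, 30\].
#' @param information_range per-column information-content bounds in bits,
#'   within \[0, 2\].
#' @param seed integer seed.
#' @param prefix id prefix; motifs are named `<prefix>_001`, ...
#' @param pseudocount passed to [normalize_pfm()].
#' @return Named list of `"pwm"` objects with distinct ids.
#' @export
generate_pwm_library <- function(n_motifs, length_range = c(6, 12),
                                 information_range = c(0.8, 1.6),
                                 seed = 1, prefix = "decoy",
                                 pseudocount = 0.8) {
  if (n_motifs < 1) stop("n_motifs must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 4L || length_range[2] > 30L)
    stop("length_range must be increasing and within [4, 30]")
  if (information_range[1] > information_range[2] ||
      information_range[1] < 0 || information_range[2] > 2)
    stop("information_range must be increasing and within [0, 2]")

  with_seed(seed, {
    lapply(stats::setNames(seq_len(n_motifs),
                           sprintf("%s_%03d", prefix, seq_len(n_motifs))),
           function(i) {
      W <- if (length_range[1] == length_range[2]) length_range[1] else
        sample(seq(length_range[1], length_range[2]), 1L)
      counts <- vapply(seq_len(W), function(j) {
        ic <- runif(1L, information_range[1], information_range[2])
        p <- dominance_for_ic(ic)
        main <- round(1000 * p)
        rest <- 1000 - main
        others <- rep(rest %/% 3, 3L)
        extra <- rest - 3 * (rest %/% 3)
        if (extra > 0) others[seq_len(extra)] <- others[seq_len(extra)] + 1L
        dom <- sample(4L, 1L)
        out <- numeric(4L)
        out[dom] <- main
        out[setdiff(seq_len(4L), dom)] <- sample(others)
        out
      }, numeric(4L))
      rownames(counts) <- DNA_BASES
      normalize_pfm(counts, pseudocount = pseudocount,
                    id = sprintf("%s_%03d", prefix, i))
    })
  })
}

#' Generate background promoter sequences
#'
#' I.i.d. base model with a GC-content parameter: per position, C and G
#' each occur with probability `gc_content / 2`, A and T with
#' `(1 - gc_content) / 2`.
#'
#' @param gene_ids unique gene identifiers.
#' @param length promoter length in bp (>= 1).
#' @param gc_content GC fraction in (0, 1).
#' @param seed integer seed.
#' @return Named character vector of sequences.
#' @export
generate_promoters <- function(gene_ids, length, gc_content = 0.45,
                               seed = 1) {
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length < 1) stop("promoter length must be >= 1")
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie strictly in (0, 1)")
  n <- base::length(gene_ids)
  probs <- c((1 - gc_content) / 2, gc_content / 2,
             gc_content / 2, (1 - gc_content) / 2)
  with_seed(seed, {
    bases <- sample(DNA_BASES, n * length, replace = TRUE, prob = probs)
    m <- matrix(bases, nrow = n, byrow = TRUE)
    seqs <- apply(m, 1L, paste0, collapse = "")
    stats::setNames(seqs, gene_ids)
  })
}

#' Plant sampled motif occurrences into promoters
#'
#' Each target gene independently receives, with probability `rate`, one
#' site sampled base-by-base from the motif's count frequencies, written
#' over the existing bases (promoter length is preserved) at a uniformly
#' random admissible start. Non-target genes are untouched by the call;
#' call repeatedly for multi-motif designs.
#'
#' @param promoters named character vector.
#' @param pwm a `"pwm"` object; its width must not exceed the plantable
#'   region.
#' @param target_genes subset of `names(promoters)` eligible for planting.
#' @param rate planting probability per target gene, in \[0, 1\].
#' @param seed integer seed.
#' @param region optional 0-based half-open `(start, end)` window within
#'   the promoter to plant into; default the whole promoter.
#' @return List with `promoters` (modified vector) and `occurrences`
#'   (data frame: gene, motif, start, strand, site).
#' @export
plant_motifs <- function(promoters, pwm, target_genes, rate, seed = 1,
                         region = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!all(target_genes %in% names(promoters)))
    stop("target genes absent from promoters")
  W <- pwm$width
  freq <- sweep(pwm$counts, 2L, colSums(pwm$counts), `/`)
  occ <- list()
  with_seed(seed, {
    for (g in target_genes) {
      L <- nchar(promoters[[g]])
      reg <- if (is.null(region)) c(0L, L) else as.integer(region)
      if (reg[1] < 0 || reg[2] > L || reg[2] - reg[1] < W)
        stop("motif (width ", W, ") does not fit in the plantable region ",
             "of gene ", g)
      if (runif(1L) >= rate) next
      site <- paste(vapply(seq_len(W), function(j)
        sample(DNA_BASES, 1L, prob = freq[, j]), character(1L)),
        collapse = "")
      start <- reg[1] + sample.int(reg[2] - reg[1] - W + 1L, 1L) - 1L
      s <- promoters[[g]]
      substr(s, start + 1L, start + W) <- site
      promoters[[g]] <- s
      occ[[base::length(occ) + 1L]] <- data.frame(
        gene = g, motif = pwm$id, start = start, strand = "+",
        site = site, stringsAsFactors = FALSE)
    }
    occurrences <- if (base::length(occ)) do.call(rbind, occ) else
      data.frame(gene = character(), motif = character(),
                 start = integer(), strand = character(),
                 site = character(), stringsAsFactors = FALSE)
    list(promoters = promoters, occurrences = occurrences)
  })
}

#' Simulate the expression matrix of a study
#'
#' Per-gene baseline (normal) plus the group's per-condition log2 effect
#' plus i.i.d. Gaussian replicate noise, on the log2 scale.
#'
#' @param config a [study_config()].
#' @param groups named character vector gene -> group label (groups absent
#'   from `config$effect_log2fc` get no effect).
#' @param seed integer seed (defaults to a stream derived from the config
#'   seed).
#' @return List with `expression` (genes x samples matrix, columns named
#'   `<condition>_<replicate>`) and `conditions` (named sample ->
#'   condition vector).
#' @export
generate_expression <- function(config, groups,
                                seed = child_seed(config$seed, 7L)) {
  validate_study_config(config)
  genes <- names(groups)
  n <- length(genes)
  samples <- as.vector(t(outer(config$conditions,
                               seq_len(config$n_replicates),
                               function(c, r) paste(c, r, sep = "_"))))
  cond_of <- rep(config$conditions, each = config$n_replicates)
  effect <- matrix(0, nrow = n, ncol = length(samples),
                   dimnames = list(genes, samples))
  for (grp in names(config$effect_log2fc)) {
    eff <- config$effect_log2fc[[grp]]
    rows <- which(groups == grp)
    for (cond in names(eff))
      effect[rows, cond_of == cond] <- eff[[cond]]
  }
  with_seed(seed, {
    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    noise <- matrix(rnorm(n * length(samples), 0, config$noise_sd),
                    nrow = n)
    mat <- baseline + effect + noise
    dimnames(mat) <- list(genes, samples)
    list(expression = mat,
         conditions = stats::setNames(cond_of, samples))
  })
}

#' Generate a complete synthetic study
#'
#' One-call bundle: long and short promoter windows (the short window is
#' the TSS-proximal end of the long one), a motif library (synthetic
#' CREB-like and E2F1-like focal motifs plus decoys), planted motif
#' occurrences, a four-condition expression matrix and an annotation table
#' tagging a stratified fraction of genes with an actin term. Focal sites
#' are planted inside the short window so that both window classes carry
#' them. The `truth` element records the planted structure and is intended
#' only for validation, never as an analysis input.
#'
#' @param config a [study_config()].
#' @return A list of class `"promoter_study"` with elements `config`,
#'   `promoters_long`, `promoters_short`, `pwms`, `expression`,
#'   `conditions`, `annotation` and `truth`.
#' @export
generate_study <- function(config = study_config()) {
  validate_study_config(config)
  seed <- config$seed
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  groups <- stats::setNames(rep("null", config$n_genes), genes)
  if (config$n_up > 0) groups[seq_len(config$n_up)] <- "up_in_AB"
  if (config$n_down > 0)
    groups[config$n_up + seq_len(config$n_down)] <- "down_in_AB"

  long <- generate_promoters(genes, config$promoter_length_long,
                             config$gc_content,
                             seed = child_seed(seed, 1L))
  decoys <- if (config$n_motifs > 0)
    generate_pwm_library(config$n_motifs, seed = child_seed(seed, 2L))
  else list()
  pwms <- c(focal_pwms(), decoys)

  # plant focal motifs inside the short (TSS-proximal) window of the long
  # promoter so the 500 bp and 5000 bp analyses both see them
  region <- c(config$promoter_length_long - config$promoter_length_short,
              config$promoter_length_long)
  occurrences <- list()
  k <- 10L
  for (m in names(config$planted_rates)) {
    pr <- config$planted_rates[[m]]
    if (is.null(pwms[[m]]))
      stop("planted motif '", m, "' is not in the library")
    target <- genes[groups == pr$group]
    rest <- setdiff(genes, target)
    res <- plant_motifs(long, pwms[[m]], target, pr$target,
                        seed = child_seed(seed, k), region = region)
    long <- res$promoters
    occurrences[[length(occurrences) + 1L]] <- res$occurrences
    res <- plant_motifs(long, pwms[[m]], rest, pr$background,
                        seed = child_seed(seed, k + 1L), region = region)
    long <- res$promoters
    occurrences[[length(occurrences) + 1L]] <- res$occurrences
    k <- k + 2L
  }
  occurrences <- do.call(rbind, c(occurrences, list(
    data.frame(gene = character(), motif = character(), start = integer(),
               strand = character(), site = character(),
               stringsAsFactors = FALSE))))

  short <- stats::setNames(substr(
    long, config$promoter_length_long - config$promoter_length_short + 1L,
    config$promoter_length_long), genes)

  expr <- generate_expression(config, groups,
                              seed = child_seed(seed, 7L))

  # annotation: allocate the actin tag across every gene group so the
  # annotated subset spans up, down and null genes
  other_terms <- c("protein kinase activity", "DNA binding",
                   "membrane transport", "cell cycle",
                   "oxidoreductase activity", "RNA splicing",
                   "ion channel activity", "proteolysis")
  actin_genes <- with_seed(child_seed(seed, 8L), {
    unlist(lapply(unique(groups), function(grp) {
      g <- genes[groups == grp]
      kk <- round(config$actin_fraction * length(g))
      if (kk > 0) sample(g, kk) else character()
    }), use.names = FALSE)
  })
  annotation <- with_seed(child_seed(seed, 9L), data.frame(
    gene = genes,
    term = ifelse(genes %in% actin_genes,
                  "actin cytoskeleton organization",
                  sample(other_terms, length(genes), replace = TRUE)),
    stringsAsFactors = FALSE))

  structure(list(
    config = config,
    promoters_long = long,
    promoters_short = short,
    pwms = pwms,
    expression = expr$expression,
    conditions = expr$conditions,
    annotation = annotation,
    truth = list(groups = groups, occurrences = occurrences,
                 actin_genes = sort(actin_genes))
  ), class = "promoter_study")
}

#' @export
print.promoter_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic promoter/expression study\n")
  cat(sprintf("  %d genes, conditions %s x %d replicates (seed %d)\n",
              cfg$n_genes, paste(cfg$conditions, collapse = "/"),
              cfg$n_replicates, cfg$seed))
  cat(sprintf("  promoter windows: %d bp and %d bp; %d motifs (%d focal)\n",
              cfg$promoter_length_short, cfg$promoter_length_long,
              length(x$pwms), length(x$pwms) - cfg$n_motifs))
  cat(sprintf("  planted occurrences: %d; actin-tagged genes: %d\n",
              nrow(x$truth$occurrences), length(x$truth$actin_genes)))
  invisible(x)
}

#' Write all study components to disk
#'
#' Promoters as FASTA (one file per window class), the motif library as
#' JASPAR-style PFM text, expression and sample-condition map as TSV,
#' annotation as TSV and the planted truth as JSON.
#'
#' @param study a `"promoter_study"`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "promoter_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    promoters_short = file.path(dir, "promoters_500bp.fasta"),
    promoters_long = file.path(dir, "promoters_5000bp.fasta"),
    motifs = file.path(dir, "motifs.pfm"),
    expression = file.path(dir, "expression.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(study$promoters_short, paths[["promoters_short"]])
  write_fasta(study$promoters_long, paths[["promoters_long"]])
  write_pfm(study$pwms, paths[["motifs"]])
  write_expression(study$expression, study$conditions,
                   paths[["expression"]], paths[["conditions"]])
  write_annotation(study$annotation, paths[["annotation"]])
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
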