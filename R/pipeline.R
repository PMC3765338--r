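# End-to-end pipeline: differential expression -> gene sets -> motif/gene
# matrix -> co-inertia + representation calls -> focal-TFBS
# stratification, with a file-based runner that records a hashed manifest.

#' Run the full signature analysis on an in-memory study
#'
#' Executes every analysis stage on the components of a study bundle
#' (observed data only; the planted truth of a synthetic study is never
#' read):
#' \enumerate{
#'   \item per-treatment differential expression versus control (BH at
#'     `alpha`);
#'   \item the three-set Venn partition of significant gene sets and the
#'     up/down split of the co-treatment contrast;
#'   \item the binary motif/gene matrix over short promoter windows;
#'   \item co-inertia of the motif matrix against gene-set membership
#'     indicators (up/down) with the RV permutation test, plus per-motif
#'     representation calls of the up-set against the regulated-gene
#'     universe (up and down sets pooled);
#'   \item focal-site stratification over the annotation-term subset in
#'     long promoter windows.
#' }
#'
#' @param study a `"promoter_study"` (or any list with the same observed
#'   components: `expression`, `conditions`, `promoters_short`,
#'   `promoters_long`, `pwms`, `annotation`, `config`).
#' @param threshold relative-score scan threshold (default 0.85).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations for representation/stratification tests
#'   (default 1999).
#' @param n_perm_global permutations for the global RV test (default 499).
#' @param go_term annotation term for the stratified subset (default
#'   `"actin"`).
#' @param focal ids of the focal motifs counted in the long window
#'   (default `c("creb_like", "e2f1_like")`, intersected with the
#'   library).
#' @param seed integer seed driving all permutation tests.
#' @return A list of class `"signature_analysis"`: `de` (per-contrast
#'   results), `venn`, `up_set`, `down_set`, `motif_matrix`, `cia`,
#'   `global_test`, `representation`, `fold_changes`, `stratification`
#'   (NULL when the design lacks the needed sets) and `params`.
#' @export
analyze_study <- function(study, threshold = 0.85, alpha = 0.05,
                          n_perm = 1999, n_perm_global = 499,
                          go_term = "actin",
                          focal = c("creb_like", "e2f1_like"),
                          seed = 1) {
  conds <- study$config$conditions
  control <- conds[1L]
  treatments <- setdiff(conds, control)

  de <- lapply(stats::setNames(treatments, treatments), function(tr)
    differential_expression(study$expression, study$conditions,
                            c(tr, control), alpha = alpha))
  sig <- lapply(de, function(d) d$gene[d$significant])

  venn <- if (length(treatments) >= 3L)
    venn_partition(sig[[1L]], sig[[2L]], sig[[3L]],
                   universe = rownames(study$expression))
  else NULL

  ab <- treatments[length(treatments)]
  de_ab <- de[[ab]]
  up_set <- de_ab$gene[de_ab$significant & de_ab$direction == "up"]
  down_set <- de_ab$gene[de_ab$significant & de_ab$direction == "down"]

  mgm <- build_motif_gene_matrix(study$promoters_short, study$pwms,
                                 threshold = threshold, mode = "binary")

  cia <- NULL; global_test <- NULL; representation <- NULL
  regulated <- intersect(rownames(mgm), union(up_set, down_set))
  if (length(intersect(up_set, regulated)) > 0L &&
      length(intersect(down_set, regulated)) > 0L) {
    y <- cbind(up = as.numeric(regulated %in% up_set),
               down = as.numeric(regulated %in% down_set))
    rownames(y) <- regulated
    pair <- center_tables(mgm[regulated, , drop = FALSE], y)
    cia <- coinertia(pair, n_axes = 2)
    global_test <- permutation_test_global(pair, n_perm = n_perm_global,
                                           seed = child_seed(seed, 31L))
    representation <- motif_representation(
      mgm, gene_set = intersect(up_set, regulated), universe = regulated,
      n_perm = n_perm, alpha = alpha, seed = child_seed(seed, 32L))
  }

  fc <- fold_change_table(study$expression, study$conditions,
                          c(ab, control))

  stratification <- NULL
  focal <- intersect(focal, names(study$pwms))
  subset <- subset_by_go(rownames(study$expression), study$annotation,
                         go_term)
  if (length(focal) && length(subset) >= 6L) {
    counts <- count_focal_sites(subset, study$promoters_long,
                                study$pwms[focal], threshold = threshold)
    stratification <- tryCatch(
      stratify(counts, fc, n_perm = n_perm, alpha = alpha,
               seed = child_seed(seed, 33L)),
      error = function(e) {
        warning("stratification skipped: ", conditionMessage(e))
        NULL
      })
  }

  structure(list(
    de = de, venn = venn, up_set = up_set, down_set = down_set,
    motif_matrix = mgm, cia = cia, global_test = global_test,
    representation = representation, fold_changes = fc,
    stratification = stratification,
    params = list(threshold = threshold, alpha = alpha, n_perm = n_perm,
                  n_perm_global = n_perm_global, go_term = go_term,
                  focal = focal, seed = seed, control = control,
                  co_treatment = ab)
  ), class = "signature_analysis")
}

#' @export
print.signature_analysis <- function(x, ...) {
  cat("Promoter regulatory-signature analysis\n")
  for (tr in names(x$de)) {
    d <- x$de[[tr]]
    cat(sprintf("  %s vs %s: %d significant genes (BH < %.2g)\n",
                tr, x$params$control, sum(d$significant), x$params$alpha))
  }
  if (!is.null(x$venn))
    cat(sprintf("  unique to co-treatment: %d genes\n",
                length(x$venn$regions$only_AB)))
  cat(sprintf("  motif/gene matrix: %d genes x %d motifs (threshold %.2f)\n",
              nrow(x$motif_matrix), ncol(x$motif_matrix),
              x$params$threshold))
  if (!is.null(x$cia))
    cat(sprintf("  co-inertia RV = %.4f (global permutation p = %.4g)\n",
                x$cia$rv, x$global_test$p.value))
  if (!is.null(x$representation)) {
    r <- x$representation
    cat(sprintf("  representation calls (up vs down universe): %d over, %d under at p < %.2g\n",
                sum(r$significant & r$direction == "over"),
                sum(r$significant & r$direction == "under"),
                x$params$alpha))
  }
  if (!is.null(x$stratification)) {
    s <- x$stratification$stats
    for (i in seq_len(nrow(s)))
      cat(sprintf("  stratification %s: rho = %+.3f (p = %.4g)\n",
                  s$motif[i], s$rho[i], s$p_rho[i]))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects stage parameters and input/output paths for [run_pipeline()].
#' When `study_config` is supplied the pipeline simulates its own inputs;
#' otherwise the four input paths must point to existing files.
#'
#' @param out_dir output directory.
#' @param study_config optional [study_config()] for simulated input.
#' @param expression,conditions,promoters_short,promoters_long,motifs,annotation
#'   input file paths (ignored when simulating).
#' @param threshold,alpha,n_perm,n_perm_global,go_term,focal,seed stage
#'   parameters as in [analyze_study()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, study_config = NULL,
                            expression = NULL, conditions = NULL,
                            promoters_short = NULL, promoters_long = NULL,
                            motifs = NULL, annotation = NULL,
                            threshold = 0.85, alpha = 0.05,
                            n_perm = 1999, n_perm_global = 499,
                            go_term = "actin",
                            focal = c("creb_like", "e2f1_like"),
                            seed = 1) {
  cfg <- list(out_dir = out_dir, study_config = study_config,
              inputs = list(expression = expression,
                            conditions = conditions,
                            promoters_short = promoters_short,
                            promoters_long = promoters_long,
                            motifs = motifs, annotation = annotation),
              threshold = threshold, alpha = alpha, n_perm = n_perm,
              n_perm_global = n_perm_global, go_term = go_term,
              focal = focal, seed = as.integer(seed))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(study_config)) {
    paths <- unlist(cfg$inputs)
    if (length(paths) < 6L || any(!nzchar(paths)))
      stop("without a study_config, all six input paths are required")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  } else {
    validate_study_config(study_config)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the file-based pipeline
#'
#' Simulates (or reads) the inputs, runs [analyze_study()], writes every
#' stage output as plain text under `out_dir` and returns a manifest with
#' an MD5 hash per file. Re-running with the same configuration and seed
#' reproduces identical hashes. Inputs are never modified.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the `analysis`, the written `manifest`
#'   (data frame: file, md5) and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$study_config)) {
    study <- generate_study(config$study_config)
    write_study(study, file.path(config$out_dir, "simulated_input"))
  } else {
    ex <- read_expression(config$inputs$expression,
                          config$inputs$conditions)
    conds <- unique(unname(ex$conditions))
    study <- list(
      expression = ex$expression, conditions = ex$conditions,
      promoters_short = read_fasta(config$inputs$promoters_short),
      promoters_long = read_fasta(config$inputs$promoters_long),
      pwms = read_pfm(config$inputs$motifs),
      annotation = read_annotation(config$inputs$annotation),
      config = list(conditions = conds))
  }

  analysis <- analyze_study(study, threshold = config$threshold,
                            alpha = config$alpha, n_perm = config$n_perm,
                            n_perm_global = config$n_perm_global,
                            go_term = config$go_term,
                            focal = config$focal, seed = config$seed)

  out <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out[[length(out) + 1L]] <<- path
  }
  for (tr in names(analysis$de))
    emit(analysis$de[[tr]], sprintf("de_%s.tsv", tr))
  if (!is.null(analysis$venn)) {
    venn_df <- do.call(rbind, lapply(names(analysis$venn$regions),
      function(r) if (length(analysis$venn$regions[[r]]))
        data.frame(region = r, gene = analysis$venn$regions[[r]],
                   stringsAsFactors = FALSE) else NULL))
    emit(venn_df %||%
           data.frame(region = character(), gene = character()),
         "venn_regions.tsv")
  }
  emit(data.frame(gene = rownames(analysis$motif_matrix),
                  analysis$motif_matrix, check.names = FALSE),
       "motif_gene_matrix.tsv")
  if (!is.null(analysis$representation))
    emit(analysis$representation, "representation_calls.tsv")
  if (!is.null(analysis$cia)) {
    emit(data.frame(motif = rownames(analysis$cia$x_loadings),
                    analysis$cia$x_loadings, check.names = FALSE),
         "cia_motif_loadings.tsv")
    cia_path <- file.path(config$out_dir, "cia_summary.json")
    jsonlite::write_json(list(
      singular_values = analysis$cia$singular_values,
      total_coinertia = analysis$cia$total_coinertia,
      rv = analysis$cia$rv,
      global_p = analysis$global_test$p.value,
      n_perm_global = config$n_perm_global), cia_path,
      auto_unbox = TRUE, digits = NA)
    out[[length(out) + 1L]] <- cia_path
  }
  emit(data.frame(gene = names(analysis$fold_changes),
                  log2fc = unname(analysis$fold_changes)),
       "fold_changes.tsv")
  if (!is.null(analysis$stratification)) {
    emit(analysis$stratification$table, "stratification_table.tsv")
    emit(analysis$stratification$stats, "stratification_stats.tsv")
  }

  manifest <- data.frame(file = basename(unlist(out)),
                         md5 = unname(tools::md5sum(unlist(out))),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(analysis = analysis, manifest = manifest,
                 manifest_path = manifest_path))
}
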