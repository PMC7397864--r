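#' Run the full screen analysis pipeline
#'
#' Binds all stages end to end on a screen (either a
#' [simulate_screen()] object or a directory written by
#' [write_screen()]):
#'
#' 1. knockdown QC: per-ASO success and targets with at least
#'    `min_asos_per_target` successful ASOs;
#' 2. growth: plate-truncated slopes, normalized rates, pooled t-tests
#'    against plate NC_A controls, BH FDR, significant-inhibition flags;
#' 3. lncRNA-level hit calling with conditional cutoffs against the
#'    screen's own empirical background;
#' 4. global growth-concordance permutation test;
#' 5. molecular phenotype: per-ASO differential expression, experiment-wide
#'    Z-scores, signed DEG calls;
#' 6. pair concordance (Jaccard against nontargeting pairs) and the
#'    reproducible-pair filter;
#' 7. optional motif activities (ridge MARA) and their growth correlation;
#' 8. optional preranked GSEA per ASO (ranking by DE Z-score), the signed
#'    score matrix, and pathway-growth correlations;
#' 9. optional morphology feature effects.
#'
#' @param screen A `synthetic_screen` object or a directory path.
#' @param outdir Optional output directory; when given, stage outputs are
#'   written as TSV/JSON with seed- and configuration-stamped headers.
#' @param seed Integer seed governing every permutation stage.
#' @param n_perm Permutations for the concordance tests (default 10000).
#' @param gsea_n_perm Permutations per GSEA ranking (default 1000).
#' @param fdr_threshold,lfc_threshold,z_threshold DEG gates.
#' @param min_common_degs,alpha Reproducible-pair gates; `alpha` is also
#'   the conditional-cutoff background level.
#' @param min_asos_per_target Successful ASOs required to assess a target
#'   (default 2).
#' @param run_mara,run_gsea,run_morphology Stage switches.
#' @return A list of stage results plus a `summary` list of headline
#'   counts.
#' @export
run_pipeline <- function(screen, outdir = NULL, seed = 1,
                         n_perm = 10000, gsea_n_perm = 1000,
                         fdr_threshold = 0.05, lfc_threshold = 0.5,
                         z_threshold = 1.645, min_common_degs = 5,
                         alpha = 0.05, min_asos_per_target = 2,
                         run_mara = TRUE, run_gsea = TRUE,
                         run_morphology = TRUE) {
  if (is.character(screen)) screen <- read_screen(screen)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## 1. knockdown QC
  kd_success <- stage("kd_qc", kd_success_table(screen$kd))
  ok_targets <- successful_targets(kd_success, min_asos_per_target)
  target_map <- kd_success[kd_success$success &
                             kd_success$target_id %in% ok_targets,
                           c("aso_id", "target_id")]

  ## 2. growth phenotype
  growth <- stage("growth", analyze_growth(screen$confluence,
                                           fdr_threshold = fdr_threshold))

  ## 3. conditional-cutoff hit calling
  hits <- stage("hit_calling",
                call_lncrna_hits(growth, target_map, alpha = alpha))

  ## 4. global growth concordance
  rates <- stats::setNames(growth$normalized_rate, growth$aso_id)
  rates <- rates[names(rates) %in% target_map$aso_id]
  concordance <- stage("growth_concordance",
                       global_growth_concordance(rates, target_map,
                                                 n_perm = n_perm,
                                                 seed = seed,
                                                 exhaustive = FALSE))

  ## 5. molecular phenotype for successful ASOs with expression data
  expr_asos <- intersect(target_map$aso_id,
                         screen$sample_sheet$aso_id)
  mp <- stage("molecular_phenotype",
              molecular_phenotype(screen$expression, screen$sample_sheet,
                                  asos = expr_asos,
                                  fdr_threshold = fdr_threshold,
                                  z_threshold = z_threshold,
                                  lfc_threshold = lfc_threshold))
  sets <- deg_sets(mp$calls)

  ## 6. pair concordance and reproducible pairs
  pairs <- stage("pair_concordance",
                 pair_concordance_test(sets, target_map,
                                       n_null_pairs = n_perm, seed = seed))
  reproducible <- reproducible_pairs(pairs, min_common = min_common_degs,
                                     alpha = alpha)

  ## 7. motif activities
  mara <- NULL
  motif_growth <- NULL
  if (run_mara && !is.null(screen$site_counts)) {
    mara <- stage("mara", {
      tpm <- normalize_tpm(screen$expression)
      fit_motif_activities(log2(tpm + 1), screen$site_counts)
    })
    aso_act <- average_columns_by(mara$activities,
                                  screen$sample_sheet$aso_id[
                                    match(colnames(mara$activities),
                                          screen$sample_sheet$sample_id)])
    motif_growth <- tryCatch(
      motif_growth_correlation(aso_act, rates),
      error = function(e) NULL)
  }

  ## 8. preranked GSEA per ASO on DE Z-scores
  gsea <- NULL
  pathway_growth <- NULL
  if (run_gsea && !is.null(screen$gene_sets)) {
    gsea <- stage("gsea", {
      lapply(stats::setNames(mp$asos, mp$asos), function(a) {
        preranked_gsea(mp$z[, a], screen$gene_sets,
                       n_perm = gsea_n_perm, seed = seed)
      })
    })
    score_mat <- vapply(gsea, function(d) d$signed_score,
                        numeric(nrow(gsea[[1]])))
    rownames(score_mat) <- gsea[[1]]$set
    score_mat <- score_mat[stats::complete.cases(score_mat), ,
                           drop = FALSE]
    pathway_growth <- tryCatch(
      pathway_growth_correlation(score_mat, rates),
      error = function(e) NULL)
  }

  ## 9. morphology
  morphology <- NULL
  if (run_morphology && !is.null(screen$morphology)) {
    morphology <- stage("morphology",
                        morphology_effects(screen$morphology,
                                           alpha = alpha))
  }

  summary <- list(
    n_asos = nrow(kd_success),
    n_successful_asos = sum(kd_success$success),
    n_targets_assessed = length(ok_targets),
    n_significant_asos = sum(growth$significant_inhibition),
    n_hit_lncrnas = sum(hits$is_hit),
    hit_fraction = if (nrow(hits) > 0) mean(hits$is_hit) else NA_real_,
    growth_concordance_p = concordance$p_value,
    n_reproducible_pairs = nrow(reproducible),
    n_reproducible_targets = length(attr(reproducible, "targets")),
    seed = seed
  )

  result <- list(kd_success = kd_success, target_map = target_map,
                 growth = growth, hits = hits,
                 growth_concordance = concordance,
                 molecular = mp, pairs = pairs,
                 reproducible_pairs = reproducible,
                 mara = mara, motif_growth = motif_growth,
                 gsea = gsea, pathway_growth = pathway_growth,
                 morphology = morphology, summary = summary)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    meta <- c(seed = as.character(seed),
              config_hash = if (!is.null(screen$config))
                config_hash(screen$config) else "external",
              fdr_threshold = as.character(fdr_threshold),
              lfc_threshold = as.character(lfc_threshold),
              z_threshold = as.character(z_threshold))
    write_tsv(kd_success, file.path(outdir, "kd_success.tsv"), meta)
    write_tsv(growth, file.path(outdir, "growth_results.tsv"), meta)
    write_tsv(hits, file.path(outdir, "lncrna_hits.tsv"), meta)
    write_tsv(pairs, file.path(outdir, "pair_concordance.tsv"), meta)
    write_tsv(matrix_to_df(mp$log2fc, "gene"),
              file.path(outdir, "log2fc_matrix.tsv"), meta)
    write_tsv(matrix_to_df(mp$z, "gene"),
              file.path(outdir, "zscore_matrix.tsv"), meta)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

average_columns_by <- function(mat, groups) {
  keep <- !is.na(groups)
  mat <- mat[, keep, drop = FALSE]
  groups <- groups[keep]
  out <- vapply(split(seq_along(groups), groups), function(i) {
    rowMeans(mat[, i, drop = FALSE])
  }, numeric(nrow(mat)))
  rownames(out) <- rownames(mat)
  out
}
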