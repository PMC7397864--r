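#' Morphology feature effects per ASO
#'
#' For every ASO x feature combination, compares the ASO's replicate wells
#' against the NC_A control wells of the same plate: the standardized
#' effect is the mean difference divided by the control standard deviation,
#' the p-value comes from the pooled two-sample t-test, and FDR is adjusted
#' across ASOs within each feature. When the feature table contains both an
#' `eccentricity` and a `cell_count` column, each ASO is additionally
#' flagged for the spindle-loss pattern: a significant (FDR < `alpha`)
#' eccentricity decrease without a significant cell-count decrease,
#' the signature of fibroblasts losing their spindle shape while still
#' proliferating.
#'
#' @param features Data frame with columns `plate`, `role`, `aso_id` and
#'   one numeric column per morphology feature (e.g. eccentricity,
#'   compactness, radius, axis_length, cell_count).
#' @param alpha FDR threshold for the pattern flag (default 0.05).
#' @return A list with `effects` (long data frame: `aso_id`, `plate`,
#'   `feature`, `effect`, `direction`, `p_value`, `fdr`) and
#'   `spindle_loss` (data frame `aso_id`, `flag`; all-`NA` flags when the
#'   required features are absent).
#' @export
morphology_effects <- function(features, alpha = 0.05) {
  meta_cols <- intersect(c("plate", "well", "role", "aso_id"),
                         names(features))
  if (!all(c("plate", "role", "aso_id") %in% meta_cols)) {
    stop("feature table needs 'plate', 'role' and 'aso_id' columns",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(features), meta_cols)
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  if (length(feat_cols) == 0) stop("no numeric feature columns",
                                   call. = FALSE)
  if (!any(features$role == "NC_A")) {
    stop("feature table has no NC_A control rows", call. = FALSE)
  }
  ctrl <- features[features$role == "NC_A", ]
  aso_tab <- features[features$role == "ASO" & !is.na(features$aso_id), ]
  rows <- list()
  for (f in feat_cols) {
    per_aso <- lapply(split(aso_tab, aso_tab$aso_id), function(w) {
      cs <- ctrl[ctrl$plate == w$plate[1], f]
      if (length(cs) < 2) {
        stop("plate ", w$plate[1], " lacks NC_A control rows for feature ",
             f, call. = FALSE)
      }
      sdc <- stats::sd(cs)
      delta <- mean(w[[f]]) - mean(cs)
      eff <- if (sdc == 0) {
        if (delta == 0) 0 else sign(delta) * Inf
      } else {
        delta / sdc
      }
      sig <- growth_significance(w[[f]], cs)
      data.frame(aso_id = w$aso_id[1], plate = w$plate[1], feature = f,
                 effect = eff, direction = sign(delta),
                 p_value = sig$p_value, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, per_aso)
    block$fdr <- adjust_fdr(block$p_value)
    rows[[f]] <- block
  }
  effects <- do.call(rbind, rows)
  rownames(effects) <- NULL

  asos <- sort(unique(aso_tab$aso_id))
  if (all(c("eccentricity", "cell_count") %in% feat_cols)) {
    sig_down <- function(feature) {
      b <- effects[effects$feature == feature, ]
      stats::setNames(b$fdr < alpha & b$effect < 0, b$aso_id)[asos]
    }
    flag <- sig_down("eccentricity") & !sig_down("cell_count")
  } else {
    flag <- rep(NA, length(asos))
  }
  list(effects = effects,
       spindle_loss = data.frame(aso_id = asos, flag = unname(flag),
                                 stringsAsFactors = FALSE))
}
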