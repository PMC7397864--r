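#' Scale an expression matrix to tags per million
#'
#' Each sample (column) is rescaled so its total expression is 1e6,
#' the CAGE tags-per-million convention. Already-normalized columns are
#' unchanged.
#'
#' @param expression Nonnegative gene x sample matrix.
#' @return Matrix of the same shape with every column summing to 1e6.
#' @export
normalize_tpm <- function(expression) {
  if (any(expression < 0)) stop("expression must be nonnegative",
                                call. = FALSE)
  cs <- colSums(expression)
  if (any(cs == 0)) {
    bad <- colnames(expression)[cs == 0]
    stop("sample(s) with zero total expression: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(expression, 2, cs / 1e6, "/")
}

#' Differential expression of one knockdown against matched controls
#'
#' Control-anchored per-gene comparison on `log2(TPM + pseudocount)`: the
#' log2 fold change is the mean over knockdown samples minus the mean over
#' control samples; the p-value is a two-sided normal test of that
#' difference using the gene-wise control variance, floored at the
#' `var_floor_quantile` quantile of all control variances so that genes
#' with accidentally tiny control variance cannot dominate; FDR is
#' Benjamini-Hochberg across genes.
#'
#' @param expression TPM-normalized gene x sample matrix.
#' @param kd_samples Column names of the knockdown samples (>= 1).
#' @param control_samples Column names of the matched negative-control
#'   samples (>= 2).
#' @param pseudocount Pseudocount in TPM units added before log2
#'   (default 1).
#' @param var_floor_quantile Quantile of control variances used as the
#'   variance floor (default 0.1).
#' @param gene_var Optional precomputed gene-wise control variance vector
#'   (one value per gene, already floored); by default the variance is
#'   estimated from `control_samples`. [molecular_phenotype()] passes a
#'   variance pooled across all plates' control libraries, which is far
#'   more stable than 6 samples per plate allow.
#' @return Data frame with one row per gene: `gene`, `log2fc`, `p_value`,
#'   `fdr`.
#' @export
differential_expression <- function(expression, kd_samples, control_samples,
                                    pseudocount = 1,
                                    var_floor_quantile = 0.1,
                                    gene_var = NULL) {
  if (length(kd_samples) < 1 || length(control_samples) < 2) {
    stop("need >= 1 knockdown and >= 2 control samples", call. = FALSE)
  }
  missing <- setdiff(c(kd_samples, control_samples), colnames(expression))
  if (length(missing) > 0) {
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  L <- log2(expression[, c(kd_samples, control_samples), drop = FALSE] +
              pseudocount)
  nk <- length(kd_samples)
  nc <- length(control_samples)
  mk <- rowMeans(L[, seq_len(nk), drop = FALSE])
  Lc <- L[, nk + seq_len(nc), drop = FALSE]
  mc <- rowMeans(Lc)
  if (is.null(gene_var)) {
    v <- rowSums((Lc - mc)^2) / (nc - 1)
    v <- pmax(v, stats::quantile(v, var_floor_quantile))
  } else {
    if (length(gene_var) != nrow(expression)) {
      stop("gene_var must have one value per gene", call. = FALSE)
    }
    v <- gene_var
  }
  lfc <- mk - mc
  se <- sqrt(v * (1 / nk + 1 / nc))
  p <- ifelse(se == 0, as.numeric(lfc == 0),
              2 * stats::pnorm(-abs(lfc / se)))
  data.frame(gene = rownames(expression), log2fc = lfc, p_value = p,
             fdr = adjust_fdr(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Scale log2 fold changes of each gene across the whole experiment
#'
#' Standardizes each gene's fold change across all ASO experiments:
#' `z = (fc - mean) / sd`, with the sample (n - 1) standard deviation.
#' Genes with zero spread get `z = 0`. This experiment-wide Z-score is the
#' second gate of the DEG definition and makes responses comparable across
#' ASOs with different global effect sizes.
#'
#' @param log2fc Gene x experiment matrix of log2 fold changes
#'   (>= 3 experiments).
#' @return Matrix of Z-scores with the same dimensions.
#' @export
scale_changes <- function(log2fc) {
  if (ncol(log2fc) < 3) {
    stop("need at least 3 ASO experiments to scale changes", call. = FALSE)
  }
  mu <- rowMeans(log2fc)
  s <- sqrt(rowSums((log2fc - mu)^2) / (ncol(log2fc) - 1))
  z <- (log2fc - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Signed DEG call from the three gating statistics
#'
#' A gene is called up-regulated (+1) when `fdr < fdr_threshold`,
#' `z > z_threshold` and `log2fc > lfc_threshold`; down-regulated (-1) when
#' all three are mirrored; 0 otherwise. Defaults are the screen thresholds
#' FDR < 0.05, |Z| > 1.645, |log2FC| > 0.5.
#'
#' @param log2fc,z,fdr Numeric vectors of equal length.
#' @param fdr_threshold,z_threshold,lfc_threshold Gate thresholds.
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
call_degs <- function(log2fc, z, fdr, fdr_threshold = 0.05,
                      z_threshold = 1.645, lfc_threshold = 0.5) {
  up <- fdr < fdr_threshold & z > z_threshold & log2fc > lfc_threshold
  dn <- fdr < fdr_threshold & z < -z_threshold & log2fc < -lfc_threshold
  as.integer(up) - as.integer(dn)
}

#' Molecular phenotype of every ASO experiment
#'
#' Runs the per-ASO differential-expression stage for a whole screen:
#' TPM-normalizes the expression matrix, contrasts each ASO's knockdown
#' samples against the NC_A control samples of the same plate/run, scales
#' each gene's fold change across all experiments into Z-scores, and calls
#' signed DEGs with the three-gate rule.
#'
#' @param expression Nonnegative gene x sample matrix.
#' @param sample_sheet Data frame mapping samples to ASOs: columns
#'   `sample_id`, `aso_id`, `target_id`, `plate`, `is_control`.
#' @param asos ASOs to analyse (default: all non-control ASOs in the
#'   sheet).
#' @param pseudocount,var_floor_quantile Passed to
#'   [differential_expression()].
#' @param fdr_threshold,z_threshold,lfc_threshold DEG gates, see
#'   [call_degs()].
#' @return An object of class `molecular_phenotype`: a list with gene x ASO
#'   matrices `log2fc`, `p`, `fdr`, `z`, `calls`, plus `asos` and the
#'   thresholds used.
#' @export
molecular_phenotype <- function(expression, sample_sheet, asos = NULL,
                                pseudocount = 1, var_floor_quantile = 0.1,
                                fdr_threshold = 0.05, z_threshold = 1.645,
                                lfc_threshold = 0.5) {
  required <- c("sample_id", "aso_id", "plate", "is_control")
  if (!all(required %in% names(sample_sheet))) {
    stop("sample sheet must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(sample_sheet$sample_id, colnames(expression))
  if (length(missing) > 0) {
    stop("sample sheet rows missing from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  tpm <- normalize_tpm(expression)
  if (is.null(asos)) {
    asos <- unique(sample_sheet$aso_id[!sample_sheet$is_control])
  }
  asos <- asos[asos %in% sample_sheet$aso_id]
  if (length(asos) < 3) {
    stop("need at least 3 ASO experiments", call. = FALSE)
  }
  ctrl_by_plate <- split(
    sample_sheet$sample_id[sample_sheet$is_control],
    sample_sheet$plate[sample_sheet$is_control])
  ## gene-wise control variance pooled across all plates (within-plate
  ## centered): stable where 6 libraries per plate are not, floored so
  ## low-variance genes cannot dominate
  Lc_all <- log2(tpm[, unlist(ctrl_by_plate, use.names = FALSE),
                     drop = FALSE] + pseudocount)
  ss <- 0
  df <- 0
  for (ctrl in ctrl_by_plate) {
    block <- Lc_all[, ctrl, drop = FALSE]
    ss <- ss + rowSums((block - rowMeans(block))^2)
    df <- df + length(ctrl) - 1
  }
  gene_var <- ss / df
  gene_var <- pmax(gene_var, stats::quantile(gene_var, var_floor_quantile))
  res <- lapply(asos, function(a) {
    rows <- sample_sheet[!sample_sheet$is_control &
                           sample_sheet$aso_id == a, ]
    ctrl <- ctrl_by_plate[[as.character(rows$plate[1])]]
    if (is.null(ctrl) || length(ctrl) < 2) {
      stop("plate ", rows$plate[1], " has fewer than 2 control libraries",
           call. = FALSE)
    }
    differential_expression(tpm, rows$sample_id, ctrl,
                            pseudocount = pseudocount,
                            var_floor_quantile = var_floor_quantile,
                            gene_var = gene_var)
  })
  genes <- rownames(expression)
  grab <- function(col) {
    m <- vapply(res, function(d) d[[col]], numeric(length(genes)))
    dimnames(m) <- list(genes, asos)
    m
  }
  lfc <- grab("log2fc")
  p <- grab("p_value")
  fdr <- grab("fdr")
  z <- scale_changes(lfc)
  calls <- matrix(0L, nrow(lfc), ncol(lfc), dimnames = dimnames(lfc))
  for (j in seq_len(ncol(lfc))) {
    calls[, j] <- call_degs(lfc[, j], z[, j], fdr[, j],
                            fdr_threshold, z_threshold, lfc_threshold)
  }
  structure(list(log2fc = lfc, p = p, fdr = fdr, z = z, calls = calls,
                 asos = asos,
                 thresholds = c(fdr = fdr_threshold, z = z_threshold,
                                log2fc = lfc_threshold)),
            class = "molecular_phenotype")
}

#' @export
print.molecular_phenotype <- function(x, ...) {
  cat(sprintf("Molecular phenotype: %d genes x %d ASO experiments\n",
              nrow(x$log2fc), ncol(x$log2fc)))
  cat(sprintf("  DEGs per ASO: median %d (thresholds: FDR < %.3g, |Z| > %.3g, |log2FC| > %.3g)\n",
              stats::median(colSums(x$calls != 0)), x$thresholds["fdr"],
              x$thresholds["z"], x$thresholds["log2fc"]))
  invisible(x)
}

#' Signed DEG sets per ASO
#'
#' Converts a gene x ASO call matrix (entries in `{-1, 0, 1}`) into one
#' signed membership set per ASO, encoding each DEG as `"gene|+"` or
#' `"gene|-"`. Sign-aware sets make the Jaccard concordance statistic count
#' only genes responding in the same direction.
#'
#' @param calls Gene x ASO integer matrix from [molecular_phenotype()].
#' @return Named list of character vectors, one per ASO.
#' @export
deg_sets <- function(calls) {
  out <- lapply(seq_len(ncol(calls)), function(j) {
    nz <- calls[, j] != 0
    paste0(rownames(calls)[nz], ifelse(calls[nz, j] > 0, "|+", "|-"))
  })
  names(out) <- colnames(calls)
  out
}

#' Response of divergent partner genes to lncRNA knockdown
#'
#' Many targeted lncRNAs share a bidirectional promoter with a
#' protein-coding partner gene. This summarizes the partner's measured
#' log2 fold change in every ASO experiment targeting the mapped lncRNA
#' and reports the screen-wide median of |log2FC|; partners absent from
#' the expression universe are recorded as missing and excluded from the
#' median.
#'
#' @param mp A [molecular_phenotype()] object.
#' @param target_map Data frame `aso_id`, `target_id` for the analysed
#'   ASOs.
#' @param partner_map Data frame `target_id`, `partner_gene`.
#' @return List with `per_aso` (data frame `aso_id`, `target_id`,
#'   `partner_gene`, `log2fc`, `fdr`, `missing`) and
#'   `median_abs_log2fc` (`NA` when no partner is measurable).
#' @export
divergent_partner_response <- function(mp, target_map, partner_map) {
  if (nrow(partner_map) == 0) {
    return(list(per_aso = data.frame(), median_abs_log2fc = NA_real_))
  }
  pm <- stats::setNames(partner_map$partner_gene, partner_map$target_id)
  rows <- target_map[target_map$target_id %in% names(pm) &
                       target_map$aso_id %in% colnames(mp$log2fc), ]
  if (nrow(rows) == 0) {
    return(list(per_aso = data.frame(), median_abs_log2fc = NA_real_))
  }
  per_aso <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    g <- pm[[rows$target_id[i]]]
    present <- g %in% rownames(mp$log2fc)
    data.frame(aso_id = rows$aso_id[i], target_id = rows$target_id[i],
               partner_gene = g,
               log2fc = if (present) mp$log2fc[g, rows$aso_id[i]] else NA,
               fdr = if (present) mp$fdr[g, rows$aso_id[i]] else NA,
               missing = !present, stringsAsFactors = FALSE)
  }))
  med <- if (all(per_aso$missing)) NA_real_ else
    stats::median(abs(per_aso$log2fc), na.rm = TRUE)
  list(per_aso = per_aso, median_abs_log2fc = med)
}
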