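#' Fit motif activities by ridge-penalized least squares
#'
#' Minimal motif activity response analysis: log2 expression is modelled as
#' `E[p, s] = c_p + m_s + sum_m N'[p, m] * A[m, s]`, where `N'` is the
#' column-centered promoter x motif site-count matrix and `A` are the
#' per-sample motif activities. After double-centering `E` (removing
#' promoter and sample means), the activities solve the ridge system
#' `(N'^T N' + lambda I) A = N'^T E~`. Standard errors come from the ridge
#' covariance with per-sample residual variance, and `z = A / se`.
#'
#' When `lambda` is `NULL` it is chosen by generalized cross-validation
#' over a log-spaced grid. Because each activity column solves against a
#' row-centered response, every motif's activities sum to ~0 across
#' samples (relative activities).
#'
#' @param expression Promoter/gene x sample matrix of log2 expression
#'   (same row universe as `site_counts`).
#' @param site_counts Nonnegative promoter/gene x motif count matrix.
#' @param lambda Ridge penalty (>= 0), or `NULL` for GCV selection.
#' @param lambda_grid Candidate penalties for GCV.
#' @return Object of class `mara_fit`: list with motif x sample matrices
#'   `activities`, `se`, `z`, the `lambda` used, the effective degrees of
#'   freedom `df`, and the GCV curve (when selected).
#' @export
fit_motif_activities <- function(expression, site_counts, lambda = NULL,
                                 lambda_grid = 10^seq(-3, 3,
                                                      length.out = 25)) {
  if (nrow(expression) != nrow(site_counts) ||
      !identical(rownames(expression), rownames(site_counts))) {
    stop("expression and site_counts must share the same promoter rows",
         call. = FALSE)
  }
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0",
                                           call. = FALSE)
  P <- nrow(expression)
  S <- ncol(expression)
  M <- ncol(site_counts)
  Ec <- expression - rowMeans(expression)
  Ec <- sweep(Ec, 2, colMeans(Ec))
  Nc <- sweep(site_counts, 2, colMeans(site_counts))
  sv <- svd(Nc)
  d <- sv$d
  rank_ok <- M <= P && min(d) > max(d) * 1e-10
  if (!is.null(lambda) && lambda == 0 && !rank_ok) {
    stop("site-count matrix is rank deficient; use lambda > 0",
         call. = FALSE)
  }
  Tm <- crossprod(sv$u, Ec)              # r x S
  gcv <- NULL
  if (is.null(lambda)) {
    ss_tot <- sum(Ec^2)
    ss_fit <- rowSums(Tm^2)              # per singular direction
    gcv <- vapply(lambda_grid, function(l) {
      s <- d^2 / (d^2 + l)
      rss <- ss_tot - sum(ss_fit) + sum((1 - s)^2 * ss_fit)
      edf <- sum(s)
      rss / (P - edf)^2
    }, numeric(1))
    lambda <- lambda_grid[which.min(gcv)]
    names(gcv) <- signif(lambda_grid, 3)
  }
  shrink <- d / (d^2 + lambda)
  A <- sv$v %*% (shrink * Tm)
  dimnames(A) <- list(colnames(site_counts), colnames(expression))
  edf <- sum(d^2 / (d^2 + lambda))
  resid <- Ec - Nc %*% A
  sigma2 <- colSums(resid^2) / max(P - edf, 1)
  hdiag <- as.vector(sv$v^2 %*% (d^2 / (d^2 + lambda)^2))
  se <- sqrt(outer(hdiag, sigma2))
  dimnames(se) <- dimnames(A)
  z <- A / ifelse(se == 0, 1, se)
  structure(list(activities = A, se = se, z = z, lambda = lambda,
                 df = edf, gcv = gcv),
            class = "mara_fit")
}

#' @export
print.mara_fit <- function(x, ...) {
  cat(sprintf("Motif activity fit: %d motifs x %d samples (lambda = %.4g, edf = %.1f)\n",
              nrow(x$activities), ncol(x$activities), x$lambda, x$df))
  invisible(x)
}

.correlate_rows <- function(mat, rates, min_n = 10, what = "row") {
  shared <- intersect(colnames(mat), names(rates))
  if (length(shared) < min_n) {
    stop("need at least ", min_n, " shared samples", call. = FALSE)
  }
  mat <- mat[, shared, drop = FALSE]
  r <- rates[shared]
  keep <- apply(mat, 1, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " ", what,
            "(s) with zero variance excluded from correlation")
  }
  res <- do.call(rbind, lapply(rownames(mat)[keep], function(m) {
    ct <- stats::cor.test(mat[m, ], r, method = "pearson")
    data.frame(name = m, r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(data.frame(name = character(0), r = numeric(0),
                                      p_value = numeric(0),
                                      fdr = numeric(0)))
  res$fdr <- adjust_fdr(res$p_value)
  rownames(res) <- NULL
  res
}

#' Correlate motif activities with growth rates
#'
#' Pearson correlation of each motif's activity with the normalized growth
#' rate across shared samples, with BH FDR across motifs. Motifs with
#' zero-variance activities are excluded with a warning.
#'
#' @param activities Motif x sample activity (or Z-score) matrix.
#' @param rates Named numeric vector of normalized growth rates.
#' @param min_n Minimum shared samples (default 10).
#' @return Data frame `motif`, `r`, `p_value`, `fdr`.
#' @export
motif_growth_correlation <- function(activities, rates, min_n = 10) {
  res <- .correlate_rows(activities, rates, min_n, what = "motif")
  names(res)[1] <- "motif"
  res
}
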