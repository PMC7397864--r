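#' Weighted running-sum enrichment score
#'
#' Classic preranked enrichment: genes are ordered by decreasing ranking
#' statistic; walking down the list, hits (set members) add
#' `|stat|^weight / sum_hits |stat|^weight` and misses subtract
#' `1 / (N - set size)`. The enrichment score is the extremum of the
#' running sum by absolute value, positive for sets concentrated at the
#' top of the ranking and negative for sets at the bottom.
#'
#' @param stats Named numeric vector of ranking statistics (no duplicate
#'   genes, all finite).
#' @param gene_set Character vector of genes.
#' @param weight Exponent on `|stat|` for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(stats, gene_set, weight = 1) {
  check_ranked(stats)
  ord <- order(stats, decreasing = TRUE)
  hit <- names(stats)[ord] %in% gene_set
  if (!any(hit)) stop("gene set does not intersect the ranked list",
                      call. = FALSE)
  if (all(hit)) stop("gene set equals the whole ranked universe",
                     call. = FALSE)
  w <- abs(stats[ord])^weight
  wsum <- sum(w[hit])
  inc <- if (wsum == 0) hit / sum(hit) else ifelse(hit, w / wsum, 0)
  running <- cumsum(inc - (!hit) / sum(!hit))
  pick_extremum(running)
}

## Extremum by absolute value; exact-magnitude ties (to fp tolerance) take
## the positive branch so the convention is deterministic.
pick_extremum <- function(vals) {
  mx <- max(vals)
  mn <- min(vals)
  if (abs(mx) >= abs(mn) - 1e-12) unname(mx) else unname(mn)
}

check_ranked <- function(stats) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("ranking statistics must be uniquely named by gene",
         call. = FALSE)
  }
  if (any(!is.finite(stats))) stop("ranking statistics must be finite",
                                   call. = FALSE)
  invisible(stats)
}

## Enrichment score from sorted hit positions only: O(k) per evaluation,
## used for the permutation null. w_sorted = |stat|^weight in ranking
## order; positions must be sorted increasing. Algebraically identical to
## the O(N) running sum because extrema occur just before or just after a
## hit.
es_from_positions <- function(positions, w_sorted, n) {
  k <- length(positions)
  wh <- w_sorted[positions]
  wsum <- sum(wh)
  cw <- if (wsum == 0) seq_len(k) / k else cumsum(wh) / wsum
  after <- cw - (positions - seq_len(k)) / (n - k)
  before <- after - if (wsum == 0) 1 / k else wh / wsum
  pick_extremum(c(after, before))
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' Computes the weighted running-sum enrichment score for each gene set,
#' builds a null by permuting gene labels (equivalently, drawing random
#' sets of the same size from the ranked universe), and reports a
#' normalized enrichment score (ES divided by the mean |null ES| of the
#' same sign), a plus-one empirical p-value against same-sign nulls, BH
#' FDR across sets, and the signed summary score
#' `-log10(p) * sign(NES)`. Sets smaller than `min_size` (after
#' intersection with the universe) are skipped with a note.
#'
#' @param stats Named numeric ranking statistics (e.g. per-ASO DE
#'   Z-scores).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @param min_size,max_size Set-size bounds after intersection
#'   (defaults 5 and 500).
#' @param weight Hit-weight exponent (default 1).
#' @return Data frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p_value`, `fdr`, `signed_score`, `note`.
#' @export
preranked_gsea <- function(stats, gene_sets, n_perm = 1000, seed = NULL,
                           min_size = 5, max_size = 500, weight = 1) {
  check_ranked(stats)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- order(stats, decreasing = TRUE)
  ranked_names <- names(stats)[ord]
  w_sorted <- abs(stats[ord])^weight
  n <- length(stats)
  null_cache <- new.env(parent = emptyenv())
  null_for_size <- function(k) {
    key <- as.character(k)
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    es <- vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample.int(n, k)), w_sorted, n)
    }, numeric(1))
    null_cache[[key]] <- es
    es
  }
  out <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    g <- intersect(gene_sets[[nm]], ranked_names)
    k <- length(g)
    if (k < min_size || k > max_size || k == n) {
      return(data.frame(set = nm, size = k, es = NA_real_, nes = NA_real_,
                        p_value = NA_real_, fdr = NA_real_,
                        signed_score = NA_real_,
                        note = "skipped: set size out of bounds",
                        stringsAsFactors = FALSE))
    }
    es <- es_from_positions(sort(match(g, ranked_names)), w_sorted, n)
    null <- null_for_size(k)
    same <- if (es >= 0) null[null > 0] else -null[null < 0]
    if (es == 0 || length(same) == 0) {
      p <- 1
      nes <- 0
    } else {
      p <- (sum(same >= abs(es) - 1e-12) + 1) / (length(same) + 1)
      nes <- sign(es) * abs(es) / mean(same)
    }
    data.frame(set = nm, size = k, es = es, nes = nes, p_value = p,
               fdr = NA_real_,
               signed_score = signed_enrichment(p, nes), note = "",
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- adjust_fdr(out$p_value[ok])
  rownames(out) <- NULL
  out
}

#' Signed enrichment summary score
#'
#' `-log10(p) * sign(NES)`: a single signed number per pathway combining
#' enrichment strength and direction, 0 when `p = 1`.
#'
#' @param p Nominal p-value(s) in `(0, 1]` (use a plus-one empirical p so
#'   0 cannot occur).
#' @param nes Normalized enrichment score(s).
#' @return Numeric signed score(s).
#' @export
signed_enrichment <- function(p, nes) {
  if (any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]; use a plus-one empirical p upstream",
         call. = FALSE)
  }
  -log10(p) * sign(nes)
}

#' Correlate pathway signed scores with growth rates
#'
#' Pearson correlation of each gene set's signed enrichment score with the
#' normalized growth rate across ASOs, BH-adjusted across sets. Sets with
#' constant scores are excluded with a warning.
#'
#' @param scores Set x ASO matrix of signed enrichment scores.
#' @param rates Named numeric vector of normalized growth rates per ASO.
#' @param min_n Minimum shared ASOs (default 10).
#' @return Data frame `set`, `r`, `p_value`, `fdr`.
#' @export
pathway_growth_correlation <- function(scores, rates, min_n = 10) {
  res <- .correlate_rows(scores, rates, min_n, what = "gene set")
  names(res)[1] <- "set"
  res
}

#' Read gene sets in GMT format
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
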