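#' Jaccard index of two (signed) DEG sets
#'
#' `|A intersect B| / |A union B|`; two empty sets have Jaccard 0 by
#' convention. Elements are arbitrary labels, typically the signed gene
#' encoding produced by [deg_sets()].
#'
#' @param a,b Character vectors (sets).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

all_label_permutations <- function(labels) {
  n <- length(labels)
  perm_idx <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_idx(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  lapply(perm_idx(seq_len(n)), function(i) labels[i])
}

same_target_pair_stat <- function(rates, labels) {
  d <- 0
  k <- 0
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    d <- d + sum(abs(rates[pairs[1, ]] - rates[pairs[2, ]]))
    k <- k + ncol(pairs)
  }
  if (k == 0) return(NA_real_)
  d / k
}

#' Permutation test of global growth concordance
#'
#' Tests whether ASOs targeting the same lncRNA have more concordant
#' normalized growth rates than ASOs targeting different lncRNAs. The
#' statistic is the mean absolute within-pair difference of normalized
#' rates over all same-target ASO pairs; the null is built by shuffling the
#' target labels over ASOs (preserving group sizes), and the empirical
#' p-value uses the plus-one rule `p = (#\{D_perm <= D_obs\} + 1) /
#' (n_perm + 1)`. On small instances (`<= 7` ASOs by default) the complete
#' permutation distribution is enumerated instead and the p-value is the
#' exact fraction of arrangements at least as concordant as observed.
#'
#' @param rates Named numeric vector of normalized growth rates, one per
#'   ASO.
#' @param target_map Data frame `aso_id`, `target_id` covering the rated
#'   ASOs.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive `TRUE`/`FALSE` to force or forbid full enumeration;
#'   `NULL` enumerates when there are at most 7 ASOs.
#' @return List with `statistic` (observed mean within-pair difference),
#'   `p_value`, `method`, and `n_perm`.
#' @export
global_growth_concordance <- function(rates, target_map, n_perm = 10000,
                                      seed = NULL, exhaustive = NULL) {
  labels <- target_map$target_id[match(names(rates), target_map$aso_id)]
  if (any(is.na(labels))) {
    stop("every rated ASO must appear in target_map", call. = FALSE)
  }
  sizes <- table(labels)
  if (sum(sizes >= 2) < 2) {
    stop("need at least 2 targets with >= 2 ASOs", call. = FALSE)
  }
  d_obs <- same_target_pair_stat(rates, labels)
  eps <- 1e-12
  if (is.null(exhaustive)) exhaustive <- length(rates) <= 7
  if (exhaustive) {
    d_all <- vapply(all_label_permutations(labels),
                    function(l) same_target_pair_stat(rates, l), numeric(1))
    return(list(statistic = d_obs,
                p_value = mean(d_all <= d_obs + eps),
                method = "exhaustive", n_perm = length(d_all)))
  }
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d_perm <- vapply(seq_len(n_perm), function(b) {
    same_target_pair_stat(rates, sample(labels))
  }, numeric(1))
  list(statistic = d_obs,
       p_value = (sum(d_perm <= d_obs + eps) + 1) / (n_perm + 1),
       method = "label-shuffle", n_perm = n_perm)
}

#' Concordance test of same-target ASO pairs against nontargeting pairs
#'
#' For every pair of ASOs targeting the same lncRNA, computes the Jaccard
#' index of their signed DEG sets and an empirical p-value against a null
#' of Jaccard indices from ASO pairs targeting *different* lncRNAs
#' (sampled without replacement), with the plus-one rule
#' `p = (#\{J_null >= J_obs\} + 1) / (n_null + 1)`.
#'
#' @param sets Named list of signed DEG sets (see [deg_sets()]).
#' @param target_map Data frame `aso_id`, `target_id` covering the sets.
#' @param n_null_pairs Different-target pairs sampled for the null
#'   (default 10000; capped at the number available).
#' @param seed Optional integer seed for null-pair sampling.
#' @param min_null_pairs Minimum different-target pairs required
#'   (default 100); lower it only for toy examples.
#' @return Data frame with one row per same-target pair: `aso_a`, `aso_b`,
#'   `target_id`, `pair_type`, `n_common_degs`, `jaccard`, `empirical_p`.
#'   The sampled null Jaccard values are attached as attribute
#'   `null_jaccard`.
#' @export
pair_concordance_test <- function(sets, target_map, n_null_pairs = 10000,
                                  seed = NULL, min_null_pairs = 100) {
  asos <- names(sets)
  labels <- target_map$target_id[match(asos, target_map$aso_id)]
  if (any(is.na(labels))) {
    stop("every DEG set must appear in target_map", call. = FALSE)
  }
  n <- length(asos)
  if (n < 2) stop("need at least 2 ASOs", call. = FALSE)
  pairs <- utils::combn(n, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  n_diff <- sum(!same)
  if (n_diff < min_null_pairs) {
    stop("fewer than ", min_null_pairs,
         " different-target ASO pairs available for the null",
         call. = FALSE)
  }
  if (sum(same) == 0) stop("no same-target ASO pairs", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  diff_idx <- which(!same)
  take <- if (n_diff > n_null_pairs) sample(diff_idx, n_null_pairs) else
    diff_idx
  j_null <- vapply(take, function(k) {
    jaccard_index(sets[[pairs[1, k]]], sets[[pairs[2, k]]])
  }, numeric(1))
  same_idx <- which(same)
  out <- do.call(rbind, lapply(same_idx, function(k) {
    a <- sets[[pairs[1, k]]]
    b <- sets[[pairs[2, k]]]
    j <- jaccard_index(a, b)
    data.frame(aso_a = asos[pairs[1, k]], aso_b = asos[pairs[2, k]],
               target_id = labels[pairs[1, k]], pair_type = "same_target",
               n_common_degs = length(intersect(a, b)), jaccard = j,
               empirical_p = (sum(j_null >= j - 1e-12) + 1) /
                 (length(j_null) + 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "null_jaccard") <- j_null
  out
}

#' Retain reproducibly responding ASO pairs
#'
#' Keeps same-target pairs with at least `min_common` common signed DEGs
#' and an empirical concordance p-value at most `alpha` — the screen's
#' definition of a reproducible knockdown-mediated molecular response.
#'
#' @param pairs Data frame from [pair_concordance_test()].
#' @param min_common Minimum common DEG count (default 5).
#' @param alpha Empirical p-value threshold (default 0.05).
#' @return The retained rows; the distinct targets covered are attached as
#'   attribute `targets`.
#' @export
reproducible_pairs <- function(pairs, min_common = 5, alpha = 0.05) {
  keep <- pairs[pairs$n_common_degs >= min_common &
                  pairs$empirical_p <= alpha, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "targets") <- sort(unique(keep$target_id))
  keep
}

#' Conditional significance cutoff for lncRNA hit calling
#'
#' Given `n` successful ASOs for a target and a background pool of per-ASO
#' significance flags from nontargeting context, finds the smallest number
#' of significant ASOs `k_min` such that drawing `n` flags from the pool
#' without replacement yields at least `k_min` significant ones with
#' probability below `alpha`. If no `k <= n` achieves this the target
#' cannot be called and `k_min = n + 1`. By default the resampling tail is
#' computed exactly (the hypergeometric tail, i.e. the infinite-resample
#' limit); supply `n_resample` for a Monte Carlo estimate instead.
#'
#' @param n Number of successful ASOs for the target (1 to 10).
#' @param background_flags Logical vector (>= 50) of significance flags
#'   from ASOs targeting other lncRNAs.
#' @param alpha Background rate to stay below (default 0.05).
#' @param n_resample Number of Monte Carlo draws; `NULL` (default) for the
#'   exact tail.
#' @param seed Optional seed for the Monte Carlo mode.
#' @return Integer `k_min` in `1 .. n + 1`.
#' @export
conditional_cutoff <- function(n, background_flags, alpha = 0.05,
                               n_resample = NULL, seed = NULL) {
  if (length(background_flags) == 0) {
    stop("background pool is empty", call. = FALSE)
  }
  if (length(background_flags) < 50) {
    stop("background pool must contain at least 50 flags", call. = FALSE)
  }
  if (n < 1 || n > 10) stop("n must be between 1 and 10", call. = FALSE)
  m <- length(background_flags)
  K <- sum(background_flags)
  tail_prob <- if (is.null(n_resample)) {
    function(k) stats::phyper(k - 1, K, m - K, n, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    draws <- stats::rhyper(n_resample, K, m - K, n)
    function(k) mean(draws >= k)
  }
  for (k in seq_len(n)) {
    if (tail_prob(k) < alpha) return(k)
  }
  n + 1L
}

#' Call lncRNA-level growth hits with conditional cutoffs
#'
#' A target with `n` successful ASOs is called a hit when at least
#' `k_min(n)` of them are significantly growth-inhibited, where `k_min` is
#' the conditional cutoff keeping the resampled background call rate below
#' `alpha` ([conditional_cutoff()]). The background pool for each target is
#' the significance flags of all successful ASOs targeting *other* lncRNAs,
#' so the cutoff adapts to the screen's own false-positive level.
#'
#' @param growth Data frame from [analyze_growth()] (needs `aso_id` and
#'   `significant_inhibition`).
#' @param target_map Data frame `aso_id`, `target_id` listing the
#'   successful ASOs to assess.
#' @param alpha Adjusted background level (default 0.05).
#' @param cutoffs Optional named integer vector of precomputed `k_min`
#'   values per target id; every assessed target must then be present.
#' @param n_resample,seed Passed to [conditional_cutoff()] when cutoffs are
#'   computed internally.
#' @return Data frame with one row per target: `target_id`,
#'   `n_successful_asos`, `n_significant_asos`, `k_min`, `is_hit`,
#'   `background_rate`. The screen-wide significant fraction is attached
#'   as attribute `screen_background_rate`.
#' @export
call_lncrna_hits <- function(growth, target_map, alpha = 0.05,
                             cutoffs = NULL, n_resample = NULL,
                             seed = NULL) {
  tm <- target_map[target_map$aso_id %in% growth$aso_id, , drop = FALSE]
  if (nrow(tm) == 0) stop("no ASOs shared between growth results and ",
                          "target_map", call. = FALSE)
  flags <- stats::setNames(growth$significant_inhibition, growth$aso_id)
  out <- do.call(rbind, lapply(split(tm, tm$target_id), function(g) {
    tg <- g$target_id[1]
    f <- flags[g$aso_id]
    pool <- flags[tm$aso_id[tm$target_id != tg]]
    k_min <- if (!is.null(cutoffs)) {
      if (!tg %in% names(cutoffs)) {
        stop("target ", tg, " absent from supplied cutoffs", call. = FALSE)
      }
      cutoffs[[tg]]
    } else {
      conditional_cutoff(length(f), pool, alpha = alpha,
                         n_resample = n_resample, seed = seed)
    }
    data.frame(target_id = tg, n_successful_asos = length(f),
               n_significant_asos = sum(f), k_min = k_min,
               is_hit = sum(f) >= k_min,
               background_rate = mean(pool), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "screen_background_rate") <- mean(flags[tm$aso_id])
  out
}
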