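## Independent brute-force / closed-form oracles used to pin down the
## package's statistics. These deliberately share no code with the
## implementation.

## Benjamini-Hochberg step-up, computed literally from the definition:
## sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, p[ord[j]] * m / j)
    q_sorted[i] <- min(cand, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

## Textbook pooled two-sample t statistic.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

## Jaccard by explicit element counting.
jaccard_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(0)
  inter <- 0
  for (x in a) if (any(b == x)) inter <- inter + 1
  inter / (length(a) + length(b) - inter)
}

## Literal weighted running-sum enrichment score (position by position).
es_oracle <- function(stats, gene_set, weight = 1) {
  ord <- order(stats, decreasing = TRUE)
  g <- names(stats)[ord]
  s <- abs(stats[ord])^weight
  hit <- g %in% gene_set
  wsum <- sum(s[hit])
  running <- numeric(length(g))
  val <- 0
  for (i in seq_along(g)) {
    if (hit[i]) {
      val <- val + if (wsum == 0) 1 / sum(hit) else s[i] / wsum
    } else {
      val <- val - 1 / sum(!hit)
    }
    running[i] <- val
  }
  ## extremum by |.|, positive branch on ties (shared convention)
  mx <- max(running)
  mn <- min(running)
  if (abs(mx) >= abs(mn) - 1e-12) mx else mn
}

## Hypergeometric tail via explicit binomial coefficients, then the
## smallest k with tail < alpha.
kmin_hyper_oracle <- function(n, flags, alpha = 0.05) {
  M <- length(flags); K <- sum(flags)
  tail_k <- function(k) {
    tot <- 0
    for (j in k:min(n, K)) {
      tot <- tot + choose(K, j) * choose(M - K, n - j) / choose(M, n)
    }
    if (k > min(n, K)) 0 else tot
  }
  for (k in seq_len(n)) if (tail_k(k) < alpha) return(k)
  n + 1L
}

## Every permutation of a vector, by naive recursion.
perms_oracle <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_oracle(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

## Mean absolute within-pair difference over same-label pairs.
pair_stat_oracle <- function(rates, labels) {
  tot <- 0; k <- 0
  for (i in seq_along(rates)) {
    for (j in seq_along(rates)) {
      if (i < j && labels[i] == labels[j]) {
        tot <- tot + abs(rates[i] - rates[j]); k <- k + 1
      }
    }
  }
  unname(tot / k)
}

## Small helper: a fast default screen config for tests.
test_config <- function(...) {
  screen_config(n_targets = 8, asos_per_target = 5, n_genes = 200,
                n_motifs = 5, n_gene_sets = 6, ...)
}
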