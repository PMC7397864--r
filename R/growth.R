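#' Truncate confluence series to the plate control window
#'
#' Growth slopes are only meaningful while the plate is in its near-linear
#' phase, so every well on a plate is truncated at the first time point at
#' which the mean confluence of that plate's NC_A control wells reaches 90%.
#' If the controls never reach 90%, the full series is kept.
#'
#' @param confluence Long-format data frame with columns `plate`, `well`,
#'   `role`, `aso_id`, `time_h`, `confluence`.
#' @return The input restricted to the per-plate control window.
#' @export
truncate_to_control_window <- function(confluence) {
  keep <- unlist(lapply(split(seq_len(nrow(confluence)), confluence$plate),
                        function(idx) {
    sub <- confluence[idx, ]
    nc <- sub[sub$role == "NC_A", ]
    if (nrow(nc) == 0) {
      stop("plate ", sub$plate[1], " has no NC_A control wells",
           call. = FALSE)
    }
    nc_mean <- tapply(nc$confluence, nc$time_h, mean)
    times <- as.numeric(names(nc_mean))
    hit <- which(nc_mean >= 90)
    t90 <- if (length(hit) == 0) Inf else times[min(hit)]
    kept_times <- unique(sub$time_h[sub$time_h <= t90])
    if (length(kept_times) < 3) {
      stop("plate ", sub$plate[1], ": fewer than 3 time points remain ",
           "after truncating to the control window", call. = FALSE)
    }
    idx[sub$time_h <= t90]
  }), use.names = FALSE)
  confluence[sort(keep), , drop = FALSE]
}

#' Ordinary least-squares growth slope of one well
#'
#' @param times Time points in hours (at least 3, not all equal).
#' @param values % confluence at each time point.
#' @return The OLS slope of confluence on time, in % confluence per hour.
#' @examples
#' estimate_growth_rate(seq(0, 30, 3), 10 + 2 * seq(0, 30, 3))  # exactly 2
#' @export
estimate_growth_rate <- function(times, values) {
  if (length(times) < 3 || length(values) != length(times)) {
    stop("need at least 3 (time, confluence) points", call. = FALSE)
  }
  td <- times - mean(times)
  sxx <- sum(td^2)
  if (sxx == 0) stop("degenerate time grid: all times equal", call. = FALSE)
  sum(td * (values - mean(values))) / sxx
}

#' Normalize a growth slope by plate controls
#'
#' The normalized growth rate is the well slope divided by the mean slope of
#' the same plate's NC_A control wells. Negative slopes (cells shrinking or
#' detaching) pass through as negative normalized rates to flag severe
#' growth inhibition.
#'
#' @param slope Well slope (% confluence / h).
#' @param control_slopes Slopes of the plate's NC_A wells.
#' @return Dimensionless normalized growth rate.
#' @export
normalize_growth_rate <- function(slope, control_slopes) {
  if (length(control_slopes) < 1) {
    stop("at least one control slope is required", call. = FALSE)
  }
  m <- mean(control_slopes)
  if (m <= 0) {
    stop("plate controls failed: mean control slope is not positive",
         call. = FALSE)
  }
  slope / m
}

#' Pooled two-sample t-test of replicate slopes against plate controls
#'
#' Equal-variance (pooled) two-sample Student t statistic with
#' `n1 + n2 - 2` degrees of freedom and a two-sided p-value. With two
#' replicate wells tested against six plate controls this gives 6 degrees
#' of freedom. Zero pooled variance with equal means yields `t = 0, p = 1`;
#' zero pooled variance with unequal means is degenerate and yields
#' `p = 0` with infinite `t`.
#'
#' @param replicate_slopes Slopes of the ASO's replicate wells (>= 2).
#' @param control_slopes Slopes of the plate's control wells (>= 2).
#' @return A list with `t_stat`, `p_value`, `df`, and `degenerate`.
#' @export
growth_significance <- function(replicate_slopes, control_slopes) {
  n1 <- length(replicate_slopes)
  n2 <- length(control_slopes)
  if (n1 < 2 || n2 < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(replicate_slopes) +
            (n2 - 1) * stats::var(control_slopes)) / df
  delta <- mean(replicate_slopes) - mean(control_slopes)
  if (sp2 == 0) {
    if (delta == 0) {
      return(list(t_stat = 0, p_value = 1, df = df, degenerate = FALSE))
    }
    return(list(t_stat = sign(delta) * Inf, p_value = 0, df = df,
                degenerate = TRUE))
  }
  t_stat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df), df = df,
       degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment applied screen-wide (across all ASOs of a run, or
#' across all genes of one differential-expression contrast).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in `[0, 1]`, in the input order.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-ASO growth analysis of a confluence table
#'
#' Runs the full growth-phenotype pipeline on a long-format confluence
#' table: truncates every plate to its NC_A 90% control window, fits an OLS
#' slope per well, normalizes each ASO's mean slope by the mean slope of
#' the same plate's controls, tests the replicate wells' raw slopes against
#' the plate control slopes with a pooled two-sample t-test, and adjusts
#' p-values across all ASOs by Benjamini-Hochberg. An ASO is flagged as
#' significantly growth-inhibited when its FDR is at most `fdr_threshold`
#' and its normalized rate is below 1.
#'
#' @param confluence Long-format data frame (`plate`, `well`, `role`,
#'   `aso_id`, `time_h`, `confluence`).
#' @param fdr_threshold FDR cutoff for the inhibition call (default 0.05).
#' @return Data frame with one row per ASO: `aso_id`, `plate`, `slope`,
#'   `normalized_rate`, `t_stat`, `p_value`, `fdr`,
#'   `significant_inhibition`.
#' @export
analyze_growth <- function(confluence, fdr_threshold = 0.05) {
  trunc <- truncate_to_control_window(confluence)
  key <- paste(trunc$plate, trunc$well, sep = ":")
  first <- !duplicated(key)
  well_info <- data.frame(plate = trunc$plate[first],
                          well = trunc$well[first],
                          role = trunc$role[first],
                          aso_id = trunc$aso_id[first],
                          stringsAsFactors = FALSE)
  well_info$slope <- vapply(split(seq_len(nrow(trunc)), key)[key[first]],
                            function(i) {
                              estimate_growth_rate(trunc$time_h[i],
                                                   trunc$confluence[i])
                            }, numeric(1))
  ctrl <- split(well_info$slope[well_info$role == "NC_A"],
                well_info$plate[well_info$role == "NC_A"])
  aso_rows <- well_info[well_info$role == "ASO" & !is.na(well_info$aso_id), ]
  out <- do.call(rbind, lapply(split(aso_rows, aso_rows$aso_id),
                               function(w) {
    cs <- ctrl[[as.character(w$plate[1])]]
    if (is.null(cs)) {
      stop("plate ", w$plate[1], " has no control slopes", call. = FALSE)
    }
    sig <- growth_significance(w$slope, cs)
    data.frame(aso_id = w$aso_id[1], plate = w$plate[1],
               slope = mean(w$slope),
               normalized_rate = normalize_growth_rate(mean(w$slope), cs),
               t_stat = sig$t_stat, p_value = sig$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$fdr <- adjust_fdr(out$p_value)
  out$significant_inhibition <- out$fdr <= fdr_threshold &
    out$normalized_rate < 1
  out
}
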