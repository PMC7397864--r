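#' Classify knockdown success for one ASO
#'
#' An ASO counts as a successful knockdown when more than 40% knockdown
#' efficiency is reached in at least two primer pairs, or more than 60% in a
#' single primer pair. Both thresholds are strict inequalities on the
#' fraction scale (0.40 is not "more than 40%").
#'
#' @param efficiencies Numeric vector of knockdown efficiencies in `[0, 1]`,
#'   one per primer pair (typically three).
#' @return `TRUE` if the ASO passes the success rule.
#' @examples
#' classify_knockdown(c(0.45, 0.41, 0.10))  # TRUE, two pairs above 40%
#' classify_knockdown(c(0.61, 0.05, 0.05))  # TRUE, one pair above 60%
#' classify_knockdown(c(0.39, 0.40, 0.10))  # FALSE
#' @export
classify_knockdown <- function(efficiencies) {
  if (length(efficiencies) == 0) {
    stop("at least one primer-pair efficiency is required", call. = FALSE)
  }
  if (any(!is.finite(efficiencies)) || any(efficiencies < 0) ||
      any(efficiencies > 1)) {
    stop("efficiencies must be fractions in [0, 1]", call. = FALSE)
  }
  sum(efficiencies > 0.40) >= 2 || max(efficiencies) > 0.60
}

#' Per-ASO knockdown success from a long efficiency table
#'
#' Aggregates a long-format table (one row per ASO x primer pair,
#' replicate measurements averaged per primer pair first) and applies
#' [classify_knockdown()] to each ASO.
#'
#' @param kd Data frame with columns `aso_id`, `target_id`, `primer_id`,
#'   `efficiency`.
#' @return Data frame with one row per ASO: `aso_id`, `target_id`,
#'   `success`.
#' @export
kd_success_table <- function(kd) {
  required <- c("aso_id", "target_id", "primer_id", "efficiency")
  if (!all(required %in% names(kd))) {
    stop("kd table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  per_primer <- stats::aggregate(
    efficiency ~ aso_id + target_id + primer_id, data = kd, FUN = mean)
  by_aso <- split(per_primer$efficiency,
                  paste(per_primer$aso_id, per_primer$target_id, sep = "\r"))
  keys <- do.call(rbind, strsplit(names(by_aso), "\r", fixed = TRUE))
  out <- data.frame(aso_id = keys[, 1], target_id = keys[, 2],
                    success = vapply(by_aso, classify_knockdown, logical(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$aso_id), , drop = FALSE]
}

#' Targets with enough successful ASOs
#'
#' @param success Data frame as returned by [kd_success_table()] (columns
#'   `aso_id`, `target_id`, `success`).
#' @param min_asos Minimum number of successful ASOs required per target
#'   (default 2, the screen's threshold for target-level analyses).
#' @return Character vector of target ids.
#' @export
successful_targets <- function(success, min_asos = 2) {
  if (nrow(success) == 0) return(character(0))
  counts <- tapply(success$success, success$target_id, sum)
  sort(names(counts)[counts >= min_asos])
}
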