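#' Screen design configuration
#'
#' Builds a validated configuration describing the design of a synthetic ASO
#' knockdown screen: how many lncRNA targets and ASOs per target, the plate
#' layout (duplicated ASO wells plus six non-targeting NC_A control wells per
#' plate), the imaging time grid, the knockdown-efficiency distribution, and
#' the planted effect structure (growth effects, shared downstream gene
#' modules, ASO-specific off-target modules, motif activities, pathways).
#'
#' Defaults mirror a fibroblast ASO screen imaged every 3 h for 48 h with
#' ASOs transfected in duplicate, five non-overlapping ASOs per target, and
#' six NC_A wells per plate anchoring normalization and testing.
#'
#' @param n_targets Number of lncRNA targets.
#' @param asos_per_target ASOs designed per target (default 5).
#' @param n_plates Number of plates; `NULL` fills plates with up to 45
#'   duplicated ASOs each (96-well layout with 6 control wells).
#' @param controls_per_plate NC_A control wells (and control CAGE libraries)
#'   per plate (default 6).
#' @param replicate_wells Imaging replicate wells per ASO (default 2).
#' @param n_genes Genes in the expression universe; the first `n_targets`
#'   genes are the targeted lncRNAs themselves.
#' @param n_motifs Transcription-factor motifs in the site-count matrix.
#' @param n_gene_sets Gene sets emitted in GMT form.
#' @param frac_true_growth_hits Fraction of targets with a planted growth
#'   effect shared by their successful ASOs.
#' @param frac_true_molecular_hits Fraction of targets with a planted shared
#'   downstream gene module.
#' @param growth_effect_size Relative slope reduction in `[0, 1]` for
#'   successful ASOs of growth-hit targets.
#' @param shared_module_size Genes per target-specific shared module.
#' @param offtarget_module_size Genes per ASO-specific off-target module.
#' @param module_effect_size Magnitude (log2 units) of shared-module effects.
#' @param offtarget_effect_size Magnitude (log2 units) of off-target effects.
#' @param kd_efficiency_params Beta shape parameters for the per-ASO true
#'   knockdown efficiency.
#' @param primer_noise_sd Gaussian noise of per-primer-pair RT-qPCR
#'   efficiency measurements (fraction scale).
#' @param n_primer_pairs Primer pairs measured per ASO (default 3).
#' @param noise_sd_confluence Additive well noise on % confluence.
#' @param noise_sd_logexpr Gaussian noise on log2 expression.
#' @param slope_sd_well Well-to-well slope variability (% confluence / h).
#' @param base_slope Control growth slope (% confluence / h).
#' @param start_confluence Seeding confluence (%).
#' @param timepoints_h Imaging time grid in hours (default 0 to 48 by 3).
#' @param kd_reps CAGE libraries sequenced per ASO (default 2, matching
#'   transfection in duplicate).
#' @param expression_from_motifs If `TRUE`, the log2 expression matrix gains
#'   a site-counts-times-planted-activities component so motif-activity
#'   recovery can be benchmarked against truth.
#' @param motif_activity_sd Standard deviation of planted motif activities.
#' @param seed Integer seed; the whole screen is deterministic given the
#'   configuration.
#'
#' @return An object of class `screen_config` (a validated list).
#' @seealso [simulate_screen()]
#' @export
screen_config <- function(n_targets = 20,
                          asos_per_target = 5,
                          n_plates = NULL,
                          controls_per_plate = 6,
                          replicate_wells = 2,
                          n_genes = 1000,
                          n_motifs = 20,
                          n_gene_sets = 25,
                          frac_true_growth_hits = 0.1,
                          frac_true_molecular_hits = 0.2,
                          growth_effect_size = 0.5,
                          shared_module_size = 30,
                          offtarget_module_size = 20,
                          module_effect_size = 1.0,
                          offtarget_effect_size = 1.0,
                          kd_efficiency_params = c(4.5, 5.5),
                          primer_noise_sd = 0.05,
                          n_primer_pairs = 3,
                          noise_sd_confluence = 2,
                          noise_sd_logexpr = 0.3,
                          slope_sd_well = 0.05,
                          base_slope = 1.8,
                          start_confluence = 10,
                          timepoints_h = seq(0, 48, by = 3),
                          kd_reps = 2,
                          expression_from_motifs = FALSE,
                          motif_activity_sd = 1,
                          seed = 1L) {
  cfg <- list(
    n_targets = n_targets, asos_per_target = asos_per_target,
    n_plates = n_plates, controls_per_plate = controls_per_plate,
    replicate_wells = replicate_wells, n_genes = n_genes,
    n_motifs = n_motifs, n_gene_sets = n_gene_sets,
    frac_true_growth_hits = frac_true_growth_hits,
    frac_true_molecular_hits = frac_true_molecular_hits,
    growth_effect_size = growth_effect_size,
    shared_module_size = shared_module_size,
    offtarget_module_size = offtarget_module_size,
    module_effect_size = module_effect_size,
    offtarget_effect_size = offtarget_effect_size,
    kd_efficiency_params = kd_efficiency_params,
    primer_noise_sd = primer_noise_sd,
    n_primer_pairs = n_primer_pairs,
    noise_sd_confluence = noise_sd_confluence,
    noise_sd_logexpr = noise_sd_logexpr,
    slope_sd_well = slope_sd_well,
    base_slope = base_slope, start_confluence = start_confluence,
    timepoints_h = timepoints_h, kd_reps = kd_reps,
    expression_from_motifs = expression_from_motifs,
    motif_activity_sd = motif_activity_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (is.null(x)) return(invisible())
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min ||
        x != round(x)) {
      stop("invalid configuration: '", field, "' must be an integer >= ",
           min, call. = FALSE)
    }
  }
  chk_frac <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop("invalid configuration: '", field, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  chk_pos <- function(field, strict = FALSE) {
    x <- cfg[[field]]
    if (length(x) != 1 || !is.numeric(x) || is.na(x) ||
        (strict && x <= 0) || (!strict && x < 0)) {
      stop("invalid configuration: '", field, "' must be ",
           if (strict) "> 0" else ">= 0", call. = FALSE)
    }
  }
  for (f in c("n_targets", "asos_per_target", "controls_per_plate",
              "replicate_wells", "n_genes", "n_motifs", "n_gene_sets",
              "shared_module_size", "offtarget_module_size",
              "n_primer_pairs", "kd_reps")) {
    chk_count(f)
  }
  chk_count("n_plates")
  for (f in c("frac_true_growth_hits", "frac_true_molecular_hits",
              "growth_effect_size")) {
    chk_frac(f)
  }
  for (f in c("module_effect_size", "offtarget_effect_size",
              "primer_noise_sd", "noise_sd_confluence", "noise_sd_logexpr",
              "slope_sd_well", "motif_activity_sd")) {
    chk_pos(f)
  }
  chk_pos("base_slope", strict = TRUE)
  if (cfg$start_confluence < 0 || cfg$start_confluence > 100) {
    stop("invalid configuration: 'start_confluence' must lie in [0, 100]",
         call. = FALSE)
  }
  kp <- cfg$kd_efficiency_params
  if (length(kp) != 2 || any(!is.finite(kp)) || any(kp <= 0)) {
    stop("invalid configuration: 'kd_efficiency_params' must be two ",
         "positive Beta shape parameters", call. = FALSE)
  }
  tp <- cfg$timepoints_h
  if (length(tp) < 3 || any(!is.finite(tp)) || any(diff(tp) <= 0)) {
    stop("invalid configuration: 'timepoints_h' must be a strictly ",
         "increasing grid with at least 3 points", call. = FALSE)
  }
  if (cfg$n_genes < cfg$n_targets) {
    stop("invalid configuration: 'n_genes' must be at least 'n_targets' ",
         "(targets are part of the gene universe)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Synthetic ASO screen configuration\n")
  cat(sprintf("  %d targets x %d ASOs (%d primer pairs), %d replicate wells\n",
              x$n_targets, x$asos_per_target, x$n_primer_pairs,
              x$replicate_wells))
  cat(sprintf("  %d genes, %d motifs, %d gene sets; seed %d\n",
              x$n_genes, x$n_motifs, x$n_gene_sets, x$seed))
  cat(sprintf("  planted hits: growth %.0f%%, molecular %.0f%%\n",
              100 * x$frac_true_growth_hits,
              100 * x$frac_true_molecular_hits))
  invisible(x)
}
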