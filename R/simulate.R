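#' Simulate one well's confluence time course
#'
#' Early-phase fibroblast growth is close to linear in % confluence, so a
#' well is modelled as `start + slope * t` plus additive Gaussian noise,
#' clipped to the instrument range `[0, 100]`.
#'
#' @param slope Growth slope in % confluence per hour.
#' @param times Strictly increasing time grid in hours.
#' @param start Seeding confluence in `[0, 100]`.
#' @param noise_sd Standard deviation of additive well noise (% confluence).
#' @return Numeric vector of % confluence values, one per time point.
#' @examples
#' simulate_confluence(2, seq(0, 30, by = 3), start = 10, noise_sd = 0)
#' @export
simulate_confluence <- function(slope, times, start = 10, noise_sd = 0) {
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (start < 0 || start > 100) {
    stop("'start' must lie in [0, 100]", call. = FALSE)
  }
  v <- start + slope * times
  if (noise_sd > 0) v <- v + stats::rnorm(length(times), 0, noise_sd)
  pmin(pmax(v, 0), 100)
}

#' Simulate a synthetic ASO knockdown screen
#'
#' Generates a complete screen with the statistical structure the analysis
#' assumes: a long-format confluence table (NC_A control wells plus
#' duplicated ASO wells per plate), per-ASO x primer-pair knockdown
#' efficiencies, a gene x sample expression matrix with a sample sheet, a
#' promoter x motif site-count matrix, gene sets, a per-well morphology
#' feature table, and the planted ground truth.
#'
#' Planted structure:
#' * each ASO draws a true knockdown efficiency from a Beta distribution;
#'   per-primer measurements add Gaussian noise, and ASOs are "successful"
#'   when they pass [classify_knockdown()];
#' * the targeted lncRNA's expression in its knockdown samples is reduced by
#'   the ASO's efficiency (in expectation);
#' * growth-hit targets reduce the growth slope of all their successful
#'   ASOs' wells by `growth_effect_size`;
#' * molecular-hit targets shift a target-specific shared gene module with a
#'   common direction in all their successful ASOs, while every ASO also
#'   perturbs its own off-target module;
#' * molecular-hit targets additionally lose eccentricity (spindle shape)
#'   without losing cells, and growth-hit targets lose cell count, in the
#'   morphology table.
#'
#' With `frac_true_growth_hits = frac_true_molecular_hits = 0` and
#' `growth_effect_size = 0` the screen is a null screen: every ASO well has
#' the same expected slope as the NC_A controls, which is what the
#' empirical-background calibration of hit calling consumes.
#'
#' @param config A [screen_config()] object.
#' @return An object of class `synthetic_screen`: a list with elements
#'   `confluence`, `kd`, `expression`, `sample_sheet`, `site_counts`,
#'   `gene_sets`, `morphology`, `truth`, and `config`.
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_config")) {
    stop("'config' must be a screen_config object", call. = FALSE)
  }
  validate_screen_config(config)
  cf <- config
  set.seed(cf$seed)

  n_asos <- cf$n_targets * cf$asos_per_target
  targets <- sprintf("LNC%03d", seq_len(cf$n_targets))
  asos <- sprintf("%s_ASO%02d",
                  rep(targets, each = cf$asos_per_target),
                  rep(seq_len(cf$asos_per_target), cf$n_targets))
  aso_target <- stats::setNames(rep(targets, each = cf$asos_per_target), asos)

  ## --- knockdown efficiencies (true and per-primer measured) -------------
  e_true <- stats::setNames(
    pmin(stats::rbeta(n_asos, cf$kd_efficiency_params[1],
                      cf$kd_efficiency_params[2]), 0.98), asos)
  kd <- data.frame(
    aso_id = rep(asos, each = cf$n_primer_pairs),
    target_id = rep(unname(aso_target), each = cf$n_primer_pairs),
    primer_id = rep(sprintf("primer_%d", seq_len(cf$n_primer_pairs)), n_asos),
    stringsAsFactors = FALSE
  )
  kd$efficiency <- pmin(pmax(
    rep(e_true, each = cf$n_primer_pairs) +
      stats::rnorm(nrow(kd), 0, cf$primer_noise_sd), 0), 0.98)
  success <- vapply(split(kd$efficiency, kd$aso_id), classify_knockdown,
                    logical(1))[asos]

  ## --- planted hit targets ----------------------------------------------
  growth_hits <- sample(targets, round(cf$frac_true_growth_hits *
                                         cf$n_targets))
  molecular_hits <- sample(targets, round(cf$frac_true_molecular_hits *
                                            cf$n_targets))

  ## --- plate layout ------------------------------------------------------
  asos_per_plate_cap <- max(1L, floor((96 - cf$controls_per_plate) /
                                        cf$replicate_wells))
  n_plates <- if (is.null(cf$n_plates)) {
    ceiling(n_asos / asos_per_plate_cap)
  } else {
    cf$n_plates
  }
  plate_of_aso <- stats::setNames(((seq_len(n_asos) - 1L) %% n_plates) + 1L,
                                  asos)

  ## --- well-level growth slopes and confluence ---------------------------
  slope_mult <- ifelse(aso_target[asos] %in% growth_hits & success,
                       1 - cf$growth_effect_size, 1)
  wells <- data.frame(
    plate = c(rep(seq_len(n_plates), each = cf$controls_per_plate),
              rep(unname(plate_of_aso), each = cf$replicate_wells)),
    role = c(rep("NC_A", n_plates * cf$controls_per_plate),
             rep("ASO", n_asos * cf$replicate_wells)),
    aso_id = c(rep(NA_character_, n_plates * cf$controls_per_plate),
               rep(asos, each = cf$replicate_wells)),
    stringsAsFactors = FALSE
  )
  wells <- wells[order(wells$plate), ]
  wells$well <- unlist(lapply(split(seq_len(nrow(wells)), wells$plate),
                              function(i) sprintf("W%02d", seq_along(i))),
                       use.names = FALSE)
  mult <- ifelse(wells$role == "NC_A", 1,
                 slope_mult[match(wells$aso_id, asos)])
  wells$slope_true <- cf$base_slope * mult +
    stats::rnorm(nrow(wells), 0, cf$slope_sd_well)

  nt <- length(cf$timepoints_h)
  confluence <- data.frame(
    plate = rep(wells$plate, each = nt),
    well = rep(wells$well, each = nt),
    role = rep(wells$role, each = nt),
    aso_id = rep(wells$aso_id, each = nt),
    time_h = rep(cf$timepoints_h, nrow(wells)),
    stringsAsFactors = FALSE
  )
  confluence$confluence <- unlist(lapply(wells$slope_true, function(s) {
    simulate_confluence(s, cf$timepoints_h, cf$start_confluence,
                        cf$noise_sd_confluence)
  }), use.names = FALSE)

  ## --- expression universe ----------------------------------------------
  genes <- c(targets,
             sprintf("G%05d", seq_len(cf$n_genes - cf$n_targets)))
  baseline_log2 <- c(stats::rnorm(cf$n_targets, 3.5, 1),
                     pmax(stats::rnorm(cf$n_genes - cf$n_targets, 4, 2), 0))
  names(baseline_log2) <- genes
  nontarget_genes <- setdiff(genes, targets)

  ## shared downstream modules (disjoint across molecular-hit targets when
  ## the universe allows, otherwise drawn independently)
  shared_modules <- list()
  if (length(molecular_hits) > 0 && cf$shared_module_size > 0) {
    need <- length(molecular_hits) * cf$shared_module_size
    if (need <= length(nontarget_genes)) {
      pool <- sample(nontarget_genes, need)
      idx <- split(pool, rep(seq_along(molecular_hits),
                             each = cf$shared_module_size))
      names(idx) <- molecular_hits
    } else {
      idx <- stats::setNames(lapply(molecular_hits, function(t)
        sample(nontarget_genes, cf$shared_module_size)), molecular_hits)
    }
    shared_modules <- lapply(idx, function(g) {
      data.frame(gene = g,
                 effect = sample(c(-1, 1), length(g), replace = TRUE) *
                   cf$module_effect_size,
                 stringsAsFactors = FALSE)
    })
  }
  offtarget_modules <- stats::setNames(lapply(asos, function(a) {
    g <- sample(nontarget_genes, min(cf$offtarget_module_size,
                                     length(nontarget_genes)))
    data.frame(gene = g,
               effect = sample(c(-1, 1), length(g), replace = TRUE) *
                 cf$offtarget_effect_size,
               stringsAsFactors = FALSE)
  }), asos)

  ## --- sample sheet: per-plate NC_A libraries + kd_reps per ASO ----------
  sample_sheet <- rbind(
    data.frame(
      sample_id = sprintf("P%02d_NC_%02d",
                          rep(seq_len(n_plates), each = cf$controls_per_plate),
                          rep(seq_len(cf$controls_per_plate), n_plates)),
      aso_id = NA_character_,
      target_id = NA_character_,
      plate = rep(seq_len(n_plates), each = cf$controls_per_plate),
      is_control = TRUE, stringsAsFactors = FALSE),
    data.frame(
      sample_id = sprintf("%s_rep%d", rep(asos, each = cf$kd_reps),
                          rep(seq_len(cf$kd_reps), n_asos)),
      aso_id = rep(asos, each = cf$kd_reps),
      target_id = rep(unname(aso_target), each = cf$kd_reps),
      plate = rep(unname(plate_of_aso), each = cf$kd_reps),
      is_control = FALSE, stringsAsFactors = FALSE)
  )
  n_samples <- nrow(sample_sheet)

  ## --- motif layer --------------------------------------------------------
  site_counts <- matrix(stats::rpois(cf$n_genes * cf$n_motifs, 1),
                        nrow = cf$n_genes,
                        dimnames = list(genes,
                                        sprintf("M%03d", seq_len(cf$n_motifs))))
  motif_activities <- NULL
  if (cf$expression_from_motifs) {
    motif_activities <- matrix(
      stats::rnorm(cf$n_motifs * n_samples, 0, cf$motif_activity_sd),
      nrow = cf$n_motifs,
      dimnames = list(colnames(site_counts), sample_sheet$sample_id))
  }

  ## --- log2 expression ----------------------------------------------------
  log2_expr <- matrix(rep(baseline_log2, n_samples), nrow = cf$n_genes,
                      dimnames = list(genes, sample_sheet$sample_id))
  for (i in which(!sample_sheet$is_control)) {
    a <- sample_sheet$aso_id[i]
    tg <- aso_target[[a]]
    log2_expr[tg, i] <- log2_expr[tg, i] + log2(1 - e_true[[a]])
    if (tg %in% names(shared_modules) && success[[a]]) {
      m <- shared_modules[[tg]]
      log2_expr[m$gene, i] <- log2_expr[m$gene, i] + m$effect
    }
    m <- offtarget_modules[[a]]
    log2_expr[m$gene, i] <- log2_expr[m$gene, i] + m$effect
  }
  if (cf$expression_from_motifs) {
    nc <- sweep(site_counts, 2, colMeans(site_counts))
    log2_expr <- log2_expr + nc %*% motif_activities
  }
  log2_expr <- log2_expr +
    matrix(stats::rnorm(length(log2_expr), 0, cf$noise_sd_logexpr),
           nrow = nrow(log2_expr))
  expression <- 2^log2_expr

  ## --- gene sets: molecular-hit modules embedded in the first sets --------
  gene_sets <- list()
  set_names <- sprintf("PW%03d", seq_len(cf$n_gene_sets))
  planted <- utils::head(names(shared_modules), cf$n_gene_sets)
  for (i in seq_len(cf$n_gene_sets)) {
    if (i <= length(planted)) {
      core <- shared_modules[[planted[i]]]$gene
      extra <- sample(setdiff(nontarget_genes, core),
                      min(length(core), length(nontarget_genes) -
                            length(core)))
      gene_sets[[set_names[i]]] <- c(core, extra)
    } else {
      gene_sets[[set_names[i]]] <- sample(
        nontarget_genes, min(sample(20:80, 1), length(nontarget_genes)))
    }
  }
  pathway_membership <- stats::setNames(utils::head(set_names,
                                                    length(planted)), planted)

  ## --- morphology features (one row per imaged well) ----------------------
  morph_mult <- ifelse(wells$role == "NC_A", 1,
                       ifelse(aso_target[wells$aso_id] %in% molecular_hits &
                                success[wells$aso_id], 1, 0))
  morph_mult[is.na(morph_mult)] <- 0
  growth_mult <- ifelse(wells$role == "ASO" &
                          aso_target[wells$aso_id] %in% growth_hits &
                          success[wells$aso_id], 1, 0)
  growth_mult[is.na(growth_mult)] <- 0
  spindle_loss <- ifelse(wells$role == "ASO", morph_mult, 0)
  morphology <- data.frame(
    plate = wells$plate, well = wells$well, role = wells$role,
    aso_id = wells$aso_id,
    eccentricity = stats::rnorm(nrow(wells), 0.85, 0.02) -
      0.1 * spindle_loss,
    compactness = stats::rnorm(nrow(wells), 2.0, 0.1),
    radius = stats::rnorm(nrow(wells), 30, 2),
    axis_length = stats::rnorm(nrow(wells), 80, 5),
    cell_count = stats::rnorm(nrow(wells), 200, 15) *
      (1 - cf$growth_effect_size * growth_mult),
    stringsAsFactors = FALSE
  )

  truth <- list(
    growth_hit_targets = growth_hits,
    molecular_hit_targets = molecular_hits,
    kd_efficiency = e_true,
    aso_success = success,
    aso_target = aso_target,
    shared_modules = shared_modules,
    offtarget_modules = offtarget_modules,
    motif_activities = motif_activities,
    pathway_membership = pathway_membership,
    base_slope = cf$base_slope,
    well_slopes = stats::setNames(wells$slope_true,
                                  paste(wells$plate, wells$well, sep = ":"))
  )

  out <- list(confluence = confluence, kd = kd, expression = expression,
              sample_sheet = sample_sheet, site_counts = site_counts,
              gene_sets = gene_sets, morphology = morphology,
              truth = truth, config = cf)
  class(out) <- "synthetic_screen"
  out
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("Synthetic ASO knockdown screen\n")
  cat(sprintf("  %d targets, %d ASOs, %d wells, %d expression samples\n",
              x$config$n_targets,
              x$config$n_targets * x$config$asos_per_target,
              length(unique(paste(x$confluence$plate, x$confluence$well))),
              ncol(x$expression)))
  cat(sprintf("  planted growth hits: %d, molecular hits: %d\n",
              length(x$truth$growth_hit_targets),
              length(x$truth$molecular_hit_targets)))
  invisible(x)
}
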