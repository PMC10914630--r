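# Synthetic-cohort generator with recorded ground truth.
#
# Emulates the post-quantification protein matrix the pipeline consumes:
# planted diurnal rhythms (single 24-h harmonic), diagnosis effects,
# synaptosome enrichment folds, correlated co-expression modules built from
# shared latent factors, TMT-plex batch offsets, and Gaussian residual noise.

#' Simulation configuration
#'
#' Defaults mirror a 20 + 20 postmortem case-control cohort at desk scale.
#' Amplitudes, fold-changes and noise are on the log2 scale throughout.
#'
#' @param n_per_group Subjects per diagnosis group.
#' @param n_proteins Number of proteins.
#' @param frac_rhythmic Fraction of proteins given a diurnal rhythm in
#'   unaffected subjects.
#' @param amplitude_dist Range (low, high) of planted rhythm amplitudes.
#' @param frac_de Fraction of proteins with a nonzero diagnosis effect.
#' @param de_logfc_dist Range of |log2 fold-change| for DE proteins; signs
#'   are assigned at random.
#' @param frac_enriched Fraction of proteins enriched in synaptosomes.
#' @param enrich_fold_dist Range of linear synaptosome/homogenate folds.
#' @param n_modules,module_size Co-expression module count and size.
#' @param module_cor_by_group Named target mean within-module correlation per
#'   group (`unaffected`, `OUD`).
#' @param rhythm_loss_frac Fraction of rhythmic proteins whose amplitude is
#'   zeroed in OUD (rhythm loss).
#' @param rhythm_gain_frac Fraction of proteins rhythmic only in OUD.
#' @param noise_sd Residual noise standard deviation.
#' @param plex_sd Standard deviation of per-plex batch offsets.
#' @param covariate_effects Named slopes for `age`, `pmi`, `sexM`.
#' @param tod_sampling "uniform" over [0, 24) or "empirical-like" (deaths
#'   clustered in late night / early morning).
#' @param region Brain region label stamped on the metadata.
#' @param seed Master seed; generation is a pure function of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 20, n_proteins = 2000,
                       frac_rhythmic = 0.1, amplitude_dist = c(0.5, 1),
                       frac_de = 0.05, de_logfc_dist = c(0.3, 0.8),
                       frac_enriched = 0.2, enrich_fold_dist = c(1.25, 3),
                       n_modules = 0, module_size = 50,
                       module_cor_by_group = c(unaffected = 0.6, OUD = 0.6),
                       rhythm_loss_frac = 0.3, rhythm_gain_frac = 0,
                       noise_sd = 0.5, plex_sd = 0.2,
                       covariate_effects = c(age = 0.002, pmi = 0.005, sexM = 0.05),
                       tod_sampling = c("uniform", "empirical-like"),
                       region = "NAc", seed = 1) {
  tod_sampling <- match.arg(tod_sampling)
  cfg <- list(n_per_group = n_per_group, n_proteins = n_proteins,
              frac_rhythmic = frac_rhythmic, amplitude_dist = amplitude_dist,
              frac_de = frac_de, de_logfc_dist = de_logfc_dist,
              frac_enriched = frac_enriched, enrich_fold_dist = enrich_fold_dist,
              n_modules = n_modules, module_size = module_size,
              module_cor_by_group = module_cor_by_group,
              rhythm_loss_frac = rhythm_loss_frac,
              rhythm_gain_frac = rhythm_gain_frac,
              noise_sd = noise_sd, plex_sd = plex_sd,
              covariate_effects = covariate_effects,
              tod_sampling = tod_sampling, region = region, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  fracs <- c(cfg$frac_rhythmic, cfg$frac_de, cfg$frac_enriched,
             cfg$rhythm_loss_frac, cfg$rhythm_gain_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_per_group < 1 || cfg$n_proteins < 1) stop("counts must be positive")
  if (cfg$amplitude_dist[1] > cfg$amplitude_dist[2] ||
      cfg$enrich_fold_dist[1] > cfg$enrich_fold_dist[2] ||
      cfg$de_logfc_dist[1] > cfg$de_logfc_dist[2]) {
    stop("distribution lows must not exceed highs")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_proteins) {
    stop("module_size * n_modules exceeds n_proteins")
  }
  if (any(cfg$module_cor_by_group < 0 | cfg$module_cor_by_group >= 1)) {
    stop("module correlations must lie in [0, 1)")
  }
  invisible(cfg)
}

#' @noRd
sample_tod <- function(n, mode) {
  if (mode == "uniform") return(stats::runif(n, 0, 24))
  # death times clustered late night / early morning, with a uniform floor
  src <- stats::rbinom(n, 1, 0.6)
  t <- ifelse(src == 1, stats::rnorm(n, mean = 4, sd = 2.5), stats::runif(n, 0, 24))
  t %% 24
}

#' @noRd
sim_subjects <- function(cfg, preparation) {
  n <- cfg$n_per_group
  subject_id <- sprintf("S%03d", seq_len(2 * n))
  # case-control pairs are adjacent so that TMT blocks hold both groups
  group <- rep(c("unaffected", "OUD"), n)
  sex <- rep(rep_len(c("M", "F"), n), each = 2)
  age <- round(stats::runif(2 * n, 25, 65), 1)
  pmi <- round(stats::runif(2 * n, 5, 25), 1)
  # subject pairs assigned to TMT blocks of 10 channels
  plex <- paste0("plex", ((seq_len(2 * n) - 1L) %/% 10L) + 1L)
  tod <- sample_tod(2 * n, cfg$tod_sampling)
  sunrise <- pmin(pmax(stats::rnorm(2 * n, 6, 0.5), 4), 8)
  sunset <- pmin(pmax(stats::rnorm(2 * n, 18, 0.5), 16), 20)
  data.frame(
    sample_id = paste(subject_id, cfg$region, substr(preparation, 1, 3), sep = "_"),
    subject_id = subject_id, group = group, region = cfg$region,
    preparation = preparation, sex = sex, age = age, pmi = pmi, plex = plex,
    tod = round(tod, 4), sunrise = round(sunrise, 4), sunset = round(sunset, 4),
    stringsAsFactors = FALSE
  )
}

#' @noRd
plant_truth <- function(cfg) {
  p <- cfg$n_proteins
  protein_id <- sprintf("P%05d", seq_len(p))
  n_r <- round(cfg$frac_rhythmic * p)
  n_de <- round(cfg$frac_de * p)
  n_en <- round(cfg$frac_enriched * p)
  n_gain <- round(cfg$rhythm_gain_frac * p)

  rhythmic_u <- rep(FALSE, p)
  idx_r <- if (n_r > 0) sample.int(p, n_r) else integer(0)
  rhythmic_u[idx_r] <- TRUE
  n_loss <- round(cfg$rhythm_loss_frac * n_r)
  idx_loss <- if (n_loss > 0) sample(idx_r, n_loss) else integer(0)
  idx_gain <- if (n_gain > 0) sample(setdiff(seq_len(p), idx_r), n_gain) else integer(0)

  amp <- numeric(p)
  amp[c(idx_r, idx_gain)] <- stats::runif(length(idx_r) + length(idx_gain),
                                          cfg$amplitude_dist[1], cfg$amplitude_dist[2])
  amplitude_u <- amp
  amplitude_u[idx_gain] <- 0
  amplitude_o <- amp
  amplitude_o[idx_loss] <- 0
  rhythmic_o <- amplitude_o > 0
  phase <- stats::runif(p, 0, 24)
  phase[amp == 0] <- NA_real_

  logfc <- numeric(p)
  idx_de <- if (n_de > 0) sample.int(p, n_de) else integer(0)
  logfc[idx_de] <- stats::runif(n_de, cfg$de_logfc_dist[1], cfg$de_logfc_dist[2]) *
    sample(c(-1, 1), n_de, replace = TRUE)

  fold <- rep(1, p)
  idx_en <- if (n_en > 0) sample.int(p, n_en) else integer(0)
  fold[idx_en] <- stats::runif(n_en, cfg$enrich_fold_dist[1], cfg$enrich_fold_dist[2])

  module <- rep("grey", p)
  if (cfg$n_modules > 0) {
    idx_mod <- sample.int(p, cfg$n_modules * cfg$module_size)
    module[idx_mod] <- rep(paste0("M", seq_len(cfg$n_modules)), each = cfg$module_size)
  }

  data.frame(protein_id = protein_id,
             rhythmic_unaffected = rhythmic_u, rhythmic_oud = rhythmic_o,
             mesor = stats::runif(p, 6, 12),
             amplitude_unaffected = amplitude_u, amplitude_oud = amplitude_o,
             phase = phase, logfc = logfc, enrich_fold = fold, module = module,
             stringsAsFactors = FALSE)
}

#' @noRd
build_expression <- function(cfg, subjects, truth, plex_offset) {
  p <- cfg$n_proteins
  ns <- nrow(subjects)
  zt <- tod_to_zt(subjects$tod, subjects$sunrise)
  is_oud <- subjects$group == "OUD"
  amp <- ifelse(rep(is_oud, each = p),
                matrix(truth$amplitude_oud, p, ns),
                matrix(truth$amplitude_unaffected, p, ns))
  dim(amp) <- c(p, ns)
  phase0 <- ifelse(is.na(truth$phase), 0, truth$phase)
  rhythm <- amp * cos(outer(2 * pi * phase0 / 24, 2 * pi * zt / 24,
                            function(ph, t) t - ph))
  # outer trick above computes cos(2*pi*(zt - phase)/24) elementwise
  cov_eff <- cfg$covariate_effects
  cov_term <- cov_eff[["age"]] * subjects$age + cov_eff[["pmi"]] * subjects$pmi +
    cov_eff[["sexM"]] * (subjects$sex == "M")

  vals <- matrix(truth$mesor, p, ns) + rhythm +
    outer(truth$logfc, as.numeric(is_oud)) +
    matrix(cov_term, p, ns, byrow = TRUE) +
    matrix(plex_offset[subjects$plex], p, ns, byrow = TRUE)

  noise <- matrix(stats::rnorm(p * ns, 0, cfg$noise_sd), p, ns)
  if (cfg$n_modules > 0) {
    r <- cfg$module_cor_by_group
    for (m in unique(truth$module[truth$module != "grey"])) {
      rows <- which(truth$module == m)
      f <- stats::rnorm(ns)
      rg <- ifelse(is_oud, r[["OUD"]], r[["unaffected"]])
      shared <- matrix(sqrt(rg) * f, length(rows), ns, byrow = TRUE)
      noise[rows, ] <- cfg$noise_sd *
        (shared + matrix(sqrt(1 - rg), length(rows), ns, byrow = TRUE) *
           matrix(stats::rnorm(length(rows) * ns), length(rows), ns))
    }
  }
  vals <- vals + noise
  dimnames(vals) <- list(truth$protein_id, subjects$sample_id)
  attr(vals, "is_log2") <- TRUE
  vals
}

#' Simulate a single-preparation cohort
#'
#' Expression for protein g in sample s is
#' `mesor_g + A_{g,group(s)} * cos(2*pi*(zt_s - phase_g)/24) + logfc_g * 1[OUD]
#'  + covariate terms + plex offset + module factor + N(0, noise_sd^2)`.
#'
#' @param cfg A [sim_config()].
#' @param preparation Preparation label for the metadata.
#' @return List with `dataset` (a `pr_dataset`) and `truth` (list of
#'   `proteins` and `samples` ground-truth data.frames).
#' @export
simulate_cohort <- function(cfg, preparation = "homogenate") {
  validate_sim_config(cfg)
  with_local_seed(cfg$seed, {
    subjects <- sim_subjects(cfg, preparation)
    truth <- plant_truth(cfg)
    plexes <- unique(subjects$plex)
    plex_offset <- stats::setNames(stats::rnorm(length(plexes), 0, cfg$plex_sd), plexes)
    expr <- build_expression(cfg, subjects, truth, plex_offset)
    ds <- align_dataset(expr, subjects)
    samples <- data.frame(sample_id = subjects$sample_id, plex = subjects$plex,
                          plex_offset = unname(plex_offset[subjects$plex]),
                          tod = subjects$tod,
                          zt = tod_to_zt(subjects$tod, subjects$sunrise),
                          stringsAsFactors = FALSE)
    list(dataset = ds, truth = list(proteins = truth, samples = samples))
  })
}

#' Simulate paired homogenate and synaptosome preparations
#'
#' Both preparations share subjects and the homogenate signal; the
#' synaptosome adds `log2(enrich_fold)` for enriched proteins plus
#' independent noise, so paired differences recover the planted folds.
#'
#' @param cfg A [sim_config()].
#' @return List with `homogenate`, `synaptosome` (both `pr_dataset`) and
#'   `truth`.
#' @export
simulate_paired_preparations <- function(cfg) {
  base <- simulate_cohort(cfg, preparation = "homogenate")
  hom <- base$dataset
  truth <- base$truth
  syn_subjects <- hom$subjects
  syn_subjects$preparation <- "synaptosome"
  syn_subjects$sample_id <- paste(syn_subjects$subject_id, cfg$region, "syn", sep = "_")
  seeds <- spawn_seeds(cfg$seed, 2)
  syn_expr <- with_local_seed(seeds[2], {
    hom$expr + log2(truth$proteins$enrich_fold) +
      matrix(stats::rnorm(length(hom$expr), 0, cfg$noise_sd),
             nrow(hom$expr), ncol(hom$expr))
  })
  dimnames(syn_expr) <- list(rownames(hom$expr), syn_subjects$sample_id)
  attr(syn_expr, "is_log2") <- TRUE
  syn <- align_dataset(syn_expr, syn_subjects)
  list(homogenate = hom, synaptosome = syn, truth = truth)
}

#' Write a simulated cohort (expression, metadata, ground truth, config)
#'
#' @param sim Result of [simulate_cohort()].
#' @param cfg The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression.tsv", "metadata.tsv",
                            "truth_proteins.tsv", "truth_samples.tsv",
                            "sim_config.yaml"))
  write_expression(sim$dataset$expr, paths[1])
  utils::write.table(sim$dataset$subjects, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$proteins, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), paths[5])
  invisible(paths)
}
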