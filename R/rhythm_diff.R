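# Differential rhythmicity between diagnosis groups: delta R2 with
# independent within-group permutation nulls, gain/loss classification,
# rhythm-parameter differences, and Fisher-exact overlap of rhythmic sets.

#' @noRd
group_slice <- function(ds, group) {
  keep <- ds$subjects$group == group
  sub <- ds$subjects[keep, , drop = FALSE]
  list(Y = ds$expr[, sub$sample_id, drop = FALSE],
       zt = tod_to_zt(sub$tod, sub$sunrise))
}

#' Delta-R2 differential rhythmicity test for one protein
#'
#' Observed `delta_r2 = R2_unaffected - R2_OUD`. The null permutes ZT
#' assignments within the unaffected samples and, independently, within the
#' OUD samples, refitting both cosinors each time. The tail is chosen by the
#' sign of the observed delta (positive: loss of rhythmicity in OUD;
#' negative: gain); the class is assigned when `p_change < alpha`.
#'
#' @param ds A `pr_dataset` containing both groups.
#' @param protein_id Protein to test.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Classification threshold (default 0.05).
#' @return List: protein_id, r2_unaffected, r2_oud, delta_r2, p_change,
#'   change_class.
#' @export
delta_r2_test <- function(ds, protein_id, n_perm = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(ds, "pr_dataset"))
  if (!protein_id %in% rownames(ds$expr)) {
    stop(sprintf("protein '%s' absent from dataset", protein_id))
  }
  u <- group_slice(ds, "unaffected")
  o <- group_slice(ds, "OUD")
  if (ncol(u$Y) < 6L || ncol(o$Y) < 6L) stop("both groups need >= 6 samples")
  yu <- u$Y[protein_id, ]
  yo <- o$Y[protein_id, ]
  r2u <- fit_cosinor(yu, u$zt)$r2
  r2o <- fit_cosinor(yo, o$zt)$r2
  delta <- r2u - r2o
  Qu <- centred_harmonic_Q(u$zt)
  Qo <- centred_harmonic_Q(o$zt)
  res <- with_local_seed(seed, {
    null_u <- null_r2_one(yu, Qu, n_perm)
    null_o <- null_r2_one(yo, Qo, n_perm)
    null_delta <- null_u - null_o
    if (delta > 0) {
      p <- (1 + sum(null_delta >= delta)) / (n_perm + 1)
      cls <- "loss"
    } else if (delta < 0) {
      p <- (1 + sum(null_delta <= delta)) / (n_perm + 1)
      cls <- "gain"
    } else {
      p <- 1
      cls <- "none"
    }
    list(p = p, cls = cls)
  })
  cls <- if (res$p < alpha) res$cls else "none"
  list(protein_id = protein_id, r2_unaffected = r2u, r2_oud = r2o,
       delta_r2 = delta, p_change = res$p, change_class = cls)
}

#' Delta-R2 tests over the union of group-rhythmic proteins
#'
#' Differential rhythmicity is restricted to proteins significantly rhythmic
#' in at least one group; others are skipped with a log entry.
#'
#' @param ds A `pr_dataset` containing both groups.
#' @param fits_u,fits_o Rhythm fits per group from [cosinor_rhythmicity()].
#' @param alpha Rhythmicity and classification threshold.
#' @param n_perm,seed Permutation settings; each protein uses its own
#'   derived seed.
#' @return data.frame of delta-R2 records for the eligible proteins.
#' @export
differential_rhythmicity <- function(ds, fits_u, fits_o, alpha = 0.05,
                                     n_perm = 1000, seed = 1) {
  eligible <- union(rhythmic_set(fits_u, alpha), rhythmic_set(fits_o, alpha))
  skipped <- setdiff(rownames(ds$expr), eligible)
  if (length(skipped)) {
    pr_log("differential_rhythmicity: %d protein(s) not rhythmic in either group, skipped",
           length(skipped))
  }
  if (!length(eligible)) {
    return(data.frame(protein_id = character(0), r2_unaffected = numeric(0),
                      r2_oud = numeric(0), delta_r2 = numeric(0),
                      p_change = numeric(0), change_class = character(0)))
  }
  eligible <- sort(eligible)
  all_ids <- rownames(ds$expr)
  seeds <- spawn_seeds(seed, length(all_ids))
  names(seeds) <- all_ids
  rows <- lapply(eligible, function(pid) {
    as.data.frame(delta_r2_test(ds, pid, n_perm = n_perm, seed = seeds[[pid]],
                                alpha = alpha),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differences in rhythm parameters between groups for one protein
#'
#' Restricted to proteins rhythmic in both groups. The phase difference is
#' circular, `peak_zt_OUD - peak_zt_unaffected` mapped into (-12, 12];
#' amplitude and mesor differences are plain OUD - unaffected.
#'
#' @param fit_u,fit_o Single-protein rhythm fit rows (lists or one-row
#'   data.frames) with `amplitude`, `peak_zt`, `mesor`, and `p_emp`.
#' @param alpha Rhythmicity threshold enforced on both fits when `p_emp`
#'   is present.
#' @return List: phase_diff (hours), amplitude_diff, base_diff.
#' @export
rhythm_param_diff <- function(fit_u, fit_o, alpha = 0.05) {
  for (f in list(fit_u, fit_o)) {
    if (!is.null(f$p_emp) && !(f$p_emp < alpha)) {
      stop("rhythm parameter differences require rhythmicity in both groups")
    }
  }
  d <- (fit_o$peak_zt - fit_u$peak_zt) %% 24
  phase_diff <- d - if (d > 12) 24 else 0
  list(phase_diff = phase_diff,
       amplitude_diff = fit_o$amplitude - fit_u$amplitude,
       base_diff = fit_o$mesor - fit_u$mesor)
}

#' Fisher-exact test for overlap of two rhythmic protein sets
#'
#' Builds the 2x2 table of rhythmic/non-rhythmic membership in each group
#' over a shared background and applies the two-sided Fisher exact test.
#'
#' @param set_u,set_o Protein id sets (subsets of `background`).
#' @param background Protein universe.
#' @return List: `table_counts` (2x2 matrix), `odds_ratio` (conditional MLE),
#'   `p_fisher`.
#' @export
rhythmic_overlap_test <- function(set_u, set_o, background) {
  if (!length(background)) stop("empty background")
  if (length(setdiff(set_u, background)) || length(setdiff(set_o, background))) {
    stop("rhythmic sets must be subsets of the background")
  }
  in_u <- factor(background %in% set_u, levels = c(TRUE, FALSE))
  in_o <- factor(background %in% set_o, levels = c(TRUE, FALSE))
  tab <- table(unaffected = in_u, OUD = in_o)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table_counts = unclass(tab), odds_ratio = unname(ft$estimate),
       p_fisher = ft$p.value)
}
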