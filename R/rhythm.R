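# Time-of-death rhythmicity: ZT conversion, fixed-period cosinor fits,
# permutation empirical p-values, rhythmic-set selection, and phase-ordered
# heatmap matrices.
#
# The model is a single 24-h harmonic,
#   y = M + b1*cos(2*pi*t/24) + b2*sin(2*pi*t/24),
# which is linear in (M, b1, b2); its least-squares solution is therefore
# the exact nonlinear least-squares optimum for fixed period. Amplitude and
# peak time derive from (b1, b2).

#' Convert clock time of death to Zeitgeber Time
#'
#' ZT0 is sunrise; hours before sunrise are negative. The result is wrapped
#' into [-6, 18) so that pre-sunrise deaths keep negative ZTs.
#'
#' @param tod_clock Clock time of death, hours in [0, 24).
#' @param sunrise Sunrise clock time, hours in [0, 24).
#' @param sunset Sunset clock time; parsed and accepted but unused by the
#'   default conversion.
#' @param rescale_daylength If `TRUE`, hours are rescaled so that sunset
#'   always falls at ZT12 (daylength normalisation).
#' @return ZT hours in [-6, 18).
#' @export
tod_to_zt <- function(tod_clock, sunrise, sunset = NULL,
                      rescale_daylength = FALSE) {
  if (any(tod_clock < 0 | tod_clock >= 24) || any(sunrise < 0 | sunrise >= 24)) {
    stop("tod_clock and sunrise must lie in [0, 24)")
  }
  zt <- (tod_clock - sunrise) %% 24
  if (rescale_daylength) {
    if (is.null(sunset)) stop("daylength rescaling requires sunset")
    daylen <- (sunset - sunrise) %% 24
    zt <- ifelse(zt < daylen, 12 * zt / daylen,
                 12 + 12 * (zt - daylen) / (24 - daylen))
  }
  zt - 24 * (zt >= 18)
}

#' @noRd
cosinor_basis <- function(zt) {
  cbind(intercept = 1, c = cos(2 * pi * zt / 24), s = sin(2 * pi * zt / 24))
}

#' Fit a fixed-period (24 h) cosinor to one expression series
#'
#' @param values Numeric expression vector.
#' @param zt ZT hours, same length.
#' @return List with `mesor`, `amplitude`, `peak_zt`, `r2`.
#' @export
fit_cosinor <- function(values, zt) {
  if (length(values) != length(zt)) stop("values and zt lengths differ")
  if (length(values) < 6L) stop("cosinor fit requires >= 6 samples")
  if (length(unique(zt)) == 1L) stop("zt values are all identical")
  sst <- sum((values - mean(values))^2)
  if (sst == 0) {
    warning("constant series: amplitude and R2 set to 0")
    return(list(mesor = values[1L], amplitude = 0, peak_zt = 0, r2 = 0))
  }
  X <- cosinor_basis(zt)
  fit <- stats::lm.fit(X, values)
  b <- fit$coefficients
  sse <- sum(fit$residuals^2)
  amplitude <- sqrt(b[["c"]]^2 + b[["s"]]^2)
  peak_zt <- (atan2(b[["s"]], b[["c"]]) * 24 / (2 * pi)) %% 24
  list(mesor = unname(b[["intercept"]]), amplitude = unname(amplitude),
       peak_zt = unname(peak_zt), r2 = max(0, 1 - sse / sst))
}

#' Cosinor fits for every row of an expression matrix (vectorised)
#'
#' @param Y Proteins-by-samples matrix.
#' @param zt ZT hours per sample.
#' @return data.frame with one row per protein: mesor, amplitude, peak_zt, r2.
#' @export
fit_cosinor_matrix <- function(Y, zt) {
  if (ncol(Y) != length(zt)) stop("column count must match zt length")
  if (ncol(Y) < 6L) stop("cosinor fit requires >= 6 samples")
  X <- cosinor_basis(zt)
  qrX <- qr(X)
  B <- qr.coef(qrX, t(Y))            # 3 x p
  fitted <- X %*% B
  sse <- colSums((t(Y) - fitted)^2)
  sst <- rowSums((Y - rowMeans(Y))^2)
  amplitude <- sqrt(B["c", ]^2 + B["s", ]^2)
  peak_zt <- (atan2(B["s", ], B["c", ]) * 24 / (2 * pi)) %% 24
  r2 <- ifelse(sst > 0, pmax(0, 1 - sse / sst), 0)
  amplitude[sst == 0] <- 0
  data.frame(protein_id = rownames(Y), mesor = unname(B["intercept", ]),
             amplitude = unname(amplitude), peak_zt = unname(peak_zt),
             r2 = unname(r2), row.names = NULL, stringsAsFactors = FALSE)
}

#' @noRd
# Orthonormal basis of the centred harmonic columns; R2 of a centred y is
# ||Q'y||^2 / ||y||^2.
centred_harmonic_Q <- function(zt) {
  X <- cosinor_basis(zt)[, c("c", "s"), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  qr.Q(qr(Xc))
}

#' @noRd
# Null R2 values for one protein: permuting the ZT assignment is equivalent
# in distribution to permuting the expression vector against the fixed basis.
null_r2_one <- function(y, Q, n_perm) {
  n <- length(y)
  idx <- vapply(seq_len(n_perm), function(j) sample.int(n), integer(n))
  Yp <- matrix(y[idx], n, n_perm)
  Yc <- sweep(Yp, 2, colMeans(Yp))
  denom <- colSums(Yc^2)
  num <- colSums((crossprod(Q, Yc))^2)
  ifelse(denom > 0, num / denom, 0)
}

#' Permutation empirical p-value for rhythmicity of one protein
#'
#' The observed cosinor R2 is ranked within a null of R2 values from
#' `n_perm` random reassignments of ZT to samples; the add-one estimator
#' `(1 + #{null >= obs}) / (n_perm + 1)` avoids zero p-values.
#'
#' @param values Expression vector.
#' @param zt ZT hours.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the result is a pure function of it.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(values, zt, n_perm = 1000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: empirical p resolution is coarse")
  obs <- fit_cosinor(values, zt)$r2
  with_local_seed(seed, {
    null_r2 <- null_r2_one(values, centred_harmonic_Q(zt), n_perm)
    (1 + sum(null_r2 >= obs)) / (n_perm + 1)
  })
}

#' Cosinor fits with empirical p-values for one group of a dataset
#'
#' Fits every protein within the samples of `group`, then attaches
#' permutation empirical p-values. Each protein uses its own seeded
#' permutation stream (derived from `seed` and the protein index) so results
#' do not depend on evaluation order.
#'
#' @param ds A `pr_dataset`.
#' @param group "unaffected" or "OUD".
#' @param n_perm Permutations per protein.
#' @param seed Master seed.
#' @return data.frame of rhythm fits: protein_id, group, mesor, amplitude,
#'   peak_zt, r2, p_emp.
#' @export
cosinor_rhythmicity <- function(ds, group, n_perm = 1000, seed = 1) {
  stopifnot(inherits(ds, "pr_dataset"))
  keep <- ds$subjects$group == group
  if (sum(keep) < 6L) stop(sprintf("group '%s' has fewer than 6 samples", group))
  sub <- ds$subjects[keep, , drop = FALSE]
  Y <- ds$expr[, sub$sample_id, drop = FALSE]
  zt <- tod_to_zt(sub$tod, sub$sunrise)
  fits <- fit_cosinor_matrix(Y, zt)
  Q <- centred_harmonic_Q(zt)
  # key the per-protein seed streams by sorted id so that p-values do not
  # depend on the row order of the expression matrix
  seeds <- stats::setNames(spawn_seeds(seed, nrow(Y)), sort(rownames(Y)))
  p_emp <- vapply(seq_len(nrow(Y)), function(i) {
    with_local_seed(seeds[[rownames(Y)[i]]], {
      null_r2 <- null_r2_one(Y[i, ], Q, n_perm)
      (1 + sum(null_r2 >= fits$r2[i])) / (n_perm + 1)
    })
  }, numeric(1))
  cbind(fits[, "protein_id", drop = FALSE], group = group,
        fits[, c("mesor", "amplitude", "peak_zt", "r2")], p_emp = p_emp,
        stringsAsFactors = FALSE)
}

#' Select the rhythmic protein set at a significance level
#'
#' @param fits Output of [cosinor_rhythmicity()].
#' @param alpha Empirical p threshold (default 0.05, strict).
#' @return Character vector of protein ids with `p_emp < alpha`.
#' @export
rhythmic_set <- function(fits, alpha = 0.05) {
  fits$protein_id[fits$p_emp < alpha]
}

#' Phase-ordered, Z-scored expression matrix for heatmap display
#'
#' Selects the top proteins by ascending empirical p (ties: descending R2,
#' then id), Z-transforms each row, orders rows by peak ZT and columns by
#' sample ZT. Pass `row_order` to reuse another group's ordering while
#' re-standardising within this dataset.
#'
#' @param ds A `pr_dataset` (already restricted to the samples to display).
#' @param fits Rhythm fits for these proteins.
#' @param top_n Number of proteins to keep (default 200).
#' @param row_order Optional explicit protein ordering to apply.
#' @return List: `matrix` (Z-scored, ordered), `row_order`, `col_order`.
#' @export
phase_ordered_matrix <- function(ds, fits, top_n = 200, row_order = NULL) {
  stopifnot(inherits(ds, "pr_dataset"))
  if (is.null(row_order)) {
    fits <- fits[order(fits$p_emp, -fits$r2, fits$protein_id), , drop = FALSE]
    if (nrow(fits) < top_n) {
      pr_log("phase_ordered_matrix: only %d proteins available (top_n = %d)",
             nrow(fits), top_n)
      top_n <- nrow(fits)
    }
    sel <- fits[seq_len(top_n), , drop = FALSE]
    row_order <- sel$protein_id[order(sel$peak_zt, sel$protein_id)]
  }
  zt <- tod_to_zt(ds$subjects$tod, ds$subjects$sunrise)
  col_order <- ds$subjects$sample_id[order(zt, ds$subjects$sample_id)]
  M <- ds$expr[row_order, col_order, drop = FALSE]
  M <- t(scale(t(M)))
  M[is.nan(M)] <- 0
  list(matrix = M, row_order = row_order, col_order = col_order)
}
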