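test_that("TOD to ZT conversion anchors at sunrise and wraps into [-6, 18)", {
  expect_equal(tod_to_zt(6, 6), 0)
  expect_equal(tod_to_zt(5, 6), -1)
  expect_equal(tod_to_zt(1, 6), -5)
  expect_equal(tod_to_zt(23, 6), 17)
  # bijective over a fine grid, range respected
  grid <- seq(0, 23.75, by = 0.25)
  z <- tod_to_zt(grid, rep(6.5, length(grid)))
  expect_true(all(z >= -6 & z < 18))
  expect_equal(length(unique(round(z, 6))), length(grid))
  expect_error(tod_to_zt(25, 6), "0, 24")
})

test_that("daylength rescaling maps sunset to ZT12", {
  expect_equal(tod_to_zt(19, 5, 19, rescale_daylength = TRUE), 12)
  expect_equal(tod_to_zt(5, 5, 19, rescale_daylength = TRUE), 0)
})

test_that("cosinor recovers an exact sinusoid and handles degeneracy", {
  t <- seq(0, 22, by = 2)
  y <- 5 + 2 * cos(2 * pi * (t - 4) / 24)
  f <- fit_cosinor(y, t)
  expect_equal(f$mesor, 5, tolerance = 1e-9)
  expect_equal(f$amplitude, 2, tolerance = 1e-9)
  expect_equal(f$peak_zt, 4, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  expect_warning(f0 <- fit_cosinor(rep(3, 12), t), "constant")
  expect_equal(f0$amplitude, 0)
  expect_equal(f0$r2, 0)
  expect_error(fit_cosinor(y[1:4], t[1:4]), ">= 6")
})

test_that("matrix and single-series cosinor fits agree", {
  set.seed(42)
  t <- runif(12, -6, 18)
  Y <- matrix(rnorm(60), 5, 12, dimnames = list(paste0("P", 1:5), NULL))
  fits <- fit_cosinor_matrix(Y, t)
  for (i in 1:5) {
    f <- fit_cosinor(Y[i, ], t)
    expect_equal(fits$mesor[i], f$mesor, tolerance = 1e-10)
    expect_equal(fits$amplitude[i], f$amplitude, tolerance = 1e-10)
    expect_equal(fits$peak_zt[i], f$peak_zt, tolerance = 1e-10)
    expect_equal(fits$r2[i], f$r2, tolerance = 1e-10)
  }
})

test_that("cosinor fit is invariant to affine y transforms and zt shifts", {
  set.seed(7)
  t <- runif(20, -6, 18)
  y <- 2 + 0.8 * cos(2 * pi * (t - 9) / 24) + rnorm(20, 0, 0.5)
  f <- fit_cosinor(y, t)
  f_aff <- fit_cosinor(3 * y + 1, t)
  expect_equal(f_aff$r2, f$r2, tolerance = 1e-10)
  expect_equal(f_aff$peak_zt, f$peak_zt, tolerance = 1e-8)
  f_shift <- fit_cosinor(y, t + 5)
  expect_equal(f_shift$peak_zt, (f$peak_zt + 5) %% 24, tolerance = 1e-8)
  expect_equal(f_shift$r2, f$r2, tolerance = 1e-10)
})

test_that("empirical p is deterministic, bounded below, and saturates for a pure rhythm", {
  t <- seq(0.5, 23.5, by = 2)
  y <- 1 + 3 * cos(2 * pi * (t - 10) / 24) + rnorm(12, 0, 0.01)
  p1 <- empirical_p(y, t, n_perm = 500, seed = 99)
  p2 <- empirical_p(y, t, n_perm = 500, seed = 99)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 501)
  expect_warning(empirical_p(y, t, n_perm = 50, seed = 1), "resolution|coarse")
})

test_that("empirical p is monotone in observed R2 for a fixed permutation set", {
  set.seed(12)
  t <- runif(16, -6, 18)
  base <- rnorm(16)
  signal <- cos(2 * pi * (t - 3) / 24)
  p_of <- function(w) empirical_p(base * 0.5 + w * signal, t, n_perm = 300, seed = 5)
  # same seed => same permutations; stronger signal must not raise p
  ps <- vapply(c(0, 0.5, 1, 2, 4), p_of, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("rhythmic_set thresholds strictly and per-protein streams are order-stable", {
  fits <- data.frame(protein_id = c("A", "B", "C"),
                     p_emp = c(0.001, 0.05, 1))
  expect_equal(rhythmic_set(fits), "A")
  expect_equal(rhythmic_set(fits, alpha = 0.06), c("A", "B"))

  cfg <- sim_config(n_per_group = 10, n_proteins = 12, frac_rhythmic = 0.5,
                    seed = 4)
  sim <- simulate_cohort(cfg)
  f_all <- cosinor_rhythmicity(sim$dataset, "unaffected", n_perm = 200, seed = 8)
  ds_rev <- sim$dataset
  ds_rev$expr <- ds_rev$expr[rev(rownames(ds_rev$expr)), ]
  f_rev <- cosinor_rhythmicity(ds_rev, "unaffected", n_perm = 200, seed = 8)
  m <- match(f_all$protein_id, f_rev$protein_id)
  expect_equal(f_all$p_emp, f_rev$p_emp[m])
})

test_that("phase-ordered matrix is Z-scored, ordered, and reusable across groups", {
  cfg <- sim_config(n_per_group = 12, n_proteins = 40, frac_rhythmic = 0.5,
                    rhythm_loss_frac = 0, noise_sd = 0.1, seed = 21)
  sim <- simulate_cohort(cfg)
  ds_u <- subset_dataset(sim$dataset,
    samples = sim$dataset$subjects$sample_id[sim$dataset$subjects$group == "unaffected"])
  fits <- cosinor_rhythmicity(ds_u, "unaffected", n_perm = 200, seed = 3)
  res <- phase_ordered_matrix(ds_u, fits, top_n = 10)
  expect_equal(unname(rowMeans(res$matrix)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(res$matrix, 1, sd)), rep(1, 10), tolerance = 1e-12)
  peak <- fits$peak_zt[match(res$row_order, fits$protein_id)]
  expect_true(all(diff(peak) >= 0))
  zt <- tod_to_zt(ds_u$subjects$tod, ds_u$subjects$sunrise)
  expect_true(all(diff(zt[match(res$col_order, ds_u$subjects$sample_id)]) >= 0))

  # applying the unaffected ordering to the OUD samples keeps rows fixed
  ds_o <- subset_dataset(sim$dataset,
    samples = sim$dataset$subjects$sample_id[sim$dataset$subjects$group == "OUD"])
  res_o <- phase_ordered_matrix(ds_o, fits, row_order = res$row_order)
  expect_identical(res_o$row_order, res$row_order)
  expect_equal(unname(rowMeans(res_o$matrix)), rep(0, 10), tolerance = 1e-12)

  # asking for more proteins than available falls back to all, with a log note
  expect_message(res_all <- phase_ordered_matrix(ds_u, fits, top_n = 100),
                 "available")
  expect_equal(nrow(res_all$matrix), 40)
})
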