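test_that("group mean differences are recovered exactly without covariates", {
  vals <- matrix(5, 4, 12, dimnames = list(paste0("P", 1:4), NULL))
  vals[, 7:12] <- vals[, 7:12] + 1  # OUD samples higher by 1 log2 unit
  ds <- make_dataset(vals, group = rep(c("unaffected", "OUD"), each = 6))
  de <- fit_de(ds, covariates = character(0), moderate = FALSE)
  expect_equal(de$logfc, rep(1, 4), tolerance = 1e-12)

  ds0 <- make_dataset(matrix(rep(rnorm(4), 12), 4, 12),
                      group = rep(c("unaffected", "OUD"), each = 6))
  de0 <- classify_de(fit_de(ds0, covariates = character(0), moderate = FALSE))
  expect_equal(de0$logfc, rep(0, 4), tolerance = 1e-12)
  expect_true(all(de0$de_flag == "none"))
})

test_that("unmoderated statistics match an independent least-squares oracle", {
  set.seed(31)
  n <- 20
  group <- rep(c("unaffected", "OUD"), each = 10)
  age <- runif(n, 25, 65)
  vals <- matrix(rnorm(20 * n), 20, n, dimnames = list(sprintf("P%02d", 1:20), NULL))
  ds <- make_dataset(vals, group = group, age = age)
  de <- fit_de(ds, covariates = "age", moderate = FALSE)
  X <- cbind(1, as.numeric(group == "OUD"), age)
  for (i in 1:20) {
    o <- ols_oracle(vals[i, ], X)
    expect_equal(de$logfc[i], o$coef[2], tolerance = 1e-10)
    expect_equal(de$t_mod[i], o$t[2], tolerance = 1e-10)
    expect_equal(de$p[i], o$p[2], tolerance = 1e-10)
  }
})

test_that("moderated p-values approach unmoderated ones as prior df vanishes", {
  cfg <- sim_config(n_per_group = 8, n_proteins = 60, frac_de = 0.2, seed = 13)
  ds <- simulate_cohort(cfg)$dataset
  de_mod <- fit_de(ds, covariates = "age")
  de_ord <- fit_de(ds, covariates = "age", moderate = FALSE)
  # moderation shrinks toward the pooled prior: ordering of evidence is kept
  expect_gt(cor(-log10(de_mod$p), -log10(de_ord$p)), 0.95)
  expect_true(all(de_mod$df_total >= de_ord$df_total))
})

test_that("design problems raise targeted errors", {
  vals <- matrix(rnorm(40), 4, 10)
  group <- rep(c("unaffected", "OUD"), each = 5)
  ds <- make_dataset(vals, group = group,
                     plex = rep(c("p1", "p2"), each = 5))
  expect_error(fit_de(ds, covariates = "plex"), "collinear")

  ds_small <- make_dataset(vals[, 1:7, drop = FALSE],
                           group = c(rep("unaffected", 5), "OUD", "OUD"))
  expect_error(fit_de(ds_small, covariates = character(0)), "fewer than 3")
})

test_that("classify_de applies both thresholds with inclusive boundaries", {
  rec <- data.frame(protein_id = paste0("P", 1:5),
                    logfc = c(0.30, 0.26, 0.20, 0.50, -0.26),
                    p = c(0.04, 0.04, 0.04, 0.06, 0.05))
  out <- classify_de(rec)
  expect_equal(out$de_flag, c("up", "up", "none", "none", "down"))
  # monotone: decreasing p or increasing |logfc| never turns a call off
  stronger <- transform(rec, p = p / 2, logfc = logfc * 1.5)
  out2 <- classify_de(stronger)
  called <- out$de_flag != "none"
  expect_true(all(out2$de_flag[called] != "none"))
})

test_that("RRHO grid matches the enumerated worked example and symmetry checks", {
  set.seed(5)
  rec <- data.frame(protein_id = sprintf("P%02d", 1:8),
                    logfc = c(2, 1.5, 1, 0.5, -0.5, -1, -1.5, -2),
                    p = c(0.001, 0.005, 0.01, 0.2, 0.3, 0.01, 0.004, 0.002))
  m <- rrho_map(rec, rec, step = 2)
  # top-2 sets identical: overlap 2 of 2 over N=8
  expect_equal(m$grid[1, 1], -log10(enum_hyper_upper(2, 2, 6, 2)), tolerance = 1e-12)
  expect_equal(m$grid[1, 1], -log10(1 / 28), tolerance = 1e-12)
  diag_max <- max(diag(m$grid))
  off_max <- max(m$grid[row(m$grid) != col(m$grid)])
  expect_gt(diag_max, off_max)  # self-concordance peaks on the diagonal

  # negated scores reverse the ranking: enrichment vanishes and the
  # diagonal no longer dominates the map
  neg <- transform(rec, logfc = -logfc)
  m2 <- rrho_map(rec, neg, step = 2)
  expect_gte(max(m2$grid[row(m2$grid) != col(m2$grid)]), max(diag(m2$grid)))
  expect_lt(max(m2$grid), diag_max)

  # invariance to order-preserving transforms of the ranking scores
  rec_scaled <- transform(rec, p = p^2)  # -log10 p doubled: same order
  m3 <- rrho_map(rec_scaled, rec_scaled, step = 2)
  expect_equal(m3$grid, m$grid)

  expect_error(rrho_map(rec[1:3, ], rec[1:3, ], step = 2), "at least")
})

test_that("overlap_counts computes exact directional set intersections", {
  a <- data.frame(protein_id = c("P1", "P2", "P3"),
                  de_flag = c("up", "up", "down"))
  b <- data.frame(protein_id = c("P2", "P3", "P4"),
                  de_flag = c("up", "down", "up"))
  oc <- overlap_counts(a, b)
  expect_equal(oc$shared, c(1, 1))
  expect_equal(oc$a_only, c(1, 0))
  expect_equal(oc$b_only, c(1, 0))
  same <- overlap_counts(a, a)
  expect_equal(same$shared, c(2, 1))
  expect_equal(same$a_only + same$b_only, c(0, 0))
})
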