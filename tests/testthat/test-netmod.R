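test_that("adjacency matches a direct correlation oracle and its contracts", {
  set.seed(11)
  Y <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("P", 1:5), paste0("s", 1:6)))
  A <- build_adjacency(Y, beta = 3)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(A[i, j], abs(cor(Y[i, ], Y[j, ]))^3, tolerance = 1e-12)
  }
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)), rep(1, 5))
  expect_true(all(A >= 0 & A <= 1))

  # perfectly correlated pair: adjacency 1 at any power
  Y2 <- rbind(P1 = 1:6, P2 = 2 * (1:6) + 3, P3 = rnorm(6))
  A2 <- build_adjacency(Y2, beta = 7)
  expect_equal(A2["P1", "P2"], 1, tolerance = 1e-12)

  # soft-thresholding drives weak correlations toward zero as beta grows
  set.seed(12)
  Yn <- matrix(rnorm(400), 4, 100)
  rownames(Yn) <- paste0("P", 1:4)
  a2 <- build_adjacency(Yn, beta = 2)
  a12 <- build_adjacency(Yn, beta = 12)
  expect_lt(max(a12[upper.tri(a12)]), max(a2[upper.tri(a2)]))

  # constant rows are dropped with a log entry
  Yc <- rbind(Yn, P5 = rep(1, 100))
  expect_message(Ac <- build_adjacency(Yc, beta = 2), "constant")
  expect_equal(nrow(Ac), 4)
})

test_that("adjacency and downstream results are invariant to protein order and affine rescaling", {
  set.seed(13)
  Y <- matrix(rnorm(80), 8, 10, dimnames = list(paste0("P", 1:8), paste0("s", 1:10)))
  A <- build_adjacency(Y, beta = 4)
  Yr <- Y[sample(8), ]
  Ar <- build_adjacency(Yr, beta = 4)
  expect_equal(Ar[rownames(A), colnames(A)], A, tolerance = 1e-12,
               ignore_attr = "beta")
  Ys <- Y
  Ys[3, ] <- 5 * Y[3, ] - 2
  expect_equal(build_adjacency(Ys, beta = 4), A, tolerance = 1e-12)
})

test_that("module detection recovers planted blocks and leaves noise grey", {
  cfg <- sim_config(n_per_group = 30, n_proteins = 120, n_modules = 2,
                    module_size = 35,
                    module_cor_by_group = c(unaffected = 0.8, OUD = 0.8),
                    frac_rhythmic = 0, frac_de = 0, plex_sd = 0,
                    covariate_effects = c(age = 0, pmi = 0, sexM = 0), seed = 19)
  sim <- simulate_cohort(cfg)
  adj <- build_adjacency(sim$dataset, beta = 6)
  mods <- detect_modules(adj, expr = sim$dataset, min_size = 20)
  truth <- sim$truth$proteins$module
  expect_gte(rand_index(mods, truth), 0.95)
  # the two planted blocks map to two non-grey labels
  expect_gte(length(setdiff(unique(mods), "grey")), 2)

  # pure-noise input: no block structure survives the minimum size
  cfg0 <- sim_config(n_per_group = 30, n_proteins = 60, n_modules = 0,
                     frac_rhythmic = 0, frac_de = 0, plex_sd = 0,
                     covariate_effects = c(age = 0, pmi = 0, sexM = 0), seed = 23)
  sim0 <- simulate_cohort(cfg0)
  mods0 <- detect_modules(build_adjacency(sim0$dataset, beta = 6),
                          expr = sim0$dataset, min_size = 30)
  expect_true(all(mods0 == "grey") || max(table(mods0[mods0 != "grey"])) < 60)

  # permuting protein order yields the same partition up to labels
  perm <- sample(nrow(sim$dataset$expr))
  adj_p <- adj[perm, perm]
  mods_p <- detect_modules(adj_p, expr = sim$dataset$expr[perm, ], min_size = 20)
  expect_equal(rand_index(mods_p[names(mods)], mods), 1)
})

test_that("MDC is exactly 1 for identical groups and detects attenuated coupling", {
  cfg <- sim_config(n_per_group = 20, n_proteins = 80, n_modules = 1,
                    module_size = 20, frac_rhythmic = 0, frac_de = 0, seed = 29)
  sim <- simulate_cohort(cfg)
  members <- sim$truth$proteins$protein_id[sim$truth$proteins$module == "M1"]
  ds <- sim$dataset
  r <- mdc_test(ds, ds, members, n_perm = 200, seed = 1)
  expect_equal(r$mdc, 1, tolerance = 1e-12)
  expect_equal(r$direction, "unchanged")

  # swapped arguments give the reciprocal MDC
  cfg2 <- sim_config(n_per_group = 20, n_proteins = 80, n_modules = 1,
                     module_size = 20,
                     module_cor_by_group = c(unaffected = 0.7, OUD = 0.2),
                     frac_rhythmic = 0, frac_de = 0, seed = 31)
  sim2 <- simulate_cohort(cfg2)
  m2 <- sim2$truth$proteins$protein_id[sim2$truth$proteins$module == "M1"]
  ids_u <- sim2$dataset$subjects$sample_id[sim2$dataset$subjects$group == "unaffected"]
  ds_u <- subset_dataset(sim2$dataset, samples = ids_u)
  ds_o <- subset_dataset(sim2$dataset,
                         samples = setdiff(sim2$dataset$subjects$sample_id, ids_u))
  fwd <- mdc_test(ds_u, ds_o, m2, n_perm = 300, seed = 2)
  rev <- mdc_test(ds_o, ds_u, m2, n_perm = 300, seed = 2)
  expect_equal(fwd$mdc, 1 / rev$mdc, tolerance = 1e-12)
  expect_equal(fwd$direction, "loss")
  expect_equal(rev$direction, "gain")
  expect_lt(fwd$mdc, 1)

  expect_error(mdc_test(ds_u, ds_o, m2[1:2], n_perm = 100), ">= 3")
})

test_that("hub calling matches a brute-force BFS oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 10
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    dimnames(A) <- list(paste0("P", 1:n), paste0("P", 1:n))
    for (hops in 1:2) {
      h <- identify_hubs(A, rownames(A), quantile = 0.9, n_hops = hops)
      off <- A[upper.tri(A)]
      thr <- quantile(off, 0.9, names = FALSE)
      E <- A > thr
      diag(E) <- FALSE
      nhnn <- bfs_nhnn(E, hops)
      expect_equal(unname(h$nhnn), nhnn)
      expect_setequal(h$hubs, rownames(A)[nhnn > mean(nhnn)])
    }
  }
})

test_that("hub degenerate and star topologies behave as specified", {
  n <- 6
  A <- matrix(0.5, n, n)
  diag(A) <- 1
  dimnames(A) <- list(paste0("P", 1:n), paste0("P", 1:n))
  h <- identify_hubs(A, rownames(A))
  expect_equal(length(h$hubs), 0)  # no strict exceedance, no edges

  star <- matrix(0.1, n, n)
  star[1, ] <- star[, 1] <- 0.9
  diag(star) <- 1
  dimnames(star) <- dimnames(A)
  # with 5 of 15 off-diagonal values at 0.9, the 90th percentile equals 0.9
  # and the strict threshold keeps no edges; the median keeps the spokes only
  hs <- identify_hubs(star, rownames(star), quantile = 0.5, n_hops = 1)
  expect_equal(hs$hubs, "P1")

  expect_warning(h2 <- identify_hubs(A, c("P1", "P2")), "smaller")
  expect_equal(length(h2$hubs), 0)
})

test_that("disease-specific hubs are plain set algebra", {
  d <- disease_specific_hubs(c("A", "B"), c("B", "C"))
  expect_equal(d, list(unaffected_only = "A", oud_only = "C", shared = "B"))
  d2 <- disease_specific_hubs(c("A", "B"), c("A", "B"))
  expect_equal(length(d2$unaffected_only) + length(d2$oud_only), 0)
  d3 <- disease_specific_hubs("A", "B")
  expect_equal(length(d3$shared), 0)
})

test_that("module flag enrichment matches enumeration", {
  bg <- paste0("P", 1:10)
  res <- module_flag_enrichment(bg[1:4], bg[1:4], bg)
  expect_equal(res$p_hyper, enum_hyper_upper(4, 4, 6, 4), tolerance = 1e-12)
  expect_equal(res$p_hyper, 1 / 210, tolerance = 1e-12)

  res_all <- module_flag_enrichment(bg[1:4], bg, bg)
  expect_equal(res_all$p_hyper, 1)
  expect_equal(res_all$fold, 1)

  res0 <- module_flag_enrichment(bg[1:4], bg[9:10], bg)
  expect_gt(res0$p_hyper, 0.5)

  set.seed(50)
  for (i in 1:10) {
    n_bg <- sample(10:30, 1)
    bgi <- paste0("P", seq_len(n_bg))
    mem <- sample(bgi, sample(3:8, 1))
    fl <- sample(bgi, sample(3:8, 1))
    r <- module_flag_enrichment(mem, fl, bgi)
    expect_equal(r$p_hyper,
                 enum_hyper_upper(length(intersect(mem, fl)), length(fl),
                                  n_bg - length(fl), length(mem)),
                 tolerance = 1e-12)
  }
})

test_that("soft power selection prefers small powers on strongly modular data", {
  cfg <- sim_config(n_per_group = 25, n_proteins = 90, n_modules = 3,
                    module_size = 30,
                    module_cor_by_group = c(unaffected = 0.7, OUD = 0.7),
                    frac_rhythmic = 0, frac_de = 0, seed = 37)
  sim <- simulate_cohort(cfg)
  ps <- pick_soft_power(sim$dataset)
  expect_true(ps$beta %in% 1:20)
  expect_equal(nrow(ps$fit_table), 20)
})
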