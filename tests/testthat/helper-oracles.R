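# Independent oracles and small fixture builders used across test files.

# Build a pr_dataset directly from a matrix and minimal metadata.
make_dataset <- function(values, group, tod = NULL, sunrise = 6,
                         subject_id = NULL, preparation = "homogenate",
                         region = "NAc", plex = "plex1", sex = "M",
                         age = 40, pmi = 12) {
  n <- ncol(values)
  if (is.null(tod)) tod <- seq(0, 24 - 24 / n, length.out = n)
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_len(n))
  sample_id <- paste(subject_id, region, substr(preparation, 1, 3), sep = "_")
  colnames(values) <- sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  subjects <- data.frame(sample_id = sample_id, subject_id = subject_id,
                         group = rep_len(group, n), region = region,
                         preparation = preparation,
                         sex = rep_len(sex, n), age = rep_len(age, n),
                         pmi = rep_len(pmi, n), plex = rep_len(plex, n),
                         tod = rep_len(tod, n) %% 24,
                         sunrise = rep_len(sunrise, n),
                         sunset = rep_len(18, n), stringsAsFactors = FALSE)
  align_dataset(values, subjects)
}

# Brute-force cosinor oracle: coarse grid over (mesor-profiled amplitude,
# phase), then Nelder-Mead refinement of the raw SSE. Independent of the
# closed-form harmonic regression it checks.
cosinor_grid_oracle <- function(y, t) {
  sse_fun <- function(par) {
    sum((y - (par[1] + par[2] * cos(2 * pi * (t - par[3]) / 24)))^2)
  }
  amps <- seq(0, 2 * stats::sd(y) * 2, by = 0.05)
  phis <- seq(0, 23.95, by = 0.05)
  best <- c(mean(y), 0, 0)
  best_sse <- sse_fun(best)
  for (A in amps) {
    cosmat <- cos(2 * pi * outer(t, phis, "-") / 24)  # n x length(phis)
    res <- y - A * cosmat
    M <- colMeans(res)
    sse <- colSums((res - rep(M, each = length(t)))^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best <- c(M[j], A, phis[j])
    }
  }
  opt <- stats::optim(best, sse_fun, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 20000))
  par <- opt$par
  if (par[2] < 0) {
    par[2] <- -par[2]
    par[3] <- par[3] + 12
  }
  sst <- sum((y - mean(y))^2)
  list(mesor = par[1], amplitude = par[2], peak_zt = par[3] %% 24,
       r2 = 1 - opt$value / sst)
}

# Exhaustive hypergeometric upper tail by direct enumeration.
enum_hyper_upper <- function(q, m, n, k) {
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= q])
}

# Two-sided Fisher exact p by enumerating all tables with fixed margins.
enum_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  obs <- choose(c1, tab[1, 1]) * choose(N - c1, tab[1, 2]) / choose(N, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Per-protein least-squares oracle via the normal equations.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  t_stat <- b / se
  list(coef = unname(drop(b)), t = unname(drop(t_stat)),
       p = unname(2 * stats::pt(-abs(drop(t_stat)), df)))
}

# BFS n-hop neighborhood counts on a logical adjacency matrix.
bfs_nhnn <- function(E, n_hops) {
  m <- nrow(E)
  vapply(seq_len(m), function(i) {
    frontier <- i
    seen <- rep(FALSE, m)
    seen[i] <- TRUE
    for (h in seq_len(n_hops)) {
      nxt <- which(apply(E[frontier, , drop = FALSE], 2, any) & !seen)
      if (!length(nxt)) break
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    sum(seen) - 1L
  }, integer(1))
}

# Adjusted-for-chance agreement between two partitions (Rand index).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
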