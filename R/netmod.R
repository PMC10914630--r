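# Weighted co-expression networks: soft-thresholded adjacency, topological
# overlap, module detection, module differential connectivity (MDC) with a
# two-scheme permutation null, quantile-thresholded neighbor graphs with
# NHNN hub calling, and module enrichment for flagged protein sets.

#' Soft-thresholded co-expression adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned, the default) or
#' `((1 + cor)/2)^beta` (signed). Constant proteins have undefined
#' correlations and are dropped with a log entry.
#'
#' @param x A `pr_dataset` or proteins-by-samples matrix.
#' @param beta Soft power.
#' @param method Correlation type passed to [stats::cor()].
#' @param signed Use the signed transform instead of |cor|.
#' @return Symmetric adjacency matrix in [0, 1] with unit diagonal and
#'   attribute `beta`.
#' @export
build_adjacency <- function(x, beta = 6, method = "pearson", signed = FALSE) {
  Y <- if (inherits(x, "pr_dataset")) x$expr else x
  if (ncol(Y) < 4L) stop("adjacency requires >= 4 samples")
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0)) {
    pr_log("build_adjacency: dropped %d constant protein(s)", sum(sds == 0))
    Y <- Y[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(Y), method = method)
  A <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(A) <- 1
  attr(A, "beta") <- beta
  A
}

#' Choose a soft power by the scale-free topology criterion
#'
#' Returns the smallest integer power in `powers` for which the scale-free
#' model fit (signed R2 of log10 p(k) vs log10 k) reaches `target_r2`;
#' falls back to `fallback` when none qualifies.
#'
#' @param x A `pr_dataset` or matrix.
#' @param powers Candidate powers (default 1:20).
#' @param target_r2 Required fit (default 0.8).
#' @param fallback Power used when no candidate reaches the target.
#' @param n_bins Degree-histogram bins for the fit.
#' @return List: `beta`, `fit_table` (power, r2, slope, mean_k).
#' @export
pick_soft_power <- function(x, powers = 1:20, target_r2 = 0.8, fallback = 6,
                            n_bins = 10) {
  Y <- if (inherits(x, "pr_dataset")) x$expr else x
  r <- abs(stats::cor(t(Y)))
  diag(r) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(r^b)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, r2 = fit$r2, slope = fit$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$power[tab$r2 >= target_r2]
  list(beta = if (length(ok)) min(ok) else fallback, fit_table = tab)
}

#' @noRd
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(list(r2 = 0, slope = 0))
  cuts <- cut(k, n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- as.numeric(table(cuts)) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3L) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = -sign(slope) * r2, slope = unname(slope))
}

#' Topological overlap similarity from an adjacency matrix
#'
#' @param adj Adjacency matrix from [build_adjacency()].
#' @return TOM similarity matrix (unit diagonal).
#' @export
tom_similarity <- function(adj) {
  A <- adj
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

# WGCNA-style color sequence for module labels, assigned by decreasing size.
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue",
                    "darkred", "darkgreen", "darkturquoise", "darkgrey",
                    "orange", "darkorange", "white", "skyblue", "saddlebrown",
                    "steelblue")

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut at a fixed
#' fraction of the dendrogram height; clusters below `min_size` are assigned
#' to "grey". When expression is supplied, modules whose summary profiles
#' (first principal component of member expression) correlate above
#' `1 - merge_cut` are merged iteratively. Labels are color names ordered by
#' decreasing module size.
#'
#' @param adj Adjacency matrix.
#' @param expr Optional proteins-by-samples matrix (or `pr_dataset`) used
#'   for eigenprotein merging; merging is skipped when absent.
#' @param min_size Minimum module size (default 30).
#' @param merge_cut Eigenprotein dissimilarity below which modules merge
#'   (default 0.25).
#' @param cut_height Tree-cut height as a fraction of the maximum merge
#'   height (default 0.99).
#' @return Named character vector: module label per protein ("grey" =
#'   unassigned).
#' @export
detect_modules <- function(adj, expr = NULL, min_size = 30, merge_cut = 0.25,
                           cut_height = 0.99) {
  ids <- rownames(adj)
  if (nrow(adj) < min_size) {
    warning("fewer proteins than min_size: all assigned to grey")
    return(stats::setNames(rep("grey", nrow(adj)), ids))
  }
  tom <- tom_similarity(adj)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height * max(hc$height))
  labels <- ifelse(tabulate(cl)[cl] >= min_size, paste0("m", cl), "grey")
  names(labels) <- ids

  if (!is.null(expr) && length(unique(labels[labels != "grey"])) > 1L) {
    Y <- if (inherits(expr, "pr_dataset")) expr$expr else expr
    Y <- Y[ids, , drop = FALSE]
    repeat {
      mods <- unique(labels[labels != "grey"])
      if (length(mods) < 2L) break
      me <- vapply(mods, function(m) module_eigenprotein(Y[labels == m, , drop = FALSE]),
                   numeric(ncol(Y)))
      cc <- stats::cor(me)
      diag(cc) <- -Inf
      best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      if (max(cc) <= 1 - merge_cut) break
      labels[labels == mods[best[2L]]] <- mods[best[1L]]
    }
  }
  relabel_by_size(labels)
}

#' @noRd
relabel_by_size <- function(labels) {
  mods <- setdiff(names(sort(table(labels[labels != "grey"]), decreasing = TRUE)),
                  "grey")
  new <- c(.MODULE_COLORS, paste0("module", seq_len(max(0, length(mods) -
                                                          length(.MODULE_COLORS)))))
  map <- stats::setNames(new[seq_along(mods)], mods)
  out <- ifelse(labels == "grey", "grey", map[labels])
  stats::setNames(out, names(labels))
}

#' First principal component of a module's expression (eigenprotein)
#'
#' Rows are standardised first; the sign is anchored to correlate
#' positively with the mean profile.
#'
#' @param Y Member-by-sample expression matrix.
#' @return Numeric vector of length `ncol(Y)`.
#' @export
module_eigenprotein <- function(Y) {
  Z <- t(scale(t(Y)))
  Z[is.nan(Z)] <- 0
  sv <- svd(Z, nu = 0, nv = 1)
  v <- sv$v[, 1L]
  if (stats::cor(v, colMeans(Z)) < 0) v <- -v
  v
}

#' @noRd
# Mean off-diagonal soft-thresholded adjacency among the rows of Y;
# the size-normalised within-module connectivity.
connectivity_stat <- function(Y, beta, stat = "mean") {
  m <- nrow(Y)
  Yc <- Y - rowMeans(Y)
  s <- sqrt(rowSums(Yc^2))
  R <- tcrossprod(Yc / s)
  tot <- sum(abs(R)^beta) - m   # off-diagonal mass (diagonal is exactly m)
  if (stat == "mean") tot / (m * (m - 1)) else tot / 2
}

#' @noRd
# Same statistic read off a precomputed full adjacency matrix.
connectivity_from_adj <- function(adj, members, stat = "mean") {
  m <- length(members)
  tot <- sum(adj[members, members]) - sum(diag(adj[members, members]))
  if (stat == "mean") tot / (m * (m - 1)) else tot / 2
}

#' Module differential connectivity test
#'
#' `MDC = connectivity_OUD / connectivity_unaffected`, where connectivity is
#' the mean off-diagonal within-module adjacency. Significance combines two
#' permutation nulls: (1) sample-group labels permuted; (2) module members
#' replaced by random protein sets of equal size. The tail follows the
#' observed direction; `p_mdc` is the maximum of the two scheme p-values
#' (conservative). For modules built on unaffected subjects, significant
#' MDC < 1 is a loss and MDC > 1 a gain of connectivity in OUD.
#'
#' @param ds_u,ds_o `pr_dataset`s (or matrices) for the two groups, sharing
#'   the protein universe.
#' @param members Module member protein ids.
#' @param beta Soft power.
#' @param n_perm Permutations per scheme (default 1000).
#' @param seed Integer seed.
#' @param alpha Direction-call threshold (default 0.05).
#' @param stat Connectivity statistic: size-normalised "mean" (default) or
#'   summed degree.
#' @param adj_u,adj_o Optional precomputed full adjacency matrices for the
#'   two groups (as from [build_adjacency()]); used to speed up the
#'   member-permutation null when testing many modules on one dataset pair.
#' @return List: mdc, p_mdc, direction, connectivity_unaffected,
#'   connectivity_oud, p_sample_perm, p_member_perm.
#' @export
mdc_test <- function(ds_u, ds_o, members, beta = 6, n_perm = 1000, seed = 1,
                     alpha = 0.05, stat = "mean", adj_u = NULL, adj_o = NULL) {
  Yu <- if (inherits(ds_u, "pr_dataset")) ds_u$expr else ds_u
  Yo <- if (inherits(ds_o, "pr_dataset")) ds_o$expr else ds_o
  if (length(members) < 3L) stop("module must have >= 3 members")
  missing <- setdiff(members, intersect(rownames(Yu), rownames(Yo)))
  if (length(missing)) stop("module members absent from a dataset")
  ku <- connectivity_stat(Yu[members, , drop = FALSE], beta, stat)
  ko <- connectivity_stat(Yo[members, , drop = FALSE], beta, stat)
  if (ku <= 0) stop("zero connectivity in unaffected group")
  mdc <- ko / ku
  universe <- intersect(rownames(Yu), rownames(Yo))
  nu <- ncol(Yu)
  comb <- cbind(Yu[members, , drop = FALSE], Yo[members, , drop = FALSE])
  res <- with_local_seed(seed, {
    null_sample <- vapply(seq_len(n_perm), function(j) {
      idx <- sample.int(ncol(comb))
      pu <- connectivity_stat(comb[, idx[seq_len(nu)], drop = FALSE], beta, stat)
      po <- connectivity_stat(comb[, idx[-seq_len(nu)], drop = FALSE], beta, stat)
      po / pu
    }, numeric(1))
    null_member <- vapply(seq_len(n_perm), function(j) {
      mem <- sample(universe, length(members))
      if (!is.null(adj_u) && !is.null(adj_o)) {
        connectivity_from_adj(adj_o, mem, stat) /
          connectivity_from_adj(adj_u, mem, stat)
      } else {
        connectivity_stat(Yo[mem, , drop = FALSE], beta, stat) /
          connectivity_stat(Yu[mem, , drop = FALSE], beta, stat)
      }
    }, numeric(1))
    list(s = null_sample, m = null_member)
  })
  tail_p <- function(null_vals) {
    if (mdc >= 1) (1 + sum(null_vals >= mdc)) / (n_perm + 1)
    else (1 + sum(null_vals <= mdc)) / (n_perm + 1)
  }
  p_s <- tail_p(res$s)
  p_m <- tail_p(res$m)
  p_mdc <- max(p_s, p_m)
  direction <- if (p_mdc < alpha && mdc > 1) "gain"
               else if (p_mdc < alpha && mdc < 1) "loss"
               else "unchanged"
  list(mdc = mdc, p_mdc = p_mdc, direction = direction,
       connectivity_unaffected = ku, connectivity_oud = ko,
       p_sample_perm = p_s, p_member_perm = p_m)
}

#' Identify hub proteins by N-hop neighborhood size (NHNN)
#'
#' Two members are neighbors when their adjacency strictly exceeds the 90th
#' quantile of off-diagonal within-module adjacency. NHNN is the number of
#' distinct nodes within `n_hops` of a protein in that graph; hubs have
#' NHNN strictly above the module mean.
#'
#' @param adj Adjacency matrix.
#' @param members Module member ids.
#' @param quantile Adjacency quantile defining neighbors (default 0.90).
#' @param n_hops Neighborhood order (default 1).
#' @return List: `hubs` (character vector), `nhnn` (named counts),
#'   `threshold`.
#' @export
identify_hubs <- function(adj, members, quantile = 0.90, n_hops = 1) {
  if (length(setdiff(members, rownames(adj)))) stop("members absent from adjacency")
  if (length(members) < 3L) {
    warning("module smaller than 3: no hubs")
    return(list(hubs = character(0),
                nhnn = stats::setNames(integer(length(members)), members),
                threshold = NA_real_))
  }
  A <- adj[members, members, drop = FALSE]
  off <- A[upper.tri(A)]
  thr <- stats::quantile(off, probs = quantile, names = FALSE)
  E <- (A > thr)
  diag(E) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(E, mode = "max")
  nhnn <- igraph::ego_size(g, order = n_hops, mindist = 1)
  names(nhnn) <- members
  hubs <- members[nhnn > mean(nhnn)]
  list(hubs = hubs, nhnn = nhnn, threshold = thr)
}

#' Disease-specific hub proteins
#'
#' @param hubs_u,hubs_o Hub sets called in unaffected and OUD networks.
#' @return List: `unaffected_only`, `oud_only`, `shared`.
#' @export
disease_specific_hubs <- function(hubs_u, hubs_o) {
  list(unaffected_only = sort(setdiff(hubs_u, hubs_o)),
       oud_only = sort(setdiff(hubs_o, hubs_u)),
       shared = sort(intersect(hubs_u, hubs_o)))
}

#' Hypergeometric enrichment of a module for a flagged protein set
#'
#' Upper-tail hypergeometric p for the overlap between module members and a
#' flagged set (e.g. DE or rhythmic proteins) over a background.
#'
#' @param members Module member ids.
#' @param flagged Flagged protein ids.
#' @param background Protein universe.
#' @return List: p_hyper, fold (observed / expected overlap), overlap.
#' @export
module_flag_enrichment <- function(members, flagged, background) {
  if (!length(background)) stop("empty background")
  members <- intersect(members, background)
  flagged <- intersect(flagged, background)
  ov <- length(intersect(members, flagged))
  N <- length(background)
  p <- stats::phyper(ov - 1, m = length(flagged), n = N - length(flagged),
                     k = length(members), lower.tail = FALSE)
  expected <- length(members) * length(flagged) / N
  list(p_hyper = p, fold = if (expected > 0) ov / expected else NA_real_,
       overlap = ov)
}
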