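# Covariate-adjusted differential expression (OUD vs unaffected),
# DE classification, rank-rank hypergeometric overlap, and cross-region
# overlap counts.
#
# Per-protein linear models and empirical-Bayes variance moderation are
# delegated to limma; voom precision weights are not used because TMT
# log-intensities are not counts. A limma-trend option (mean-dependent
# variance prior) is available and off by default.

#' Covariate-adjusted differential expression
#'
#' Fits, per protein, a linear model of log2 expression on a diagnosis
#' indicator plus covariates, and moderates residual variances with
#' empirical Bayes. `logfc > 0` means higher expression in OUD.
#'
#' @param ds A `pr_dataset` containing both groups.
#' @param covariates Metadata column names to adjust for, e.g.
#'   `c("plex", "sex", "age", "pmi")`. Non-numeric columns become factors.
#' @param moderate If `FALSE`, report ordinary (unmoderated) t statistics
#'   and p-values.
#' @param trend Use a mean-dependent variance prior (limma-trend).
#' @param extra_covariates Optional data.frame of additional per-sample
#'   covariates (rows aligned to samples), e.g. a total peptide signal.
#' @return data.frame: protein_id, logfc, t_mod, p, df_total, fdr, de_flag
#'   (all "none" until [classify_de()]).
#' @export
fit_de <- function(ds, covariates = c("plex", "sex", "age", "pmi"),
                   moderate = TRUE, trend = FALSE, extra_covariates = NULL) {
  stopifnot(inherits(ds, "pr_dataset"))
  meta <- ds$subjects
  tab <- table(meta$group)
  if (length(tab) < 2L) stop("both diagnosis groups must be present")
  if (any(tab < 3L)) stop("fewer than 3 samples in a group")
  covariates <- intersect(covariates, colnames(meta))
  df <- data.frame(group = factor(meta$group, levels = c("unaffected", "OUD")))
  for (cv in covariates) {
    v <- meta[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  if (!is.null(extra_covariates)) {
    stopifnot(nrow(extra_covariates) == nrow(meta))
    df <- cbind(df, extra_covariates)
  }
  design <- stats::model.matrix(~ ., data = df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop(sprintf("covariate(s) collinear with the design: %s",
                 paste(aliased, collapse = ", ")))
  }
  fit <- limma::lmFit(ds$expr, design)
  coef_name <- "groupOUD"
  logfc <- fit$coefficients[, coef_name]
  if (moderate) {
    eb <- limma::eBayes(fit, trend = trend)
    t_stat <- eb$t[, coef_name]
    p <- eb$p.value[, coef_name]
    df_total <- eb$df.total
  } else {
    t_stat <- logfc / (fit$stdev.unscaled[, coef_name] * fit$sigma)
    df_total <- rep(fit$df.residual[1L], length(t_stat))
    p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  }
  data.frame(protein_id = rownames(ds$expr), logfc = unname(logfc),
             t_mod = unname(t_stat), p = unname(p),
             df_total = unname(df_total),
             fdr = stats::p.adjust(p, "BH"),
             de_flag = "none", row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify differential expression at fixed thresholds
#'
#' A protein is `up` if `p <= p_max` and `logfc >= lfc_min`, `down` if
#' `p <= p_max` and `logfc <= -lfc_min`, otherwise `none`. Boundaries are
#' included. The default `lfc_min = 0.26` corresponds to a 20% change in
#' linear expression.
#'
#' @param records Output of [fit_de()].
#' @param p_max Unadjusted p threshold (default 0.05).
#' @param lfc_min Minimum |log2 fold-change| (default 0.26).
#' @return `records` with `de_flag` set.
#' @export
classify_de <- function(records, p_max = 0.05, lfc_min = 0.26) {
  flag <- rep("none", nrow(records))
  flag[records$p <= p_max & records$logfc >= lfc_min] <- "up"
  flag[records$p <= p_max & records$logfc <= -lfc_min] <- "down"
  records$de_flag <- flag
  records
}

#' @noRd
rrho_rank <- function(records) {
  score <- -log10(records$p) * sign(records$logfc)
  records$protein_id[order(-score, records$protein_id)]
}

#' Rank-rank hypergeometric overlap map
#'
#' Proteins are ranked in each table by the signed score
#' `-log10(p) * sign(logfc)` (most upregulated first; ties broken by id).
#' For each pair of rank thresholds `(i*step, j*step)` the grid holds
#' `-log10` of the hypergeometric upper-tail probability of the overlap of
#' the two top sets.
#'
#' @param recordsA,recordsB DE tables over the same protein universe (the
#'   intersection is taken and logged).
#' @param step Rank stride between grid thresholds.
#' @return List: `grid` (matrix of -log10 p, A thresholds in rows),
#'   `thresholds`, `step`, `n`.
#' @export
rrho_map <- function(recordsA, recordsB, step = 1) {
  common <- intersect(recordsA$protein_id, recordsB$protein_id)
  dropped <- length(union(recordsA$protein_id, recordsB$protein_id)) - length(common)
  if (dropped > 0L) pr_log("rrho_map: %d protein(s) outside the shared universe dropped", dropped)
  N <- length(common)
  if (N < 2L * step) stop("rrho_map needs at least 2*step shared proteins")
  ra <- rrho_rank(recordsA[recordsA$protein_id %in% common, , drop = FALSE])
  rb <- rrho_rank(recordsB[recordsB$protein_id %in% common, , drop = FALSE])
  # position of each protein in list B, addressed by its rank in list A
  pos_b <- match(ra, rb)
  thresholds <- pmin(seq_len(ceiling(N / step)) * step, N)
  K <- length(thresholds)
  grid <- matrix(0, K, K, dimnames = list(A = thresholds, B = thresholds))
  for (i in seq_len(K)) {
    in_top_b <- sort.int(pos_b[seq_len(thresholds[i])])
    ov <- findInterval(thresholds, in_top_b)  # overlap counts per B threshold
    p <- stats::phyper(ov - 1, m = thresholds[i], n = N - thresholds[i],
                       k = thresholds, lower.tail = FALSE)
    grid[i, ] <- -log10(pmax(p, .Machine$double.xmin))
  }
  list(grid = grid, thresholds = thresholds, step = step, n = N)
}

#' Directional overlap counts between two DE tables
#'
#' @param flagsA,flagsB Classified DE tables (with `de_flag`).
#' @return data.frame with one row per direction: shared, A-only and B-only
#'   counts.
#' @export
overlap_counts <- function(flagsA, flagsB) {
  out <- lapply(c("up", "down"), function(dir) {
    a <- flagsA$protein_id[flagsA$de_flag == dir]
    b <- flagsB$protein_id[flagsB$de_flag == dir]
    data.frame(direction = dir, shared = length(intersect(a, b)),
               a_only = length(setdiff(a, b)), b_only = length(setdiff(b, a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
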