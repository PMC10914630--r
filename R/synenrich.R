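# Synapse-enrichment classification: paired synaptosome-vs-homogenate
# comparison within a diagnosis group, Bonferroni control, and restriction
# of synaptosome analyses to enriched proteins.

#' Paired synaptosome-vs-homogenate enrichment statistics
#'
#' For each protein, paired (by subject) log2 differences synaptosome -
#' homogenate are tested one-sided for a positive mean (greater abundance in
#' synaptosomes), with Bonferroni correction over the proteins tested.
#' Depleted proteins are non-enriched by construction.
#'
#' @param hom,syn `pr_dataset`s for the two preparations.
#' @param group Diagnosis group to analyse ("unaffected" or "OUD").
#' @param paired If `FALSE`, fall back to an unpaired one-sided Welch test.
#' @return data.frame: protein_id, log2_ratio, fold, p_raw, p_bonf,
#'   enriched (FALSE until [classify_enriched()]), n_pairs.
#' @export
compute_enrichment <- function(hom, syn, group, paired = TRUE) {
  stopifnot(inherits(hom, "pr_dataset"), inherits(syn, "pr_dataset"))
  proteins <- intersect(rownames(hom$expr), rownames(syn$expr))
  if (!length(proteins)) stop("preparations share no proteins")
  hs <- hom$subjects[hom$subjects$group == group, , drop = FALSE]
  ss <- syn$subjects[syn$subjects$group == group, , drop = FALSE]
  shared <- intersect(hs$subject_id, ss$subject_id)
  excluded <- length(union(hs$subject_id, ss$subject_id)) - length(shared)
  if (excluded > 0L) {
    pr_log("compute_enrichment: %d subject(s) lack one preparation, excluded", excluded)
  }
  if (length(shared) < 3L) stop("fewer than 3 paired subjects in the requested group")
  hcol <- hs$sample_id[match(shared, hs$subject_id)]
  scol <- ss$sample_id[match(shared, ss$subject_id)]
  if (paired) {
    D <- syn$expr[proteins, scol, drop = FALSE] - hom$expr[proteins, hcol, drop = FALSE]
    n <- length(shared)
    dbar <- rowMeans(D)
    sd_d <- sqrt(rowSums((D - dbar)^2) / (n - 1))
    t_stat <- ifelse(sd_d > 0, dbar * sqrt(n) / sd_d,
                     ifelse(dbar > 0, Inf, -Inf))
    p_raw <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  } else {
    H <- hom$expr[proteins, hcol, drop = FALSE]
    S <- syn$expr[proteins, scol, drop = FALSE]
    n <- length(shared)
    dbar <- rowMeans(S) - rowMeans(H)
    vh <- apply(H, 1, stats::var) / n
    vs <- apply(S, 1, stats::var) / n
    t_stat <- dbar / sqrt(vh + vs)
    df_w <- (vh + vs)^2 / (vh^2 / (n - 1) + vs^2 / (n - 1))
    p_raw <- stats::pt(t_stat, df = df_w, lower.tail = FALSE)
  }
  m <- length(proteins)
  data.frame(protein_id = proteins, log2_ratio = unname(dbar),
             fold = unname(2^dbar), p_raw = unname(p_raw),
             p_bonf = pmin(1, unname(p_raw) * m),
             enriched = FALSE, n_pairs = length(shared),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify synapse-enriched proteins
#'
#' Enriched means Bonferroni-corrected p below `alpha` AND a linear fold of
#' at least `fold_min` (boundary included). All other proteins are
#' non-enriched by default.
#'
#' @param records Output of [compute_enrichment()].
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param fold_min Minimum linear synaptosome/homogenate fold (default 1.25).
#' @return `records` with `enriched` set.
#' @export
classify_enriched <- function(records, alpha = 0.05, fold_min = 1.25) {
  records$enriched <- records$p_bonf < alpha & records$fold >= fold_min
  records
}

#' Restrict a synaptosome dataset to enriched proteins
#'
#' @param syn Synaptosome `pr_dataset`.
#' @param records Classified enrichment records (or a list of per-group
#'   record tables, combined by union).
#' @return `pr_dataset` limited to enriched proteins.
#' @export
filter_to_enriched <- function(syn, records) {
  if (is.data.frame(records)) records <- list(records)
  enriched <- sort(unique(unlist(lapply(records, function(r) {
    r$protein_id[r$enriched]
  }))))
  if (!length(enriched)) {
    stop("no enriched proteins; review alpha/fold_min thresholds")
  }
  keep <- intersect(rownames(syn$expr), enriched)
  pr_log("filter_to_enriched: keeping %d of %d protein(s)", length(keep),
         nrow(syn$expr))
  subset_dataset(syn, proteins = keep)
}
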