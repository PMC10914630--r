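# Generic over-representation analysis against GMT gene-set collections.

#' Read a gene-set collection from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are removed with a log entry.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors with attribute `source`.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      pr_log("load_gmt: removed %d duplicate member(s) in set '%s'",
             sum(duplicated(members)), fields[1])
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("empty set '%s' at line %d", fields[1], i))
    sets[[fields[1]]] <- members
  }
  attr(sets, "source") <- basename(path)
  sets
}

#' Over-representation analysis of a protein set
#'
#' Each gene set is intersected with the background, then the overlap with
#' the query is tested by the upper-tail hypergeometric distribution; BH
#' adjustment is applied across tested sets. The enrichment score is the
#' count of query hits divided by the count of background proteins in the
#' set.
#'
#' @param query Query protein ids (must be within `background`).
#' @param background Background protein universe (e.g. all quantified
#'   proteins in the preparation analysed).
#' @param sets Collection from [load_gmt()] (or any named list).
#' @param min_size,max_size Post-intersection set-size bounds; sets outside
#'   are skipped (defaults 3 and 2000).
#' @return data.frame: set, n_query_hits, n_set_in_background, p_hyper,
#'   p_adj, enrichment_score.
#' @export
run_ora <- function(query, background, sets, min_size = 3, max_size = 2000) {
  if (!length(query) || !length(background)) stop("empty query or background")
  if (length(setdiff(query, background))) {
    stop("query contains ids absent from the background")
  }
  query <- unique(query)
  background <- unique(background)
  N <- length(background)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    K <- length(s)
    if (K < min_size || K > max_size) return(NULL)
    hits <- length(intersect(query, s))
    p <- stats::phyper(hits - 1, m = K, n = N - K, k = length(query),
                       lower.tail = FALSE)
    data.frame(set = nm, n_query_hits = hits, n_set_in_background = K,
               p_hyper = p, enrichment_score = hits / K,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), n_query_hits = integer(0),
                      n_set_in_background = integer(0), p_hyper = numeric(0),
                      p_adj = numeric(0), enrichment_score = numeric(0)))
  }
  out$p_adj <- stats::p.adjust(out$p_hyper, "BH")
  out[, c("set", "n_query_hits", "n_set_in_background", "p_hyper", "p_adj",
          "enrichment_score")]
}
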