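# Data model and file I/O shared by all analysis stages.
#
# The central container is a `pr_dataset`: a log2 protein-by-sample
# expression matrix plus a subject metadata table aligned column-for-row.

.GROUPS <- c("unaffected", "OUD")
.REGIONS <- c("NAc", "DLPFC")
.PREPARATIONS <- c("homogenate", "synaptosome")

.META_COLS <- c("sample_id", "subject_id", "group", "region", "preparation",
                "sex", "age", "pmi", "plex", "tod", "sunrise", "sunset")

#' Read a protein expression matrix from TSV
#'
#' The file must have a header of sample identifiers with a first column
#' named `protein_id`. Empty cells are treated as missing.
#'
#' @param path Path to a tab-separated file.
#' @param already_log2 If `FALSE`, values are replaced by
#'   `log2(value + pseudocount)`.
#' @param pseudocount Offset added before the log2 transform of linear-scale
#'   input. Default 1.
#' @return A numeric matrix (proteins x samples) with attribute
#'   `is_log2 = TRUE`.
#' @export
load_expression <- function(path, already_log2 = TRUE, pseudocount = 1) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (ncol(raw) < 2L) stop("expression TSV needs protein_id plus >=1 sample column")
  ids <- as.character(raw[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate protein id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  samp <- colnames(raw)[-1L]
  dups <- samp[duplicated(samp)]
  if (length(dups)) {
    stop(sprintf("duplicate sample id(s): %s", paste(unique(dups), collapse = ", ")))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in seq_len(ncol(vals))) {
      bad <- which(!is.na(raw[[j + 1L]]) & is.na(suppressWarnings(as.numeric(raw[[j + 1L]]))))
      if (length(bad)) {
        stop(sprintf("non-numeric value at row %d, column '%s'", bad[1L], samp[j]))
      }
    }
    vals <- matrix(suppressWarnings(as.numeric(vals)), nrow = nrow(raw),
                   dimnames = list(NULL, samp))
  }
  rownames(vals) <- ids
  if (!already_log2) {
    if (any(vals + pseudocount <= 0, na.rm = TRUE)) {
      stop("non-positive intensities after pseudocount; cannot log2-transform")
    }
    vals <- log2(vals + pseudocount)
    pr_log("applied log2(x + %g) to linear-scale input", pseudocount)
  }
  attr(vals, "is_log2") <- TRUE
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [load_expression()]: round-trips values at full precision.
#' @param expr Numeric matrix with protein row names and sample column names.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(protein_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read subject metadata from TSV
#'
#' Required columns: sample_id, subject_id, group, region, preparation, sex,
#' age, pmi, plex, tod, sunrise, sunset. Clock fields accept "HH:MM" or
#' decimal hours in [0, 24).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame of subject records, one row per sample.
#' @export
load_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.META_COLS, colnames(df))
  if (length(missing_cols)) {
    stop(sprintf("metadata missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    warning("metadata file has a header but no rows")
    df <- df[, .META_COLS, drop = FALSE]
    return(validate_metadata(df, allow_empty = TRUE))
  }
  df <- df[, .META_COLS, drop = FALSE]
  for (col in c("tod", "sunrise", "sunset")) df[[col]] <- parse_clock(df[[col]])
  validate_metadata(df)
}

#' @noRd
validate_metadata <- function(df, allow_empty = FALSE) {
  if (nrow(df) == 0L && allow_empty) return(df)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad_group <- setdiff(unique(df$group), .GROUPS)
  if (length(bad_group)) {
    stop(sprintf("group value(s) outside {%s}: %s", paste(.GROUPS, collapse = ", "),
                 paste(bad_group, collapse = ", ")))
  }
  bad_region <- setdiff(unique(df$region), .REGIONS)
  if (length(bad_region)) {
    stop(sprintf("region value(s) outside {%s}: %s", paste(.REGIONS, collapse = ", "),
                 paste(bad_region, collapse = ", ")))
  }
  bad_prep <- setdiff(unique(df$preparation), .PREPARATIONS)
  if (length(bad_prep)) {
    stop(sprintf("preparation value(s) outside {%s}: %s",
                 paste(.PREPARATIONS, collapse = ", "),
                 paste(bad_prep, collapse = ", ")))
  }
  for (col in c("tod", "sunrise", "sunset")) {
    if (!is.numeric(df[[col]]) || any(df[[col]] < 0 | df[[col]] >= 24)) {
      stop(sprintf("'%s' must be numeric hours in [0, 24)", col))
    }
  }
  key <- paste(df$subject_id, df$region, df$preparation)
  if (anyDuplicated(key)) {
    stop("a subject contributes more than one sample for the same (region, preparation)")
  }
  df
}

#' Combine an expression matrix and metadata into an aligned dataset
#'
#' Restricts both inputs to their common samples and orders expression
#' columns to the metadata row order. Dropped samples are logged.
#'
#' @param expr Matrix from [load_expression()] (or equivalent).
#' @param subjects Metadata data.frame from [load_metadata()].
#' @param max_missing_frac Proteins with a larger fraction of missing values
#'   in either diagnosis group are dropped (default 0: complete rows only).
#' @return A `pr_dataset` list with elements `expr` and `subjects`.
#' @export
align_dataset <- function(expr, subjects, max_missing_frac = 0) {
  common <- intersect(subjects$sample_id, colnames(expr))
  if (length(common) == 0L) stop("expression and metadata share no sample ids")
  dropped <- length(union(subjects$sample_id, colnames(expr))) - length(common)
  if (dropped > 0L) pr_log("align_dataset: dropped %d unmatched sample(s)", dropped)
  subjects <- subjects[subjects$sample_id %in% common, , drop = FALSE]
  expr <- expr[, subjects$sample_id, drop = FALSE]

  miss <- is.na(expr)
  if (any(miss)) {
    keep <- rep(TRUE, nrow(expr))
    for (g in intersect(.GROUPS, unique(subjects$group))) {
      cols <- subjects$group == g
      frac <- rowMeans(miss[, cols, drop = FALSE])
      keep <- keep & (frac <= max_missing_frac)
    }
    # rows that pass the per-group missingness filter must still be complete
    keep <- keep & rowSums(miss) == 0L
    if (any(!keep)) {
      pr_log("align_dataset: dropped %d protein(s) with missing values", sum(!keep))
    }
    expr <- expr[keep, , drop = FALSE]
  }
  if (!all(is.finite(expr))) stop("non-finite expression values after missing-value handling")
  structure(list(expr = expr, subjects = subjects), class = "pr_dataset")
}

#' @export
print.pr_dataset <- function(x, ...) {
  cat(sprintf("pr_dataset: %d proteins x %d samples (%s)\n",
              nrow(x$expr), ncol(x$expr),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", ")))
  invisible(x)
}

#' Restrict a dataset to a subset of samples and/or proteins
#' @param ds A `pr_dataset`.
#' @param samples Sample ids to keep (default all).
#' @param proteins Protein ids to keep (default all).
#' @return A `pr_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, proteins = NULL) {
  stopifnot(inherits(ds, "pr_dataset"))
  if (!is.null(samples)) {
    keep <- ds$subjects$sample_id %in% samples
    ds$subjects <- ds$subjects[keep, , drop = FALSE]
    ds$expr <- ds$expr[, ds$subjects$sample_id, drop = FALSE]
  }
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, rownames(ds$expr))
    if (length(missing)) stop(sprintf("unknown protein id(s): %s",
                                      paste(utils::head(missing, 5), collapse = ", ")))
    ds$expr <- ds$expr[proteins, , drop = FALSE]
  }
  ds
}
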