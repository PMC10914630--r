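# Internal helpers: seeding, logging, small numeric utilities.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive independent integer sub-seeds from one master seed
#'
#' Each random stage (per-protein permutations, per-replicate simulations)
#' draws its own seed from the master stream so that results do not depend
#' on evaluation order.
#' @noRd
spawn_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max, n))
}

#' @noRd
pr_log <- function(fmt, ...) {
  message(sprintf(paste0("[proteorhythm] ", fmt), ...))
}

#' Parse a clock time given as "HH:MM" or decimal hours
#' @noRd
parse_clock <- function(x) {
  x <- as.character(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (grepl(":", v, fixed = TRUE)) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
        stop(sprintf("unparseable clock time '%s'", v), call. = FALSE)
      }
      out[i] <- as.numeric(parts[1]) + as.numeric(parts[2]) / 60
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) stop(sprintf("unparseable clock time '%s'", v), call. = FALSE)
      out[i] <- num
    }
  }
  if (any(out < 0 | out >= 24)) {
    stop("clock times must lie in [0, 24)", call. = FALSE)
  }
  out
}
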