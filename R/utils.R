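#' Derive a child seed from a global seed and a stage label
#'
#' All stochastic stages (simulation, unlinked-pair subsampling, permutation
#' nulls) draw their own seed from the pipeline's global seed so that each
#' stage is individually reproducible.
#'
#' @param seed integer global seed.
#' @param label character stage label, e.g. `"simulate"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # stay well inside 32-bit integer range
  as.integer((abs(seed) %% 1048573) * 2039 + (h %% 1048573) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# column means ignoring NA, returning 0 for all-NA columns
col_means_na <- function(m) {
  cm <- colMeans(m, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  cm
}

# mean-impute missing dosages per variant (columns)
impute_dosages <- function(dos) {
  if (!anyNA(dos)) return(dos)
  cm <- col_means_na(dos)
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- cm[idx[, 2L]]
  dos
}
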