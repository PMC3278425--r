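#' @importFrom rlang %||%
#' @importFrom generics tidy glance
#' @importFrom tibble as_tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tibble::as_tibble

# derive a per-repeat RNG seed from a base seed; stays within 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 1e6) * 2039 + i * 9973 + 1)
}

# run expr with a locally-set seed when one is supplied
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# column means over non-missing entries; NaN (all-missing column) -> NA
column_means <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- NA_real_
  mu
}

# paired-t p-value of a difference vector; NA when degenerate
safe_paired_p <- function(d) {
  if (length(d) < 2 || stats::sd(d) == 0) return(NA_real_)
  tryCatch(stats::t.test(d)$p.value, error = function(e) NA_real_)
}

# replace missing entries of matrix m column-wise with means mu
impute_with_means <- function(m, mu) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mu[j]
  }
  m
}
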