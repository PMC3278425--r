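# Independent oracles and small dataset builders used across tests.

# closed-form OLS by the normal equations (independent of the package's
# lm.fit-based path); returns c(intercept, slopes...)
ols_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  drop(solve(crossprod(X), crossprod(X, y)))
}

# textbook paired t-test on a difference vector
paired_t_oracle <- function(d) {
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t_stat,
       p_value = 2 * pt(-abs(t_stat), df = n - 1))
}

# pooled-variance two-sample t-test
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t_stat,
       p_value = 2 * pt(-abs(t_stat), df = na + nb - 2))
}

# literal per-subject evaluation of the stratification rule + fallback
brute_stratify <- function(train, target, thresholds, min_group_size, pair,
                           fallback = "either") {
  df <- as_tibble(train)
  keep <- vapply(seq_len(nrow(df)), function(i) {
    ok <- TRUE
    for (nm in names(thresholds)) {
      v <- df[[nm]][i]
      if (is.na(v) || abs(v - target[[nm]]) > thresholds[[nm]]) ok <- FALSE
    }
    ok
  }, logical(1))
  grp <- group_labels(train)
  n_a <- sum(keep & grp == pair$group_a)
  n_b <- sum(keep & grp == pair$group_b)
  below <- c(n_a, n_b) < min_group_size
  fall <- if (fallback == "either") any(below) else all(below)
  if (fall) seq_len(nrow(df)) else which(keep)
}

# quick nuis_data builder from vectors
toy_nuis <- function(group, features = list(), nuisances = list(),
                     group_levels = NULL) {
  n <- length(group)
  df <- tibble::tibble(subject_id = sprintf("t%03d", seq_len(n)),
                       group = group)
  for (nm in names(features)) df[[nm]] <- features[[nm]]
  for (nm in names(nuisances)) df[[nm]] <- nuisances[[nm]]
  as_nuis_data(df, id = "subject_id", group = "group",
               features = names(features), nuisances = names(nuisances),
               group_levels = group_levels)
}
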