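#' Pre-select classification features
#'
#' A feature is kept when (a) its fraction of missing values among the
#' pair's subjects is at most `max_missing_fraction` and (b) the two-sample
#' t-test p-value between the two study groups is at most `p_threshold`.
#' The pooled-variance (equal-variance) test is the default, the data being
#' treated as normally distributed; a Welch variant is available.
#'
#' @param data A `nuis_data`.
#' @param pair A [group_pair()]; both groups must be present.
#' @param max_missing_fraction Maximum tolerated missing fraction
#'   (default 0.10).
#' @param p_threshold t-test p-value cut-off. The motivating study used
#'   1e-5 for the easy (control vs patient) pair and 0.01 for the hard
#'   (stable vs progressive) pair, chosen to retain comparable feature
#'   counts.
#' @param var_equal Use the pooled-variance t statistic (default `TRUE`).
#' @return Character vector of retained feature names.
#' @export
preselect_features <- function(data, pair, max_missing_fraction = 0.10,
                               p_threshold = 0.01, var_equal = TRUE) {
  stopifnot(inherits(data, "nuis_data"), inherits(pair, "group_pair"),
            max_missing_fraction > 0, max_missing_fraction <= 1,
            p_threshold > 0, p_threshold <= 1)
  idx <- pair_indices(data, pair)
  if (length(idx) == 0) stop("no subjects in the study groups", call. = FALSE)
  sub <- subset_subjects(data, idx)
  grp <- group_labels(sub)
  if (!all(c(pair$group_a, pair$group_b) %in% grp)) {
    stop("both study groups must be present", call. = FALSE)
  }
  C <- block_matrix(sub, feature_names(sub))
  testable <- FALSE
  keep <- vapply(feature_names(sub), function(f) {
    v <- C[, f]
    if (mean(is.na(v)) > max_missing_fraction) return(FALSE)
    a <- v[grp == pair$group_a & !is.na(v)]
    b <- v[grp == pair$group_b & !is.na(v)]
    if (length(a) < 2 || length(b) < 2) return(FALSE)
    if (stats::var(a) == 0 && stats::var(b) == 0) return(FALSE)
    testable <<- TRUE
    p <- stats::t.test(a, b, var.equal = var_equal)$p.value
    p <= p_threshold
  }, logical(1))
  if (!testable) {
    stop("no feature has at least 2 non-missing values per group",
         call. = FALSE)
  }
  feature_names(sub)[keep]
}

#' Balance study groups with SMOTE oversampling
#'
#' Equalizes the two study-group counts by adding synthetic minority-class
#' subjects: each synthetic sample is a convex combination
#' `x + u * (x_nn - x)`, `u ~ U(0, 1)`, of a minority subject and one of its
#' `k_neighbors` nearest minority neighbours (Euclidean distance on the
#' classification-feature block, missing entries imputed with minority
#' means). Original subjects are preserved; subjects outside the pair (e.g.
#' a reference group) pass through unchanged.
#'
#' @param train Training `nuis_data`.
#' @param pair A [group_pair()].
#' @param k_neighbors Number of nearest minority neighbours to interpolate
#'   toward (default 5, capped at minority size minus one).
#' @param seed Optional integer seed for the interpolation draws.
#' @return A `nuis_data` with equal counts in the two study groups.
#' @export
smote_balance <- function(train, pair, k_neighbors = 5, seed = NULL) {
  stopifnot(inherits(train, "nuis_data"), inherits(pair, "group_pair"),
            k_neighbors >= 1)
  grp <- group_labels(train)
  n_a <- sum(grp == pair$group_a)
  n_b <- sum(grp == pair$group_b)
  if (n_a == n_b) return(train)
  minority <- if (n_a < n_b) pair$group_a else pair$group_b
  n_min <- min(n_a, n_b)
  n_syn <- abs(n_a - n_b)
  if (n_min < 2) {
    stop("minority group has fewer than 2 subjects; SMOTE needs a neighbour",
         call. = FALSE)
  }
  k <- min(k_neighbors, n_min - 1)

  min_idx <- which(grp == minority)
  num_cols <- c(feature_names(train), nuisance_names(train))
  M <- as.matrix(train$data[min_idx, num_cols, drop = FALSE])
  storage.mode(M) <- "double"
  M <- impute_with_means(M, column_means(M))
  Feat <- M[, feature_names(train), drop = FALSE]

  # k nearest minority neighbours by Euclidean distance on features
  D <- as.matrix(stats::dist(Feat))
  diag(D) <- Inf
  nn <- t(matrix(apply(D, 1, function(d) order(d)[seq_len(k)]), nrow = k))

  syn <- with_opt_seed(seed, {
    base <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    M[base, , drop = FALSE] + u * (M[pick, , drop = FALSE] -
                                     M[base, , drop = FALSE])
  })

  new_rows <- train$data[rep(min_idx[1], n_syn), , drop = FALSE]
  new_rows[[train$id]] <- sprintf("synthetic_%s_%04d", minority,
                                  seq_len(n_syn))
  new_rows[[train$group]] <- minority
  for (col in num_cols) new_rows[[col]] <- syn[, col]

  out <- train
  out$data <- dplyr::bind_rows(train$data, new_rows)
  out
}

# residual sum of squares of OLS y ~ [1, X[, cols]]; NULL rank marker on
# rank deficiency relative to the expected column count
ols_rss <- function(X, y, cols) {
  Xm <- cbind(1, X[, cols, drop = FALSE])
  fit <- stats::lm.fit(Xm, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank, p = ncol(Xm))
}

# partial-F p-value for the nested comparison rss_small (q params) vs
# rss_big (q+1 params) on n observations
partial_f_p <- function(rss_small, rss_big, n, q_big) {
  df2 <- n - q_big
  if (df2 < 1) return(NA_real_)
  if (rss_big <= 0) return(0)
  f <- (rss_small - rss_big) / (rss_big / df2)
  stats::pf(max(f, 0), 1, df2, lower.tail = FALSE)
}

#' Stepwise feature selection by partial F-tests
#'
#' Forward-entry / backward-removal selection for an ordinary-least-squares
#' model of a 0/1 label on candidate features. Starting from the empty
#' model, each step adds the excluded feature with the smallest partial-F
#' p-value if it is below `p_enter`, then repeatedly removes the included
#' feature with the largest partial-F p-value while it exceeds `p_remove`,
#' until a fixed point (or `max_steps`).
#'
#' Constant columns are skipped; a candidate collinear with the current
#' selection is skipped with a warning.
#'
#' @param x Numeric matrix of candidate features (named columns).
#' @param y Numeric 0/1 label vector.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must exceed `p_enter`.
#' @param max_steps Iteration guard (default 100).
#' @return Character vector of selected column names (possibly empty).
#' @export
stepwise_select <- function(x, y, p_enter = 0.05, p_remove = 0.10,
                            max_steps = 100) {
  stopifnot(is.matrix(x), is.numeric(y), nrow(x) == length(y),
            p_enter > 0, p_enter < p_remove, p_remove < 1)
  if (ncol(x) == 0) return(character(0))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  sds <- apply(x, 2, stats::sd)
  candidates <- colnames(x)[!is.na(sds) & sds > 0]
  selected <- character()
  if (length(candidates) == 0) return(selected)

  for (step in seq_len(max_steps)) {
    changed <- FALSE
    ## forward entry
    outside <- setdiff(candidates, selected)
    if (length(outside) > 0) {
      base <- ols_rss(x, y, selected)
      p_add <- vapply(outside, function(f) {
        big <- ols_rss(x, y, c(selected, f))
        if (big$rank < big$p) {
          warning("skipping collinear candidate feature '", f, "'",
                  call. = FALSE)
          return(NA_real_)
        }
        partial_f_p(base$rss, big$rss, n, big$p)
      }, numeric(1))
      if (any(!is.na(p_add)) && min(p_add, na.rm = TRUE) < p_enter) {
        selected <- c(selected, outside[which.min(p_add)])
        changed <- TRUE
      }
    }
    ## backward removal, one at a time, largest p first
    repeat {
      if (length(selected) == 0) break
      full <- ols_rss(x, y, selected)
      p_drop <- vapply(selected, function(f) {
        small <- ols_rss(x, y, setdiff(selected, f))
        partial_f_p(small$rss, full$rss, n, full$p)
      }, numeric(1))
      worst <- which.max(p_drop)
      if (length(worst) == 1 && !is.na(p_drop[worst]) &&
          p_drop[worst] > p_remove) {
        selected <- setdiff(selected, selected[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  selected
}

#' Train the linear regression classifier
#'
#' The full training pipeline for one study-group pair: restrict to the two
#' study groups, impute missing feature values with training means, balance
#' the groups with [smote_balance()], select features with
#' [stepwise_select()] on the 0/1-coded label, and fit ordinary least
#' squares of the label on the selected features. Prediction thresholds the
#' linear score at 0.5 (the balanced prior after SMOTE); a score exactly at
#' the threshold is assigned the class coded 1 (`group_b`).
#'
#' When stepwise selection retains nothing, the classifier falls back to
#' intercept-only: the score is the balanced label mean 0.5, which the tie
#' rule maps to a constant `group_b` prediction (deterministic, logged via a
#' message).
#'
#' @param train Training `nuis_data` (may contain reference-group subjects;
#'   they are not used to train the classifier).
#' @param pair A [group_pair()]; `group_a` is coded 0, `group_b` 1.
#' @param features Candidate feature names (default: all classification
#'   features).
#' @param p_enter,p_remove Stepwise thresholds, see [stepwise_select()].
#' @param smote_k SMOTE neighbour count, see [smote_balance()].
#' @param seed Optional seed for the SMOTE draws.
#' @param quiet Suppress the intercept-only fallback message.
#' @return A `linreg_classifier` with the selected features, coefficients,
#'   decision threshold, class coding and stored training means.
#' @export
train_classifier <- function(train, pair, features = NULL,
                             p_enter = 0.05, p_remove = 0.10,
                             smote_k = 5, seed = NULL, quiet = FALSE) {
  stopifnot(inherits(train, "nuis_data"), inherits(pair, "group_pair"))
  features <- features %||% feature_names(train)
  sub <- subset_subjects(train, pair_indices(train, pair))
  if (n_subjects(sub) == 0 ||
      !all(c(pair$group_a, pair$group_b) %in% group_labels(sub))) {
    stop("both study groups must be present in the training set",
         call. = FALSE)
  }

  ## impute with training means (computed before balancing)
  Feat <- block_matrix(sub, features)
  means <- column_means(Feat)
  if (anyNA(means)) {
    bad <- names(means)[is.na(means)]
    stop("feature '", bad[1], "' is missing for every training subject",
         call. = FALSE)
  }
  for (f in features) {
    v <- sub$data[[f]]
    v[is.na(v)] <- means[f]
    sub$data[[f]] <- v
  }

  bal <- smote_balance(sub, pair, k_neighbors = smote_k, seed = seed)
  y <- as.numeric(group_labels(bal) == pair$group_b)
  X <- block_matrix(bal, features)

  selected <- stepwise_select(X, y, p_enter = p_enter, p_remove = p_remove)
  if (length(selected) == 0) {
    if (!quiet) message("stepwise selection retained no feature; ",
                        "falling back to intercept-only classifier")
    coefs <- c("(Intercept)" = mean(y))
  } else {
    fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), y)
    coefs <- stats::setNames(fit$coefficients,
                             c("(Intercept)", selected))
  }

  structure(
    list(
      selected_features = selected,
      coefficients = coefs,
      decision_threshold = 0.5,
      class_codes = stats::setNames(c(0, 1), c(pair$group_a, pair$group_b)),
      feature_means = means,
      pair = pair
    ),
    class = "linreg_classifier"
  )
}

#' @export
print.linreg_classifier <- function(x, ...) {
  cat("<linreg_classifier> ", x$pair$group_a, " (0) vs ", x$pair$group_b,
      " (1); ", length(x$selected_features), " feature(s) selected\n",
      sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.linreg_classifier <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.linreg_classifier <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected_features),
                 decision_threshold = x$decision_threshold,
                 group_a = x$pair$group_a, group_b = x$pair$group_b)
}

#' Predict group labels
#'
#' Computes the linear score for each subject and assigns the class coded 1
#' when the score is greater than or equal to the decision threshold (ties
#' go to class 1). Missing feature values are imputed with the stored
#' training means.
#'
#' @param object A [train_classifier()] result.
#' @param newdata A `nuis_data` or data frame containing the selected
#'   feature columns.
#' @param type `"label"` (default) for predicted group labels, `"score"`
#'   for the raw linear score.
#' @param ... Unused.
#' @return Character label vector or numeric score vector.
#' @export
predict.linreg_classifier <- function(object, newdata,
                                      type = c("label", "score"), ...) {
  type <- match.arg(type)
  df <- if (inherits(newdata, "nuis_data")) newdata$data else
    tibble::as_tibble(newdata)
  sel <- object$selected_features
  missing_cols <- setdiff(sel, names(df))
  if (length(missing_cols) > 0) {
    stop("selected feature '", missing_cols[1], "' absent from newdata",
         call. = FALSE)
  }
  if (length(sel) == 0) {
    score <- rep(unname(object$coefficients["(Intercept)"]), nrow(df))
  } else {
    X <- as.matrix(df[, sel, drop = FALSE])
    storage.mode(X) <- "double"
    X <- impute_with_means(X, object$feature_means[sel])
    score <- drop(cbind(1, X) %*% object$coefficients)
  }
  if (type == "score") return(score)
  labels <- names(object$class_codes)
  ifelse(score >= object$decision_threshold, labels[2], labels[1])
}
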