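#' Fit a reference-group nuisance-regression model
#'
#' For every classification feature, fits an ordinary-least-squares
#' regression of that feature on the chosen nuisance features using the
#' reference-group subjects only. The reference group (typically healthy
#' controls) carries no disease-related variability, so the fitted slopes
#' capture the normal covariate effect (e.g. hippocampal volume declining
#' with age), which [correct_features()] then removes from all subjects.
#'
#' With several nuisance features the fit is a single joint multiple
#' regression per classification feature (intercept plus one coefficient per
#' nuisance), the same adjustment ANCOVA makes; it is order-independent,
#' unlike a sequence of single-covariate corrections.
#'
#' Reference subjects with a missing value in the feature or in any involved
#' nuisance are dropped from that feature's fit (complete-case per feature).
#'
#' @param train A `nuis_data` training set containing the reference group.
#' @param feature_names Classification features to model; default all.
#' @param nuisance_names Nuisance features to regress on (at least one).
#' @param reference_group Label of the reference group.
#' @return A `nuisance_model` with per-feature `slopes` (features x
#'   nuisances), `intercepts`, the reference-group nuisance means used for
#'   imputation at correction time, and `n_reference`.
#' @seealso [correct_features()], [fit_and_correct()]
#' @export
fit_nuisance_model <- function(train, feature_names = NULL, nuisance_names,
                               reference_group) {
  stopifnot(inherits(train, "nuis_data"))
  feature_names <- feature_names %||% feature_names(train)
  if (length(nuisance_names) < 1) {
    stop("at least one nuisance feature is required", call. = FALSE)
  }
  stopifnot(all(feature_names %in% train$features),
            all(nuisance_names %in% train$nuisances))
  if (!reference_group %in% group_labels(train)) {
    stop("reference group '", reference_group, "' absent from training data",
         call. = FALSE)
  }
  ref <- subset_subjects(train, group_labels(train) == reference_group)
  n_ref <- n_subjects(ref)
  k <- length(nuisance_names)
  if (n_ref < k + 2) {
    stop("too few reference subjects (", n_ref, ") for ", k,
         " nuisance feature(s)", call. = FALSE)
  }
  S_all <- block_matrix(ref, nuisance_names)
  C_all <- block_matrix(ref, feature_names)

  slopes <- matrix(NA_real_, length(feature_names), k,
                   dimnames = list(feature_names, nuisance_names))
  intercepts <- stats::setNames(rep(NA_real_, length(feature_names)),
                                feature_names)
  n_used <- stats::setNames(integer(length(feature_names)), feature_names)

  for (f in feature_names) {
    ok <- !is.na(C_all[, f]) & !rowSums(is.na(S_all))
    n_f <- sum(ok)
    if (n_f < k + 2) {
      stop("too few complete reference cases (", n_f, ") for feature '",
           f, "'", call. = FALSE)
    }
    S <- S_all[ok, , drop = FALSE]
    vs <- apply(S, 2, stats::var)
    if (any(vs == 0 | is.na(vs))) {
      stop("zero-variance nuisance feature '",
           nuisance_names[which(vs == 0 | is.na(vs))[1]],
           "' in reference group", call. = FALSE)
    }
    X <- cbind(1, S)
    fit <- stats::lm.fit(X, C_all[ok, f])
    if (fit$rank < ncol(X)) {
      stop("collinear nuisance features in reference group for feature '",
           f, "'", call. = FALSE)
    }
    intercepts[f] <- fit$coefficients[1]
    slopes[f, ] <- fit$coefficients[-1]
    n_used[f] <- n_f
  }

  structure(
    list(
      feature_names = feature_names,
      nuisance_names = nuisance_names,
      slopes = slopes,
      intercepts = intercepts,
      nuisance_means = column_means(S_all),
      reference_group = reference_group,
      n_reference = n_ref,
      n_used = n_used
    ),
    class = "nuisance_model"
  )
}

#' @export
print.nuisance_model <- function(x, ...) {
  cat("<nuisance_model> ", length(x$feature_names), " feature(s) ~ ",
      paste(x$nuisance_names, collapse = " + "),
      " | reference: ", x$reference_group,
      " (n = ", x$n_reference, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.nuisance_model <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x$slopes, rownames = "feature"),
    -"feature", names_to = "nuisance", values_to = "slope"
  )
  dplyr::mutate(long,
                intercept = unname(x$intercepts[.data$feature]),
                n = unname(x$n_used[.data$feature]))
}

#' @export
glance.nuisance_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_nuisances = length(x$nuisance_names),
    reference_group = x$reference_group,
    n_reference = x$n_reference
  )
}

#' Remove fitted nuisance effects from all subjects
#'
#' Subtracts the model-predicted nuisance contribution
#' (intercept + slopes x subject's nuisance values) from every modelled
#' classification feature, for every subject of every group. The corrected
#' values are residuals relative to the reference-group norm, so the
#' reference group has exactly zero mean in every corrected feature.
#'
#' A subject with a missing nuisance value has that regressor imputed with
#' the model's stored reference-group mean, so a present feature value is
#' never destroyed by a missing covariate. Missing feature values remain
#' missing.
#'
#' @param data A `nuis_data` containing the model's feature and nuisance
#'   columns.
#' @param model A [fit_nuisance_model()] result.
#' @return A `nuis_data` of the same shape with modelled features replaced
#'   by corrected values; other columns untouched.
#' @export
correct_features <- function(data, model) {
  stopifnot(inherits(data, "nuis_data"), inherits(model, "nuisance_model"))
  missing_cols <- setdiff(c(model$feature_names, model$nuisance_names),
                          names(data$data))
  if (length(missing_cols) > 0) {
    stop("column '", missing_cols[1], "' required by model is absent",
         call. = FALSE)
  }
  out <- data
  if (nrow(data$data) == 0) return(out)
  S <- block_matrix(data, model$nuisance_names)
  S <- impute_with_means(S, model$nuisance_means)
  predicted <- S %*% t(model$slopes) +
    matrix(model$intercepts, nrow(S), length(model$feature_names),
           byrow = TRUE)
  for (f in model$feature_names) {
    out$data[[f]] <- data$data[[f]] - unname(predicted[, f])
  }
  out
}

#' Fit on the training set, correct training and held-out data
#'
#' The regression model is learned from the training set's reference
#' subjects only; the same model then corrects both the training set and
#' (optionally) held-out data, so held-out subjects never influence the fit.
#'
#' @inheritParams fit_nuisance_model
#' @param apply_to Optional second `nuis_data` (e.g. a test set) to correct
#'   with the training-set model.
#' @return A list with elements `model`, `train` (corrected training set)
#'   and `applied` (corrected `apply_to`, or `NULL`).
#' @export
fit_and_correct <- function(train, apply_to = NULL, feature_names = NULL,
                            nuisance_names, reference_group) {
  model <- fit_nuisance_model(train, feature_names, nuisance_names,
                              reference_group)
  list(
    model = model,
    train = correct_features(train, model),
    applied = if (!is.null(apply_to)) correct_features(apply_to, model)
  )
}
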