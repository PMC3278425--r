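#' Build a stratification rule
#'
#' Stratification restricts the training set, per target subject, to the
#' subjects whose nuisance values all lie within a threshold of the target's
#' values. The threshold for nuisance feature j is `alpha` times the sample
#' standard deviation of that feature over the whole dataset — a global
#' scale parameter, not a per-split quantity.
#'
#' @param data The whole available dataset (a `nuis_data`); thresholds are
#'   computed from it.
#' @param nuisance_names Nuisance features used in the rule (at least one).
#' @param alpha Positive threshold multiplier. The default 1 gave the best
#'   average results in the motivating study.
#' @param min_group_size If, after stratification, a study group holds fewer
#'   than this many training subjects, the full training set is used instead
#'   (no stratification). Default 10.
#' @param fallback `"either"` (default) triggers the fallback when either
#'   study group falls below `min_group_size`; `"both"` only when both do.
#' @return A `strat_rule` with per-nuisance thresholds.
#' @export
make_rule <- function(data, nuisance_names, alpha = 1, min_group_size = 10,
                      fallback = c("either", "both")) {
  stopifnot(inherits(data, "nuis_data"), alpha > 0, min_group_size >= 1)
  fallback <- match.arg(fallback)
  if (length(nuisance_names) < 1) {
    stop("at least one nuisance feature is required", call. = FALSE)
  }
  stopifnot(all(nuisance_names %in% data$nuisances))
  S <- block_matrix(data, nuisance_names)
  sds <- apply(S, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    stop("zero-variance nuisance feature '",
         nuisance_names[which(is.na(sds) | sds == 0)[1]], "'",
         call. = FALSE)
  }
  structure(
    list(nuisance_names = nuisance_names, alpha = alpha,
         thresholds = alpha * sds, min_group_size = min_group_size,
         fallback = fallback),
    class = "strat_rule"
  )
}

#' @export
print.strat_rule <- function(x, ...) {
  cat("<strat_rule> alpha = ", x$alpha, ", min group size = ",
      x$min_group_size, " (", x$fallback, ")\n", sep = "")
  print(tibble::tibble(nuisance = x$nuisance_names,
                       threshold = unname(x$thresholds)))
  invisible(x)
}

#' @export
tidy.strat_rule <- function(x, ...) {
  tibble::tibble(nuisance = x$nuisance_names,
                 threshold = unname(x$thresholds),
                 alpha = x$alpha,
                 min_group_size = x$min_group_size)
}

#' Select the training subjects near a target subject
#'
#' Keeps the training subjects whose value of every rule nuisance lies
#' within that nuisance's threshold of the target's value (boundary ties
#' included). Training subjects with a missing value in a rule nuisance are
#' never selected (their proximity cannot be verified). If the selection
#' leaves too few subjects in the study groups (see [make_rule()]), the full
#' training set is returned unchanged.
#'
#' @param train Training `nuis_data`.
#' @param target_nuisance Named numeric vector: the target subject's values
#'   for (at least) the rule nuisances. Must be non-missing.
#' @param rule A [make_rule()] result.
#' @param pair A [group_pair()]: the fallback counts subjects of these two
#'   groups.
#' @return A `nuis_data` of selected subjects in original order, with
#'   attribute `"fallback"` indicating whether the whole-set fallback fired.
#' @export
stratify <- function(train, target_nuisance, rule, pair) {
  stopifnot(inherits(train, "nuis_data"), inherits(rule, "strat_rule"),
            inherits(pair, "group_pair"))
  if (is.null(names(target_nuisance))) {
    if (length(target_nuisance) != length(rule$nuisance_names)) {
      stop("unnamed target_nuisance must match the rule's nuisance count",
           call. = FALSE)
    }
    target_nuisance <- stats::setNames(target_nuisance, rule$nuisance_names)
  }
  target <- target_nuisance[rule$nuisance_names]
  if (anyNA(target)) {
    stop("target subject has a missing value in a rule nuisance feature",
         call. = FALSE)
  }
  S <- block_matrix(train, rule$nuisance_names)
  dev <- abs(sweep(S, 2, as.numeric(target)))
  ok <- rowSums(sweep(dev, 2, rule$thresholds, `<=`)) == ncol(S)
  ok[is.na(ok)] <- FALSE
  grp <- group_labels(train)
  n_a <- sum(ok & grp == pair$group_a)
  n_b <- sum(ok & grp == pair$group_b)
  below <- c(n_a, n_b) < rule$min_group_size
  fall <- if (rule$fallback == "either") any(below) else all(below)
  out <- if (fall) train else subset_subjects(train, ok)
  attr(out, "fallback") <- fall
  out
}

#' Stratify, then correct with a whole-training-set model
#'
#' The combination method: the training subset is selected around the target
#' subject with [stratify()], while the nuisance-regression model is fitted
#' on the full training set's reference group — the stratified subset may be
#' too small for a stable fit, and under the linearity assumption the same
#' regression parameters apply in every stratum. The model then corrects the
#' stratified subset (and should also correct the target subject before
#' prediction).
#'
#' @inheritParams stratify
#' @param feature_names,nuisance_names,reference_group Passed to
#'   [fit_nuisance_model()] on the full training set; `nuisance_names`
#'   defaults to the rule's nuisances.
#' @return A list with `model` (fitted on the full training set) and `data`
#'   (the corrected stratified subset, carrying the `"fallback"` attribute).
#' @export
stratify_then_correct <- function(train, target_nuisance, rule, pair,
                                  feature_names = NULL,
                                  nuisance_names = rule$nuisance_names,
                                  reference_group = pair$reference) {
  model <- fit_nuisance_model(train, feature_names, nuisance_names,
                              reference_group)
  sel <- stratify(train, target_nuisance, rule, pair)
  fall <- attr(sel, "fallback")
  out <- correct_features(sel, model)
  attr(out, "fallback") <- fall
  list(model = model, data = out)
}
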