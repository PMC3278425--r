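#' Classification accuracy
#'
#' Fraction of subjects assigned their true group label: 1 when every test
#' subject is correctly classified, 0 when all are misclassified.
#'
#' @param predicted,truth Equal-length label vectors (length >= 1).
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1) {
    stop("predicted and truth must have equal length >= 1", call. = FALSE)
  }
  mean(predicted == truth)
}

#' Build a shared cross-validation plan
#'
#' Repeated random-split (leave-N-out) cross-validation: per repeat, a
#' fraction of the pair-eligible subjects is held out as the test set and
#' the rest form the training set. Subjects outside the pair (e.g. a
#' reference group) belong to every training set and are never classified.
#' The same splits are reused for every method and nuisance subset, so
#' per-repeat accuracies are positionally comparable (paired).
#'
#' @param data A `nuis_data`.
#' @param pair A [group_pair()].
#' @param n_repeats Number of random splits (default 100).
#' @param test_fraction Held-out fraction of eligible subjects
#'   (default 0.10).
#' @param seed Integer seed; the plan is deterministic given it.
#' @param group_stratified Draw the test set per group (proportional) rather
#'   than from the pooled eligible subjects (default `FALSE`, plain random
#'   sampling).
#' @return A `cv_plan` holding the fixed list of (train, test) index pairs.
#' @export
make_cv_plan <- function(data, pair, n_repeats = 100, test_fraction = 0.10,
                         seed, group_stratified = FALSE) {
  stopifnot(inherits(data, "nuis_data"), inherits(pair, "group_pair"),
            n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  grp <- group_labels(data)
  eligible <- pair_indices(data, pair)
  n_a <- sum(grp == pair$group_a)
  n_b <- sum(grp == pair$group_b)
  if (n_a < 10 || n_b < 10) {
    stop("need at least 10 subjects per study group", call. = FALSE)
  }
  all_idx <- seq_len(n_subjects(data))
  splits <- with_opt_seed(as.integer(seed), {
    lapply(seq_len(n_repeats), function(i) {
      if (group_stratified) {
        test <- unlist(lapply(c(pair$group_a, pair$group_b), function(g) {
          g_idx <- which(grp == g)
          sample(g_idx, max(1, round(test_fraction * length(g_idx))))
        }))
        test <- sort(test)
      } else {
        test <- sort(sample(eligible,
                            max(1, round(test_fraction * length(eligible)))))
      }
      list(train = setdiff(all_idx, test), test = test)
    })
  })
  structure(
    list(splits = splits, n_repeats = n_repeats,
         test_fraction = test_fraction, seed = as.integer(seed),
         pair = pair, n_subjects = n_subjects(data)),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$n_repeats, " repeats, test fraction ",
      x$test_fraction, ", seed ", x$seed, " (",
      x$pair$group_a, " vs ", x$pair$group_b, ")\n", sep = "")
  invisible(x)
}

#' Run one nuisance-removal method over a cross-validation plan
#'
#' Executes the full pipeline for one method and one nuisance subset on
#' every split of the shared plan:
#'
#' * `original` — train the classifier on the raw training set, predict the
#'   test set.
#' * `correction` — fit the nuisance-regression model on the training set's
#'   reference group, correct both sets, then train and predict.
#' * `stratification` — for each test subject individually, select the
#'   training subjects near it with [stratify()], train a fresh classifier
#'   on the subset, and predict that one subject.
#' * `combination` — stratify per subject, but correct the subset (and the
#'   test subject) with the model fitted on the full training set's
#'   reference group.
#'
#' `correction` with an empty nuisance subset reduces exactly to `original`
#' (nothing to correct). Stratification thresholds come from a rule built on
#' the whole dataset. Identical stratified subsets within a repeat reuse one
#' fitted classifier (a pure cache; the per-repeat SMOTE seed is shared so
#' results are unchanged).
#'
#' @param data The full `nuis_data` the plan indexes into.
#' @param pair A [group_pair()]; its `reference` is the correction model's
#'   reference group.
#' @param method One of `"original"`, `"correction"`, `"stratification"`,
#'   `"combination"`.
#' @param nuisance_subset Nuisance feature names the method uses (empty only
#'   for `original`/`correction`).
#' @param plan A [make_cv_plan()] built on `data`.
#' @param features Candidate classification features (default all; pass the
#'   [preselect_features()] result to replicate the full pipeline).
#' @param alpha,min_group_size,fallback Stratification-rule parameters, see
#'   [make_rule()].
#' @param p_enter,p_remove,smote_k Classifier parameters, see
#'   [train_classifier()].
#' @param feature_group Optional name tag for the feature set (bookkeeping
#'   in result tables).
#' @return A `method_result` holding the per-repeat accuracy vector and its
#'   mean.
#' @export
run_method <- function(data, pair,
                       method = c("original", "correction",
                                  "stratification", "combination"),
                       nuisance_subset = character(), plan,
                       features = NULL, alpha = 1, min_group_size = 10,
                       fallback = "either", p_enter = 0.05, p_remove = 0.10,
                       smote_k = 5, feature_group = "features") {
  method <- match.arg(method)
  stopifnot(inherits(data, "nuis_data"), inherits(plan, "cv_plan"))
  if (plan$n_subjects != n_subjects(data)) {
    stop("plan was built for a dataset of different size", call. = FALSE)
  }
  features <- features %||% feature_names(data)
  if (length(nuisance_subset) == 0 &&
      method %in% c("stratification", "combination")) {
    stop("method '", method, "' requires at least one nuisance feature",
         call. = FALSE)
  }
  if (length(nuisance_subset) == 0 && method == "correction") {
    method_run <- "original"   # nothing to correct: exact reduction
  } else {
    method_run <- method
  }
  rule <- if (method_run %in% c("stratification", "combination")) {
    make_rule(data, nuisance_subset, alpha = alpha,
              min_group_size = min_group_size, fallback = fallback)
  }
  ref <- pair$reference

  accs <- numeric(plan$n_repeats)
  n_fallback <- 0L
  for (i in seq_len(plan$n_repeats)) {
    split <- plan$splits[[i]]
    train <- subset_subjects(data, split$train)
    test <- subset_subjects(data, split$test)
    truth <- group_labels(test)
    seed_i <- derive_seed(plan$seed, i)

    predicted <- switch(
      method_run,
      original = {
        clf <- train_classifier(train, pair, features = features,
                                p_enter = p_enter, p_remove = p_remove,
                                smote_k = smote_k, seed = seed_i,
                                quiet = TRUE)
        predict(clf, test)
      },
      correction = {
        fc <- fit_and_correct(train, test, features, nuisance_subset, ref)
        clf <- train_classifier(fc$train, pair, features = features,
                                p_enter = p_enter, p_remove = p_remove,
                                smote_k = smote_k, seed = seed_i,
                                quiet = TRUE)
        predict(clf, fc$applied)
      },
      stratification = ,
      combination = {
        model <- if (method_run == "combination") {
          fit_nuisance_model(train, features, nuisance_subset, ref)
        }
        test_use <- if (is.null(model)) test else
          correct_features(test, model)
        cache <- new.env(parent = emptyenv())
        target_m <- block_matrix(test, nuisance_subset)
        vapply(seq_len(n_subjects(test)), function(t) {
          target <- stats::setNames(as.numeric(target_m[t, ]),
                                    colnames(target_m))
          sel <- stratify(train, target, rule, pair)
          if (isTRUE(attr(sel, "fallback"))) n_fallback <<- n_fallback + 1L
          key <- paste(subject_ids(sel), collapse = "\r")
          clf <- cache[[key]]
          if (is.null(clf)) {
            train_sel <- if (is.null(model)) sel else
              correct_features(sel, model)
            clf <- train_classifier(train_sel, pair, features = features,
                                    p_enter = p_enter, p_remove = p_remove,
                                    smote_k = smote_k, seed = seed_i,
                                    quiet = TRUE)
            cache[[key]] <- clf
          }
          predict(clf, subset_subjects(test_use, t))
        }, character(1))
      }
    )
    accs[i] <- accuracy(predicted, truth)
  }

  structure(
    list(method = method, nuisance_subset = nuisance_subset,
         feature_group = feature_group,
         per_repeat_accuracy = accs, mean_accuracy = mean(accs),
         n_repeats = plan$n_repeats, plan_seed = plan$seed,
         n_fallback = n_fallback),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat("<method_result> ", x$method,
      if (length(x$nuisance_subset) > 0)
        paste0(" [", paste(x$nuisance_subset, collapse = "+"), "]"),
      ": mean accuracy ", format(x$mean_accuracy, digits = 4),
      " over ", x$n_repeats, " repeats\n", sep = "")
  invisible(x)
}

#' @export
tidy.method_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    nuisance_subset = paste(x$nuisance_subset, collapse = "+"),
    feature_group = x$feature_group,
    repeat_id = seq_len(x$n_repeats),
    accuracy = x$per_repeat_accuracy
  )
}

#' @export
glance.method_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    nuisance_subset = paste(x$nuisance_subset, collapse = "+"),
    feature_group = x$feature_group,
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$per_repeat_accuracy),
    n_repeats = x$n_repeats,
    n_fallback = x$n_fallback
  )
}

#' Paired comparison of two method results
#'
#' Two-sided paired t-test on the per-repeat accuracy differences of two
#' methods evaluated on the same cross-validation plan. When the difference
#' vector has zero variance the p-value is undefined and reported as `NA`.
#'
#' @param a,b `method_result` objects from [run_method()] on the same plan.
#' @return One-row tibble: methods, mean difference (a minus b), t
#'   statistic, p-value, repeat count.
#' @export
paired_compare <- function(a, b) {
  stopifnot(inherits(a, "method_result"), inherits(b, "method_result"))
  if (a$n_repeats != b$n_repeats || a$plan_seed != b$plan_seed) {
    stop("results come from different cross-validation plans",
         call. = FALSE)
  }
  if (a$n_repeats < 2) stop("need at least 2 repeats", call. = FALSE)
  d <- a$per_repeat_accuracy - b$per_repeat_accuracy
  tt <- if (stats::sd(d) > 0) {
    tryCatch(stats::t.test(d), error = function(e) NULL)
  }
  if (is.null(tt)) {
    message("zero-variance accuracy differences; p-value undefined")
    stat <- NA_real_
    p <- NA_real_
  } else {
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(
    method_a = a$method, method_b = b$method,
    mean_diff = mean(d), statistic = stat, p_value = p,
    n_repeats = a$n_repeats
  )
}

#' Exhaustive nuisance-feature-subset search
#'
#' Evaluates every non-empty subset of the given nuisance features for each
#' requested method on the shared cross-validation plan (plus the original
#' method once as reference), and ranks the results by mean accuracy. With
#' k nuisance features this enumerates `2^k - 1` subsets, so k is capped
#' at 12.
#'
#' @inheritParams run_method
#' @param nuisance_names Nuisance features to search over (<= 12).
#' @param methods Methods to evaluate for each subset.
#' @param include_original Also evaluate the original (uncorrected) method
#'   once (default `TRUE`).
#' @param ... Passed on to [run_method()] (`features`, `alpha`, classifier
#'   parameters, ...).
#' @return A `subset_search` tibble: method, nuisance subset, subset size,
#'   mean and sd accuracy, and the per-repeat accuracy vectors as a list
#'   column; ranked by mean accuracy.
#' @seealso [best_by_size()] for the accuracy-vs-subset-size view.
#' @export
search_nuisance_subsets <- function(data, pair, nuisance_names, plan,
                                    methods = c("correction",
                                                "stratification",
                                                "combination"),
                                    include_original = TRUE, ...) {
  stopifnot(length(nuisance_names) >= 1)
  if (length(nuisance_names) > 12) {
    stop("subset search is capped at 12 nuisance features (",
         length(nuisance_names), " given)", call. = FALSE)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  subsets <- unlist(lapply(seq_along(nuisance_names), function(m) {
    utils::combn(nuisance_names, m, simplify = FALSE)
  }), recursive = FALSE)

  runs <- list()
  if (include_original) {
    runs <- c(runs, list(run_method(data, pair, "original",
                                    character(), plan, ...)))
  }
  for (s in subsets) {
    for (m in methods) {
      runs <- c(runs, list(run_method(data, pair, m, s, plan, ...)))
    }
  }

  out <- dplyr::bind_rows(lapply(runs, function(r) {
    dplyr::mutate(glance(r),
                  subset_size = length(r$nuisance_subset),
                  accuracies = list(r$per_repeat_accuracy))
  }))
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_accuracy))
  class(out) <- c("subset_search", class(out))
  out
}

#' Best accuracy per nuisance-subset size
#'
#' Summarizes a [search_nuisance_subsets()] table into, per method, the best
#' mean accuracy achieved with each subset size (size 0 is the original
#' method). Mirrors the accuracy-vs-number-of-nuisance-features view:
#' accuracy typically rises while informative nuisances are added, then
#' declines as pure-noise nuisances dilute the selection.
#'
#' @param x A `subset_search` tibble.
#' @return A tibble with method, subset_size, best mean accuracy and the
#'   best subset at that size.
#' @export
best_by_size <- function(x) {
  stopifnot(inherits(x, "subset_search"))
  dplyr::ungroup(dplyr::slice_max(
    dplyr::group_by(tibble::as_tibble(x), .data$method, .data$subset_size),
    .data$mean_accuracy, n = 1, with_ties = FALSE
  ))[, c("method", "subset_size", "nuisance_subset", "mean_accuracy",
         "sd_accuracy")]
}
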