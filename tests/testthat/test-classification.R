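test_that("pre-selection enforces the missingness and t-test rules", {
  pair <- group_pair("A", "B")
  f_missing <- c(rnorm(17), NA, NA, NA)            # 15% missing
  f_null <- rep(c(1, 2), 10)                       # identical group means
  f_good <- c(rnorm(10, 0), rnorm(10, 4))          # strong separation
  ds <- toy_nuis(rep(c("A", "B"), each = 10),
                 list(fm = f_missing[order(rep(1:10, 2))],
                      fn = f_null, fg = f_good),
                 list(age = runif(20, 55, 90)))
  kept <- preselect_features(ds, pair, max_missing_fraction = 0.10,
                             p_threshold = 0.01)
  expect_false("fm" %in% kept)   # missing fraction 15% > 10%
  expect_false("fn" %in% kept)   # p ~ 1
  expect_true("fg" %in% kept)
})

test_that("pre-selection t-test matches the pooled-variance oracle", {
  a <- c(1, 2, 3, 4)
  b <- c(6, 7, 8, 9)
  oracle <- pooled_t_oracle(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(unname(tt$statistic), oracle$statistic, tolerance = 1e-12)
  expect_equal(tt$p.value, oracle$p_value, tolerance = 1e-12)
  expect_lt(oracle$p_value, 0.01)

  ds <- toy_nuis(rep(c("A", "B"), each = 4), list(f1 = c(a, b)),
                 list(age = runif(8, 55, 90)))
  expect_equal(preselect_features(ds, group_pair("A", "B"),
                                  p_threshold = 0.01), "f1")
  # same data fails a much stricter threshold
  expect_equal(length(preselect_features(ds, group_pair("A", "B"),
                                         p_threshold = 1e-5)), 0)
})

test_that("pre-selection errors when nothing is testable", {
  ds <- toy_nuis(rep(c("A", "B"), each = 3),
                 list(f1 = c(1, NA, NA, 2, NA, NA)),
                 list(age = runif(6, 55, 90)))
  expect_error(preselect_features(ds, group_pair("A", "B"),
                                  max_missing_fraction = 1),
               "non-missing")
})

test_that("SMOTE equalizes group counts with convex synthetics", {
  set.seed(2)
  ds <- toy_nuis(c(rep("A", 4), rep("B", 12), rep("ref", 3)),
                 list(f1 = c(rnorm(4), rnorm(12, 3), rnorm(3)),
                      f2 = rnorm(19)),
                 list(age = runif(19, 55, 90)),
                 group_levels = c("A", "B", "ref"))
  pair <- group_pair("A", "B")
  bal <- smote_balance(ds, pair, k_neighbors = 3, seed = 99)
  grp <- group_labels(bal)
  expect_equal(sum(grp == "A"), sum(grp == "B"))
  expect_equal(sum(grp == "ref"), 3)              # reference untouched
  # originals preserved verbatim
  expect_equal(as_tibble(bal)[seq_len(19), ], as_tibble(ds))
  # deterministic given the seed
  bal2 <- smote_balance(ds, pair, k_neighbors = 3, seed = 99)
  expect_identical(as_tibble(bal), as_tibble(bal2))

  # already balanced input returned unchanged
  even <- toy_nuis(rep(c("A", "B"), 5), list(f1 = rnorm(10)),
                   list(age = runif(10, 55, 90)))
  expect_identical(smote_balance(even, pair, seed = 1), even)

  # minority of size 1 has no neighbour
  lone <- toy_nuis(c("A", rep("B", 5)), list(f1 = rnorm(6)),
                   list(age = runif(6, 55, 90)))
  expect_error(smote_balance(lone, pair, seed = 1), "neighbour")
})

test_that("1-D synthetics stay inside the minority segment hull", {
  ds <- toy_nuis(c("A", "A", rep("B", 5)),
                 list(f1 = c(0, 1, rnorm(5, 10))),
                 list(age = rep(70, 7)))
  bal <- smote_balance(ds, group_pair("A", "B"), k_neighbors = 1, seed = 4)
  syn <- as_tibble(bal)$f1[-(1:7)]
  expect_length(syn, 3)
  expect_true(all(syn >= 0 & syn <= 1))
})

test_that("stepwise selection recovers the informative feature", {
  expect_equal(stepwise_select(matrix(numeric(0), 10, 0), rnorm(10)),
               character(0))

  set.seed(17)
  n <- 200
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- x1 + rnorm(n, 0, 0.1)
  X <- cbind(x1 = x1, x2 = x2)
  expect_equal(stepwise_select(X, y), "x1")

  # exhaustive audit of the fixed point over all subsets
  rss <- function(cols) sum(lm.fit(cbind(1, X[, cols, drop = FALSE]),
                                   y)$residuals^2)
  p_of <- function(small, big, q_big) {
    df2 <- n - q_big
    f <- (rss(small) - rss(big)) / (rss(big) / df2)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  expect_lt(p_of(character(0), "x1", 2), 0.05)  # x1 enters
  expect_gt(p_of("x1", c("x1", "x2"), 3), 0.05) # x2 does not
})

test_that("a residualized orthogonal feature is never selected", {
  set.seed(23)
  n <- 100
  y <- rnorm(n)
  x_raw <- rnorm(n)
  x <- lm.fit(cbind(1, y), x_raw)$residuals  # exactly uncorrelated with y
  expect_lt(abs(cor(x, y)), 1e-12)
  expect_equal(stepwise_select(cbind(x = x), y), character(0))
})

test_that("constant and collinear candidates are skipped", {
  set.seed(29)
  n <- 50
  x1 <- rnorm(n)
  y <- x1 + rnorm(n, 0, 0.1)
  X <- cbind(x1 = x1, const = rep(2, n), dup = x1)
  expect_warning(sel <- stepwise_select(X, y), "collinear")
  expect_equal(sel, "x1")
})

test_that("the trained classifier separates separable groups", {
  set.seed(31)
  ds <- toy_nuis(rep(c("A", "B"), each = 20),
                 list(f1 = c(rnorm(20, -1, 0.01), rnorm(20, 1, 0.01))),
                 list(age = runif(40, 55, 90)))
  pair <- group_pair("A", "B")
  clf <- train_classifier(ds, pair, seed = 1)
  expect_equal(clf$selected_features, "f1")
  pred <- predict(clf, ds)
  expect_equal(accuracy(pred, group_labels(ds)), 1.0)
  # a subject identical to a training subject gets its training label
  expect_equal(predict(clf, subset_subjects(ds, 1)), "A")

  # bit-identical reproducibility
  clf2 <- train_classifier(ds, pair, seed = 1)
  expect_identical(clf$coefficients, clf2$coefficients)
})

test_that("label-independent features give chance-level held-out accuracy", {
  set.seed(37)
  accs <- vapply(1:40, function(r) {
    n <- 100
    df <- tibble::tibble(
      subject_id = sprintf("s%03d", 1:n),
      group = rep(c("A", "B"), each = n / 2)
    )
    for (j in 1:5) df[[paste0("f", j)]] <- rnorm(n)
    df$age <- runif(n, 55, 90)
    ds <- as_nuis_data(df, features = paste0("f", 1:5), nuisances = "age")
    train_idx <- sort(sample(n, 70))
    clf <- train_classifier(subset_subjects(ds, train_idx),
                            group_pair("A", "B"), seed = r, quiet = TRUE)
    test <- subset_subjects(ds, setdiff(seq_len(n), train_idx))
    accuracy(predict(clf, test), group_labels(test))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("ties and the intercept-only fallback are deterministic", {
  set.seed(41)
  # pure-noise single feature: stepwise keeps nothing
  ds <- toy_nuis(rep(c("A", "B"), each = 15),
                 list(f1 = rnorm(30)),
                 list(age = runif(30, 55, 90)))
  pair <- group_pair("A", "B")
  expect_message(clf <- train_classifier(ds, pair, seed = 1),
                 "intercept-only")
  expect_length(clf$selected_features, 0)
  pred <- predict(clf, ds)
  expect_equal(unique(pred), "B")   # score 0.5 >= threshold -> class 1

  # a score exactly at the threshold goes to the class coded 1
  clf$selected_features <- "f1"
  clf$coefficients <- c("(Intercept)" = 0.5, f1 = 0)
  expect_equal(predict(clf, subset_subjects(ds, 1)), "B")

  expect_error(predict(clf, tibble::tibble(other = 1)), "absent")
})

test_that("missing features are imputed with training means at predict time", {
  ds <- toy_nuis(rep(c("A", "B"), each = 10),
                 list(f1 = c(rnorm(10, -2, 0.1), rnorm(10, 2, 0.1))),
                 list(age = runif(20, 55, 90)))
  clf <- train_classifier(ds, group_pair("A", "B"), seed = 1)
  new <- tibble::tibble(f1 = NA_real_)
  score <- predict(clf, new, type = "score")
  expected <- unname(clf$coefficients["(Intercept)"] +
                       clf$coefficients["f1"] * clf$feature_means["f1"])
  expect_equal(score, expected)
})
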