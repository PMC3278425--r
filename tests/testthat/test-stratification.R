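test_that("thresholds follow the alpha * whole-dataset-sd definition", {
  age <- c(60, 64, 68, 72, 76, 80, 62, 74)
  ds <- toy_nuis(rep(c("A", "B"), 4), list(f1 = rnorm(8)),
                 list(age = age))
  r1 <- make_rule(ds, "age", alpha = 1, min_group_size = 1)
  expect_equal(unname(r1$thresholds["age"]), sd(age))
  r2 <- make_rule(ds, "age", alpha = 2, min_group_size = 1)
  expect_equal(unname(r2$thresholds), 2 * unname(r1$thresholds))
  flat <- toy_nuis(rep(c("A", "B"), 4), list(f1 = rnorm(8)),
                   list(age = rep(70, 8)))
  expect_error(make_rule(flat, "age"), "zero-variance")
})

test_that("selection matches a brute-force scan, ties included", {
  age <- c(60, 63, 65, 66, 70, 71, 74, 75, 76, 80, 82, 85)
  ds <- toy_nuis(rep(c("A", "B"), 6), list(f1 = rnorm(12)),
                 list(age = age))
  rule <- make_rule(ds, "age", alpha = 1, min_group_size = 1)
  rule$thresholds["age"] <- 5  # override to the worked toy threshold
  pair <- group_pair("A", "B")
  sel <- stratify(ds, c(age = 70), rule, pair)
  expect_equal(as_tibble(sel)$age, age[age >= 65 & age <= 75])
  expect_false(attr(sel, "fallback"))
  # boundary ages 65 and 75 sit exactly at |age - 70| == 5 and are kept
  expect_true(all(c(65, 75) %in% as_tibble(sel)$age))
})

test_that("vacuous thresholds select everyone", {
  ds <- toy_nuis(rep(c("A", "B"), 10), list(f1 = rnorm(20)),
                 list(age = runif(20, 55, 90)))
  rule <- make_rule(ds, "age", alpha = 100, min_group_size = 1)
  sel <- stratify(ds, c(age = 70), rule, group_pair("A", "B"))
  expect_equal(n_subjects(sel), 20)
})

test_that("the whole-set fallback fires exactly when a group is too small", {
  # 9 group-A subjects inside the window, 10 group-B inside
  age <- c(seq(66, 74, along.with = 1:9), 95,
           seq(66, 74, along.with = 1:10))
  grp <- c(rep("A", 10), rep("B", 10))
  ds <- toy_nuis(grp, list(f1 = rnorm(20)), list(age = age))
  rule <- make_rule(ds, "age", min_group_size = 10)
  rule$thresholds["age"] <- 5
  pair <- group_pair("A", "B")
  sel <- stratify(ds, c(age = 70), rule, pair)
  expect_true(attr(sel, "fallback"))
  expect_equal(n_subjects(sel), 20)

  # under the conjunctive reading one small group does not trigger it
  rule$fallback <- "both"
  sel2 <- stratify(ds, c(age = 70), rule, pair)
  expect_false(attr(sel2, "fallback"))
  expect_equal(n_subjects(sel2), 19)

  # with min_group_size 9 the either-reading fallback does not fire
  rule$fallback <- "either"
  rule$min_group_size <- 9
  sel3 <- stratify(ds, c(age = 70), rule, pair)
  expect_false(attr(sel3, "fallback"))
})

test_that("selection is monotone in alpha before the fallback", {
  set.seed(21)
  ds <- toy_nuis(rep(c("A", "B"), 25), list(f1 = rnorm(50)),
                 list(age = runif(50, 55, 90), bmi = rnorm(50, 26, 4)))
  pair <- group_pair("A", "B")
  target <- c(age = 72, bmi = 27)
  alphas <- c(0.5, 1, 1.5, 2)
  sels <- lapply(alphas, function(a) {
    stratify(ds, target,
             make_rule(ds, c("age", "bmi"), alpha = a,
                       min_group_size = 1), pair)
  })
  # monotonicity holds for the pre-fallback selections
  compared <- 0
  for (i in seq_len(length(alphas) - 1)) {
    if (!attr(sels[[i]], "fallback") && !attr(sels[[i + 1]], "fallback")) {
      expect_true(all(subject_ids(sels[[i]]) %in%
                        subject_ids(sels[[i + 1]])))
      compared <- compared + 1
    }
  }
  expect_gte(compared, 2)
})

test_that("a balanced binary nuisance admits only the same category", {
  set.seed(8)
  for (p in c(0.3, 0.5, 0.7)) {
    gender <- c(rep(0, round(40 * (1 - p))), rep(1, round(40 * p)))
    ds <- toy_nuis(rep(c("A", "B"), 20), list(f1 = rnorm(40)),
                   list(gender = as.numeric(gender)))
    rule <- make_rule(ds, "gender", alpha = 1, min_group_size = 1)
    expect_lt(unname(rule$thresholds["gender"]), 1)
    sel <- stratify(ds, c(gender = 1), rule, group_pair("A", "B"))
    expect_true(all(as_tibble(sel)$gender == 1))
  }
})

test_that("multiple nuisances must all satisfy the rule; missing values", {
  age <- c(65, 70, 75, 70, 70, NA)
  bmi <- c(25, 25, 25, 40, 25, 25)
  ds <- toy_nuis(rep(c("A", "B"), 3), list(f1 = rnorm(6)),
                 list(age = age, bmi = bmi))
  rule <- make_rule(ds, c("age", "bmi"), min_group_size = 1)
  rule$thresholds <- c(age = 5, bmi = 5)
  sel <- stratify(ds, c(age = 70, bmi = 25), rule, group_pair("A", "B"))
  # subject 4 fails on bmi, subject 6 has missing age: both excluded
  expect_equal(subject_ids(sel), sprintf("t%03d", c(1, 2, 3, 5)))
  expect_error(stratify(ds, c(age = NA, bmi = 25), rule,
                        group_pair("A", "B")),
               "missing")
})

test_that("stratify agrees with the brute-force oracle on random toys", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    k <- sample(1:3, 1)
    nuis <- stats::setNames(
      lapply(seq_len(k), function(j) round(runif(n, 0, 10), 1)),
      paste0("s", seq_len(k)))
    ds <- toy_nuis(sample(c("A", "B"), n, replace = TRUE),
                   list(f1 = rnorm(n)), nuis)
    rule <- make_rule(ds, names(nuis), alpha = runif(1, 0.3, 1.5),
                      min_group_size = sample(1:6, 1))
    pair <- group_pair("A", "B")
    target <- vapply(nuis, function(v) sample(v, 1), numeric(1))
    sel <- stratify(ds, target, rule, pair)
    expected <- brute_stratify(ds, as.list(target),
                               as.list(rule$thresholds),
                               rule$min_group_size, pair)
    expect_equal(subject_ids(sel), subject_ids(ds)[expected])
  }
})

test_that("the combination corrects with the full-training-set model", {
  # group-B reference relation differs inside the narrow stratum, so a
  # subset fit would give a very different slope than the full-set fit
  s <- c(seq(0, 10, length.out = 20), seq(4.5, 5.5, length.out = 10))
  c1 <- c(2 * s[1:20], 8 - 1 * s[21:30])
  ds <- toy_nuis(c(rep("ref", 20), rep("ref", 10),
                   rep(c("A", "B"), 5)),
                 list(c1 = c(c1, rnorm(10))),
                 list(s1 = c(s, runif(10, 4.5, 5.5))))
  rule <- make_rule(ds, "s1", min_group_size = 1)
  rule$thresholds["s1"] <- 0.6
  pair <- group_pair("A", "B")

  full_model <- fit_nuisance_model(ds, "c1", "s1", "ref")
  sel <- stratify(ds, c(s1 = 5), rule, pair)
  subset_model <- fit_nuisance_model(sel, "c1", "s1", "ref")
  expect_gt(abs(full_model$slopes["c1", "s1"] -
                  subset_model$slopes["c1", "s1"]), 0.5)

  res <- stratify_then_correct(ds, c(s1 = 5), rule, pair,
                               feature_names = "c1",
                               reference_group = "ref")
  expect_equal(res$model$slopes, full_model$slopes)
  expect_equal(as_tibble(res$data),
               as_tibble(correct_features(sel, full_model)))
})

test_that("combination leaves no nuisance effect on noiseless Type-2 data", {
  s <- seq(55, 90, length.out = 30)
  ds <- toy_nuis(rep(c("ref", "A", "B"), each = 30),
                 list(c1 = c(0.1 * s, 0.1 * s, 0.1 * s + 2)),
                 list(age = rep(s, 3)))
  rule <- make_rule(ds, "age", min_group_size = 5)
  res <- stratify_then_correct(ds, c(age = 70), rule,
                               group_pair("A", "B"),
                               reference_group = "ref")
  df <- as_tibble(res$data)
  for (g in c("A", "B")) {
    sub <- df[df$group == g, ]
    beta <- ols_oracle(sub$age, sub$c1)
    expect_lt(abs(beta[2]), 1e-8)
  }
})
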