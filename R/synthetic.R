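#' Simulate the four nuisance-feature interaction types
#'
#' Generates a subject table with one active classification feature (`c1`)
#' and configurable nuisance features, following one of the four canonical
#' ways a nuisance feature can interact with a classification feature:
#'
#' * **Type 0** — no relation: `c1` is the group shift plus noise,
#'   independent of every nuisance. Neither correction nor stratification is
#'   needed.
#' * **Type 1** — the nuisance predicts group membership (log-odds linear in
#'   the nuisance) but is unrelated to `c1` within groups. Such a feature
#'   acts as a classification feature and must not be corrected or
#'   stratified on.
#' * **Type 2** — direct functional relation: `c1 = intercept + slope * s +
#'   shift + noise`, the same slope in every group. Regression correction
#'   removes it exactly.
#' * **Type 3** — group separation grows with the nuisance: the reference
#'   group and group A are flat in `s`, while group B's mean rises linearly
#'   from 0 at the bottom of the nuisance range to
#'   `gradient * separation * noise_sd` at the top. A reference-group
#'   regression sees zero slope, so correction is provably useless;
#'   stratification exploits the locally enlarged separation.
#'
#' The first entry of `nuisance_spec` is the active nuisance; any further
#' entries are drawn independently of everything else (pure noise).
#'
#' @param type Interaction type, one of 0, 1, 2, 3.
#' @param n_per_group Subjects per group (study groups `"A"`, `"B"` and,
#'   when `include_reference`, a disease-free `"ref"` group drawn like
#'   group A without the disease shift).
#' @param group_separation Mean shift of group B in units of the
#'   within-group standard deviation `noise_sd`.
#' @param slope Effect of the active nuisance on `c1` per nuisance unit
#'   (Type 2 only).
#' @param intercept Baseline value of `c1`.
#' @param noise_sd Within-group Gaussian noise standard deviation.
#' @param nuisance_spec Named list of per-nuisance distributions, each a
#'   list with `dist = "uniform"` (`min`, `max`), `"bernoulli"` (`p`) or
#'   `"normal"` (`mean`, `sd`). Default: one age-like nuisance,
#'   uniform on 55-90 years.
#' @param type1_logit_slope Log-odds of group B per standard deviation of
#'   the active nuisance (Type 1 only).
#' @param type3_separation_gradient Scales how fast group B's separation
#'   grows over the nuisance range (Type 3 only).
#' @param n_noise_features Additional inert classification features
#'   (`noise1`, `noise2`, ...), pure Gaussian noise.
#' @param include_reference Emit the third, reference group (default TRUE).
#' @param seed Optional integer seed; the dataset is deterministic given it.
#' @return A `nuis_data` with groups `A`, `B` (and `ref`), feature block
#'   `c1` (+ noise features) and the configured nuisance block. The full
#'   configuration is stored in attribute `"config"`.
#' @export
simulate_interaction <- function(type, n_per_group = 300,
                                 group_separation = 1.5, slope = 0.1,
                                 intercept = 0, noise_sd = 1,
                                 nuisance_spec = list(
                                   age = list(dist = "uniform",
                                              min = 55, max = 90)),
                                 type1_logit_slope = 2,
                                 type3_separation_gradient = 1,
                                 n_noise_features = 0,
                                 include_reference = TRUE, seed = NULL) {
  if (!type %in% 0:3) {
    stop("interaction type must be 0, 1, 2 or 3 (got ", type, ")",
         call. = FALSE)
  }
  stopifnot(n_per_group >= 2, noise_sd > 0, length(nuisance_spec) >= 1,
            !is.null(names(nuisance_spec)))
  config <- list(type = type, n_per_group = n_per_group,
                 group_separation = group_separation, slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 nuisance_spec = nuisance_spec,
                 type1_logit_slope = type1_logit_slope,
                 type3_separation_gradient = type3_separation_gradient,
                 n_noise_features = n_noise_features,
                 include_reference = include_reference, seed = seed)

  df <- with_opt_seed(seed, {
    n_study <- 2L * n_per_group
    n_total <- n_study + if (include_reference) n_per_group else 0L

    S <- vapply(nuisance_spec, draw_nuisance, numeric(n_total), n = n_total)
    colnames(S) <- names(nuisance_spec)
    s <- S[, 1]

    group <- c(rep(c("A", "B"), each = n_per_group),
               rep("ref", n_total - n_study))
    if (type == 1) {
      z <- (s[seq_len(n_study)] - mean(s[seq_len(n_study)])) /
        stats::sd(s[seq_len(n_study)])
      is_b <- stats::runif(n_study) < stats::plogis(type1_logit_slope * z)
      group[seq_len(n_study)] <- ifelse(is_b, "B", "A")
      if (length(unique(group[seq_len(n_study)])) < 2) {
        stop("degenerate draw: a study group is empty; increase n_per_group",
             call. = FALSE)
      }
    }

    shift <- group_separation * noise_sd
    mu <- switch(as.character(type),
      "0" = intercept + shift * (group == "B"),
      "1" = intercept + shift * (group == "B"),
      "2" = intercept + slope * s + shift * (group == "B"),
      "3" = {
        spec1 <- nuisance_spec[[1]]
        rng <- if (identical(spec1$dist, "uniform")) {
          c(spec1$min, spec1$max)
        } else range(s)
        ramp <- (s - rng[1]) / (rng[2] - rng[1])
        intercept + type3_separation_gradient * ramp * shift * (group == "B")
      }
    )
    c1 <- mu + stats::rnorm(n_total, 0, noise_sd)

    out <- tibble::tibble(
      subject_id = sprintf("s%04d", seq_len(n_total)),
      group = group, c1 = c1
    )
    for (j in seq_len(n_noise_features)) {
      out[[paste0("noise", j)]] <- stats::rnorm(n_total, 0, noise_sd)
    }
    dplyr::bind_cols(out, tibble::as_tibble(S))
  })

  ds <- as_nuis_data(df, id = "subject_id", group = "group",
                     features = setdiff(names(df),
                                        c("subject_id", "group",
                                          names(nuisance_spec))),
                     nuisances = names(nuisance_spec),
                     group_levels = c("A", "B",
                                      if (include_reference) "ref"))
  attr(ds, "config") <- config
  ds
}

draw_nuisance <- function(spec, n) {
  switch(spec$dist,
    uniform = stats::runif(n, spec$min, spec$max),
    bernoulli = stats::rbinom(n, 1, spec$p),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    stop("unknown nuisance distribution '", spec$dist, "'", call. = FALSE)
  )
}

#' Simulate an ADNI-like hippocampal-volume scenario
#'
#' Emulates the classic covariate structure of hippocampal volumetry:
#' volume declines linearly with age, females have smaller volumes than
#' males, and Alzheimer's disease shifts the mean down. Groups are healthy
#' controls (`"C"`) and patients (`"AD"`); age is uniform over `age_range`
#' and gender Bernoulli(0.5), coded 0 = male, 1 = female.
#'
#' `volume = baseline + slope_per_year * (age - min(age_range)) +
#'  gender_offset * female + disease_shift * AD + N(0, noise_sd^2)`
#'
#' Defaults are plausible left-hippocampus magnitudes in cubic millimetres.
#'
#' @param n_per_group Subjects per group.
#' @param age_range Two ascending numbers (years).
#' @param slope_per_year Volume change per year of age; must be negative
#'   (atrophy).
#' @param gender_offset Female-minus-male volume offset.
#' @param disease_shift AD-minus-control mean shift; must be negative.
#' @param noise_sd Residual standard deviation (> 0).
#' @param baseline Mean volume of a male control at the youngest age.
#' @param seed Optional integer seed.
#' @return A `nuis_data` with feature `left_hippocampus` and nuisances
#'   `age`, `gender`; configuration in attribute `"config"`.
#' @export
simulate_hippocampus <- function(n_per_group = 250, age_range = c(55, 90),
                                 slope_per_year = -25, gender_offset = -250,
                                 disease_shift = -600, noise_sd = 400,
                                 baseline = 4300, seed = NULL) {
  stopifnot(n_per_group >= 2, noise_sd > 0, length(age_range) == 2)
  if (age_range[2] <= age_range[1]) {
    stop("degenerate age range", call. = FALSE)
  }
  if (slope_per_year >= 0) {
    stop("slope_per_year must be negative (volume declines with age)",
         call. = FALSE)
  }
  if (disease_shift >= 0) {
    stop("disease_shift must be negative", call. = FALSE)
  }
  config <- as.list(environment())

  df <- with_opt_seed(seed, {
    n <- 2L * n_per_group
    age <- stats::runif(n, age_range[1], age_range[2])
    gender <- stats::rbinom(n, 1, 0.5)
    group <- rep(c("C", "AD"), each = n_per_group)
    volume <- baseline + slope_per_year * (age - age_range[1]) +
      gender_offset * gender + disease_shift * (group == "AD") +
      stats::rnorm(n, 0, noise_sd)
    tibble::tibble(subject_id = sprintf("s%04d", seq_len(n)),
                   group = group, left_hippocampus = volume,
                   age = age, gender = gender)
  })

  ds <- as_nuis_data(df, id = "subject_id", group = "group",
                     features = "left_hippocampus",
                     nuisances = c("age", "gender"),
                     group_levels = c("C", "AD"))
  attr(ds, "config") <- config
  ds
}
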