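cohort_df <- function(cases, controls) {
  tibble::tibble(
    value = c(cases, controls),
    group = rep(c("case", "control"), c(length(cases), length(controls)))
  )
}

auc_of <- function(cases, controls) {
  glance(roc_auc(cohort_df(cases, controls), value, group, "case", "control"))$auc
}

test_that("perfect separation gives AUC 1 and pure ties give AUC 0.5", {
  expect_equal(auc_of(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_of(c(5, 5, 5), c(5, 5)), 0.5)
})

test_that("trapezoidal AUC equals brute-force concordance on random cohorts", {
  set.seed(81)
  for (i in 1:20) {
    cases <- round(rnorm(7, 1), 1) # rounding forces ties
    controls <- round(rnorm(5), 1)
    expect_equal(auc_of(cases, controls), concordance_auc(cases, controls),
      tolerance = 1e-12
    )
  }
})

test_that("AUC agrees with pROC on a synthetic cohort", {
  skip_if_not_installed("pROC")
  co <- make_cohort(seed = 82)
  two <- co[co$group %in% c("normal", "PCa"), ]
  ours <- glance(roc_auc(two, sarcosine_molar, group, "PCa", "normal"))$auc
  ref <- suppressMessages(pROC::auc(
    pROC::roc(two$group, two$sarcosine_molar, levels = c("normal", "PCa"))
  ))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("AUC is symmetric under negation and invariant to monotone transforms", {
  set.seed(83)
  cases <- round(rlnorm(20), 1)
  controls <- round(rlnorm(15, -0.5), 1)
  expect_equal(auc_of(cases, controls) + auc_of(-cases, -controls), 1,
    tolerance = 1e-12
  )
  expect_equal(auc_of(cases, controls), auc_of(log(cases), log(controls)),
    tolerance = 1e-12
  )
  expect_equal(auc_of(cases, controls), auc_of(cases^3, controls^3),
    tolerance = 1e-12
  )
})

test_that("ROC points are monotone and classes must be non-empty", {
  set.seed(84)
  roc <- roc_auc(cohort_df(rnorm(10, 1), rnorm(10)), value, group, "case", "control")
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))
  expect_error(
    roc_auc(cohort_df(numeric(), rnorm(3)), value, group, "case", "control"),
    class = "behkit_parameter_error"
  )
})

test_that("cutoff metrics use the control mean and count ties as negative", {
  df <- cohort_df(c(3, 4), c(1, 2, 3))
  m <- cutoff_metrics(df, value, group, "case", "control")
  expect_equal(m$cutoff, 2)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 2 / 3)
  # a case exactly at the cutoff counts negative
  m2 <- cutoff_metrics(df, value, group, "case", "control", cutoff = 4)
  expect_equal(m2$sensitivity, 0)
})

test_that("combining markers preserves or improves discrimination", {
  set.seed(85)
  n <- 40
  df <- tibble::tibble(
    group = rep(c("case", "control"), each = n),
    m1 = c(rnorm(n, 1.2), rnorm(n)),
    m2 = NA_real_
  )
  # perfectly correlated second marker adds nothing under zsum
  df$m2 <- 2 * df$m1
  comb <- combine_markers(df, c("m1", "m2"), group, control = "control")
  expect_equal(
    glance(roc_auc(comb, combined, group, "case", "control"))$auc,
    glance(roc_auc(comb, m1, group, "case", "control"))$auc,
    tolerance = 1e-12
  )
  # a flat marker plus a perfect separator still separates perfectly
  df2 <- tibble::tibble(
    group = rep(c("case", "control"), each = 5),
    flat = rep(1, 10),
    sharp = c(6:10, 1:5)
  )
  comb2 <- combine_markers(df2, c("flat", "sharp"), group, control = "control")
  expect_equal(glance(roc_auc(comb2, combined, group, "case", "control"))$auc, 1)
  # or_rule produces a 0/1 score
  comb3 <- combine_markers(df2, c("flat", "sharp"), group,
    control = "control", method = "or_rule"
  )
  expect_true(all(comb3$combined %in% c(0, 1)))
  expect_error(
    combine_markers(df2, c("flat", "missing"), group, control = "control"),
    class = "behkit_parameter_error"
  )
})

test_that("two independent informative markers beat the best single marker", {
  set.seed(86)
  # each marker alone has analytic AUC ~0.8 (shift 1.19, sd 1)
  wins <- replicate(100, {
    n <- 45
    df <- tibble::tibble(
      group = rep(c("case", "control"), each = n),
      m1 = c(rnorm(n, 1.19), rnorm(n)),
      m2 = c(rnorm(n, 1.19), rnorm(n))
    )
    comb <- combine_markers(df, c("m1", "m2"), group, control = "control")
    auc_c <- glance(roc_auc(comb, combined, group, "case", "control"))$auc
    auc_1 <- glance(roc_auc(comb, m1, group, "case", "control"))$auc
    auc_2 <- glance(roc_auc(comb, m2, group, "case", "control"))$auc
    auc_c >= max(auc_1, auc_2)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("group summaries report boxplot stats and Mann-Whitney contrasts", {
  # two identical groups: medians equal, p = 1
  df <- tibble::tibble(
    value = rep(c(1, 2, 3, 4), 2),
    group = rep(c("g1", "g2"), each = 4)
  )
  gs <- group_summary(df, value, group)
  expect_equal(gs$stats$median[1], gs$stats$median[2])
  expect_equal(gs$tests$p_value, 1, tolerance = 1e-9)
  # fully separated groups of 5: U equals the full pair count 25
  df2 <- tibble::tibble(
    value = c(6:10, 1:5),
    group = rep(c("hi", "lo"), each = 5)
  )
  gs2 <- group_summary(df2, value, group)
  expect_equal(unname(gs2$tests$statistic_u), 25)
  # three groups emit three pairwise contrasts
  df3 <- tibble::tibble(value = rnorm(12), group = rep(c("a", "b", "c"), each = 4))
  expect_equal(nrow(group_summary(df3, value, group)$tests), 3L)
  expect_error(
    group_summary(
      tibble::tibble(value = c(1, 2, 3), group = c("a", "a", "b")),
      value, group
    ),
    class = "behkit_parameter_error"
  )
})
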