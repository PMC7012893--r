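#' ROC curve and AUC for a marker
#'
#' Receiver operating characteristic analysis of a cohort marker under
#' the convention that higher values are more case-like. Thresholds are
#' placed at every distinct observed value; a sample is called positive
#' when its value is strictly greater than the threshold (ties count
#' negative). The AUC is the trapezoidal integral of the curve, which for
#' this construction equals the pairwise concordance probability with
#' ties weighted one half.
#'
#' @param data Cohort tibble (one row per sample).
#' @param marker Column holding the marker values (tidy-eval).
#' @param group Column holding the group labels (tidy-eval).
#' @param case,control Labels of the case and control groups.
#'
#' @return A `roc_result`: tibble of `threshold`, `sensitivity`,
#'   `specificity` (one row per distinct value plus the all-positive
#'   endpoint) with attributes `auc`, `n_case`, `n_control`.
#' @examples
#' co <- make_cohort(seed = 1)
#' roc <- roc_auc(co, sarcosine_molar, group, case = "PCa", control = "normal")
#' glance(roc)
#' @export
roc_auc <- function(data, marker, group, case, control) {
  data <- as_tibble(data)
  values <- dplyr::pull(data, {{ marker }})
  labels <- dplyr::pull(data, {{ group }})
  cases <- values[labels == case]
  controls <- values[labels == control]
  roc_from_values(cases, controls)
}

# Core ROC construction from case/control value vectors.
roc_from_values <- function(cases, controls) {
  if (!length(cases) || !length(controls)) {
    stop_bad_arg("both the case and the control class must be non-empty.")
  }
  if (anyNA(cases) || anyNA(controls)) stop_bad_arg("marker values contain NA.")
  thresholds <- sort(unique(c(cases, controls)), decreasing = TRUE)
  sens <- vapply(thresholds, function(t) mean(cases > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(controls <= t), numeric(1))
  curve <- tibble(
    threshold = c(Inf, thresholds),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  # trapezoid over (1 - specificity, sensitivity); final point is (1, 1)
  fpr <- c(1 - curve$specificity, 1)
  tpr <- c(curve$sensitivity, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    curve,
    auc = auc,
    n_case = length(cases),
    n_control = length(controls),
    class = c("roc_result", class(curve))
  )
}

#' @describeIn roc_auc One-row summary with the AUC and class sizes.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
glance.roc_result <- function(x, ...) {
  tibble(
    auc = attr(x, "auc"),
    n_case = attr(x, "n_case"),
    n_control = attr(x, "n_control")
  )
}

#' @describeIn roc_auc The ROC points as a plain tibble.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @describeIn roc_auc ROC curve plot (sensitivity vs 1 - specificity).
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  df <- rbind(df, tibble(threshold = -Inf, sensitivity = 1, specificity = 0))
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Sensitivity and specificity at a cutoff
#'
#' Classifies samples as positive when the marker value is strictly
#' greater than the cutoff (a value equal to the cutoff counts negative)
#' and reports sensitivity (positives among cases) and specificity
#' (negatives among controls). The default cutoff is the mean marker
#' level of the control group.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold; default `NULL` uses the control-group
#'   mean.
#'
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `n_case`, `n_control`.
#' @export
cutoff_metrics <- function(data, marker, group, case, control, cutoff = NULL) {
  data <- as_tibble(data)
  values <- dplyr::pull(data, {{ marker }})
  labels <- dplyr::pull(data, {{ group }})
  cases <- values[labels == case]
  controls <- values[labels == control]
  if (!length(cases) || !length(controls)) {
    stop_bad_arg("both the case and the control class must be non-empty.")
  }
  if (is.null(cutoff)) cutoff <- mean(controls)
  tibble(
    cutoff = cutoff,
    sensitivity = mean(cases > cutoff),
    specificity = mean(controls <= cutoff),
    n_case = length(cases),
    n_control = length(controls)
  )
}

#' Combine two markers into one score
#'
#' Adds a combined-score column for two markers measured on the same
#' samples. Method `"zsum"` (default) standardizes each marker by the
#' control group's mean and sd and sums the z-scores — an orthogonal-
#' information combination that preserves AUC when the markers are
#' perfectly correlated and improves it when they are independent.
#' Method `"or_rule"` scores a sample 1 if either marker exceeds its own
#' control-group mean, else 0.
#'
#' @inheritParams roc_auc
#' @param markers Character vector of exactly two marker column names.
#' @param control Label of the control group used for standardization /
#'   cutoffs.
#' @param method `"zsum"` or `"or_rule"`.
#' @param name Name of the new column (default `"combined"`).
#'
#' @return `data` with the combined-score column appended.
#' @examples
#' co <- make_cohort(seed = 1)
#' co <- combine_markers(co, c("sarcosine_molar", "psa"), group, control = "normal")
#' glance(roc_auc(co, combined, group, case = "PCa", control = "normal"))
#' @export
combine_markers <- function(data, markers, group, control,
                            method = c("zsum", "or_rule"), name = "combined") {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (length(markers) != 2L || !all(markers %in% names(data))) {
    stop_bad_arg("`markers` must name two columns of `data`.")
  }
  if (anyNA(data[markers])) stop_bad_arg("both markers must be present for all samples.")
  labels <- dplyr::pull(data, {{ group }})
  ctrl <- labels == control
  if (!any(ctrl)) stop_bad_arg(sprintf("control group '%s' is empty.", control))
  m1 <- data[[markers[1]]]
  m2 <- data[[markers[2]]]
  score <- if (method == "zsum") {
    # a marker with zero control-group spread is centred but not scaled
    scale1 <- if (sd(m1[ctrl]) > 0) sd(m1[ctrl]) else 1
    scale2 <- if (sd(m2[ctrl]) > 0) sd(m2[ctrl]) else 1
    (m1 - mean(m1[ctrl])) / scale1 + (m2 - mean(m2[ctrl])) / scale2
  } else {
    as.numeric(m1 > mean(m1[ctrl]) | m2 > mean(m2[ctrl]))
  }
  data[[name]] <- score
  data
}

#' Per-group marker summaries and pairwise rank tests
#'
#' Boxplot statistics (median, type-7 quartiles, Tukey whiskers, mean,
#' sd) of a marker per group, together with Mann-Whitney (Wilcoxon
#' rank-sum) p-values for every pairwise group contrast. The test is
#' exact when both groups have at most 20 samples and no ties are
#' present, and uses the normal approximation with continuity and tie
#' correction otherwise.
#'
#' @inheritParams roc_auc
#'
#' @return A `group_summary` list: `$stats`, one row per group, and
#'   `$tests`, one row per group pair with the Mann-Whitney U statistic
#'   and p-value.
#' @export
group_summary <- function(data, marker, group) {
  data <- as_tibble(data)
  values <- dplyr::pull(data, {{ marker }})
  labels <- as.character(dplyr::pull(data, {{ group }}))
  split_vals <- split(values, labels)
  sizes <- vapply(split_vals, length, integer(1))
  if (any(sizes < 2L)) {
    stop_bad_arg(sprintf(
      "group(s) with fewer than 2 samples: %s",
      paste(names(sizes)[sizes < 2L], collapse = ", ")
    ))
  }
  stats <- purrr::imap_dfr(split_vals, function(v, g) {
    dplyr::bind_cols(tibble(group = g), distance_summary(v)) |>
      dplyr::rename_with(~ sub("_nm$", "", .x))
  })
  pairs <- utils::combn(names(split_vals), 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(p) {
    a <- split_vals[[p[1]]]
    b <- split_vals[[p[2]]]
    exact <- length(a) <= 20L && length(b) <= 20L && !any(duplicated(c(a, b)))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    tibble(
      group1 = p[1], group2 = p[2],
      statistic_u = unname(wt$statistic), p_value = wt$p.value
    )
  })
  structure(list(stats = stats, tests = tests), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\n$stats\n")
  print(x$stats)
  cat("\n$tests (Mann-Whitney)\n")
  print(x$tests)
  invisible(x)
}

#' @describeIn group_summary Per-group boxplot statistics.
#' @param x A `group_summary`.
#' @param ... Unused.
#' @export
tidy.group_summary <- function(x, ...) x$stats
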