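#' Method-comparison statistics for mesangial morphometry
#'
#' Harness for comparing volume estimates from the three methods (TEM
#' planimetry, PSI point counting, 3D reconstruction) on the same units:
#' one-way within-subject (repeated-measures) ANOVA, post-hoc paired
#' contrasts with percent differences, pairwise Pearson correlations, and
#' between-group comparisons of morphometric records.
#'
#' @name comparison
NULL

#' Assemble a complete-case measurement table
#'
#' @param data A data frame with one measurement per row.
#' @param unit,method,value Column names (tidy-eval) identifying the
#'   measured unit, the method label, and the non-negative measurement.
#' @return A tibble `(unit, method, value)` restricted to units measured by
#'   every method; the number of dropped (incomplete) units is attached as
#'   attribute `n_dropped` and reported via a message when non-zero.
#' @export
measurement_table <- function(data, unit = unit, method = method,
                              value = value) {
  tbl <- dplyr::transmute(
    data,
    unit = as.character({{ unit }}),
    method = as.character({{ method }}),
    value = as.numeric({{ value }})
  )
  if (any(tbl$value < 0, na.rm = TRUE)) {
    abort("Measurements must be non-negative volumes/areas.")
  }
  if (anyDuplicated(tbl[c("unit", "method")])) {
    abort("Each unit must have exactly one value per method.")
  }
  k <- length(unique(tbl$method))
  complete <- tbl |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$unit) |>
    dplyr::filter(dplyr::n() == k) |>
    dplyr::ungroup()
  n_dropped <- length(unique(tbl$unit)) - length(unique(complete$unit))
  if (n_dropped > 0) {
    message(sprintf("Dropped %d unit(s) without all %d methods.",
                    n_dropped, k))
  }
  attr(complete, "n_dropped") <- n_dropped
  complete
}

#' One-way within-subject (repeated-measures) ANOVA across methods
#'
#' Standard decomposition SS_total = SS_method + SS_subject + SS_error with
#' F = MS_method / MS_error on (k - 1, (k - 1)(n - 1)) degrees of freedom;
#' no sphericity correction is applied by default (set
#' `gg_correction = TRUE` to also report Greenhouse-Geisser adjusted
#' results).
#'
#' @param table A complete-case table from [measurement_table()].
#' @param gg_correction Also compute the Greenhouse-Geisser epsilon and
#'   corrected p-value.
#' @return A `glom_rm_anova` object with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
repeated_measures_anova <- function(table, gg_correction = FALSE) {
  methods <- sort(unique(table$method))
  units <- unique(table$unit)
  k <- length(methods)
  n <- length(units)
  if (k < 2L) abort("At least 2 methods are required.")
  if (n < 2L) {
    abort("At least 2 complete units are required.",
          class = "glom_insufficient_data")
  }
  df <- table
  df$method <- factor(df$method, levels = methods)
  df$unit_f <- factor(df$unit, levels = units)
  fit <- stats::aov(value ~ method + Error(unit_f), data = df)
  s <- summary(fit)
  within <- s[[grep("Within", names(s))]][[1]]
  between <- s[[grep("unit_f", names(s))]][[1]]
  ss_method <- within[trimws(rownames(within)) == "method", "Sum Sq"]
  ss_error <- within[trimws(rownames(within)) == "Residuals", "Sum Sq"]
  ss_subject <- between[1, "Sum Sq"]
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_method <- ss_method / df1
  ms_error <- ss_error / df2
  ss_total <- ss_method + ss_subject + ss_error
  no_effect <- ss_method <= 1e-12 * max(ss_total, 1)
  infinite_f <- !no_effect && ms_error <= 1e-12 * ms_method
  f <- if (no_effect) 0 else if (infinite_f) Inf else ms_method / ms_error
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  means <- tapply(df$value, df$method, mean)
  out <- list(
    f_statistic = f,
    df_between = df1,
    df_error = df2,
    p_value = p,
    grand_mean = mean(df$value),
    per_method_means = means,
    ss = c(method = ss_method, subject = ss_subject, error = ss_error),
    n_units = n,
    k_methods = k,
    infinite_f = infinite_f,
    sphericity_correction = NULL
  )
  if (gg_correction) {
    wide <- matrix(df$value[order(df$unit_f, df$method)], nrow = n,
                   byrow = TRUE)
    S <- stats::cov(wide)
    jk <- matrix(1 / k, k, k)
    Sc <- S - jk %*% S - S %*% jk + jk %*% S %*% jk
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    out$sphericity_correction <- list(
      epsilon = eps,
      p_value = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    )
  }
  structure(out, class = "glom_rm_anova")
}

#' @export
print.glom_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_error, x$f_statistic, x$p_value))
  cat("Method means:",
      paste(sprintf("%s = %.4g", names(x$per_method_means),
                    x$per_method_means), collapse = ", "), "\n")
  if (!is.null(x$sphericity_correction)) {
    cat(sprintf("Greenhouse-Geisser: epsilon = %.3f, corrected p = %.4g\n",
                x$sphericity_correction$epsilon,
                x$sphericity_correction$p_value))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.glom_rm_anova <- function(x, ...) {
  tibble(
    term = c("method", "subject", "residuals"),
    sumsq = unname(x$ss),
    df = c(x$df_between, x$n_units - 1L, x$df_error),
    meansq = unname(x$ss) / c(x$df_between, x$n_units - 1L, x$df_error),
    statistic = c(x$f_statistic, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
}

#' @export
glance.glom_rm_anova <- function(x, ...) {
  tibble(
    statistic = x$f_statistic,
    df = x$df_between,
    df.residual = x$df_error,
    p.value = x$p_value,
    n_units = x$n_units,
    k_methods = x$k_methods,
    grand_mean = x$grand_mean
  )
}

safe_paired_p <- function(d) {
  if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    return(list(p = if (abs(mean(d)) < 1e-12) 1 else 0,
                statistic = if (abs(mean(d)) < 1e-12) 0 else Inf))
  }
  tt <- stats::t.test(d)
  list(p = tt$p.value, statistic = unname(tt$statistic))
}

#' Post-hoc pairwise contrasts between methods
#'
#' For every method pair (A, B): the mean difference, the percent difference
#' `100 (mean_B - mean_A) / mean_A`, and a paired t-test on the within-unit
#' differences, with raw and Bonferroni-adjusted p-values.
#'
#' @param table A complete-case table from [measurement_table()].
#' @return A tibble with one row per method pair.
#' @export
posthoc_contrasts <- function(table) {
  wide <- tidyr::pivot_wider(table, names_from = "method",
                             values_from = "value")
  methods <- setdiff(names(wide), "unit")
  prs <- utils::combn(methods, 2L, simplify = FALSE)
  rows <- purrr::map_dfr(prs, function(pr) {
    a <- wide[[pr[1]]]
    b <- wide[[pr[2]]]
    ma <- mean(a); mb <- mean(b)
    if (abs(ma) < 1e-300) {
      abort("Zero reference mean: percent difference undefined.",
            class = "glom_undefined_percent")
    }
    tt <- safe_paired_p(b - a)
    tibble(
      method_a = pr[1], method_b = pr[2],
      mean_a = ma, mean_b = mb,
      mean_diff = mb - ma,
      pct_diff = 100 * (mb - ma) / ma,
      statistic = tt$statistic,
      p_value = tt$p
    )
  })
  rows$p_bonferroni <- stats::p.adjust(rows$p_value, method = "bonferroni")
  rows
}

#' Pairwise Pearson correlations between methods
#'
#' @param table A complete-case table from [measurement_table()].
#' @return A tibble `(method_a, method_b, r)`.
#' @export
method_correlations <- function(table) {
  wide <- tidyr::pivot_wider(table, names_from = "method",
                             values_from = "value")
  methods <- setdiff(names(wide), "unit")
  if (nrow(wide) < 3L) abort("At least 3 complete units are required.")
  sds <- vapply(wide[methods], stats::sd, numeric(1))
  if (any(sds < 1e-300)) {
    abort("A method column has zero variance: correlation undefined.",
          class = "glom_undefined_correlation")
  }
  prs <- utils::combn(methods, 2L, simplify = FALSE)
  purrr::map_dfr(prs, function(pr) {
    tibble(method_a = pr[1], method_b = pr[2],
           r = stats::cor(wide[[pr[1]]], wide[[pr[2]]]))
  })
}

#' Compare a morphometric quantity between groups
#'
#' Per-group mean and SD, with a Welch t-test for two groups or a one-way
#' ANOVA for three or more.
#'
#' @param data A data frame (e.g. stacked [compute_morphometrics()] rows
#'   joined to a grouping column).
#' @param value,group Columns (tidy-eval) holding the quantity and the group
#'   label.
#' @return A list with `summary` (tibble: group, n, mean, sd) and `test`
#'   (tibble: method, statistic, df, p_value).
#' @export
group_comparison <- function(data, value, group) {
  df <- dplyr::transmute(data, value = as.numeric({{ value }}),
                         group = as.character({{ group }}))
  groups <- unique(df$group)
  if (length(groups) < 2L || any(!table(df$group) >= 1L)) {
    abort("At least 2 non-empty groups are required.")
  }
  summ <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  if (any(summ$n == 1L)) {
    warn("Group of size 1: SD undefined for that group.")
    return(list(summary = summ,
                test = tibble(method = if (length(groups) == 2L) "welch_t" else "oneway_anova",
                              statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_)))
  }
  if (length(groups) == 2L) {
    a <- df$value[df$group == groups[1]]
    b <- df$value[df$group == groups[2]]
    if (stats::sd(c(a - mean(a), b - mean(b))) < 1e-12 * max(1, abs(mean(df$value)))) {
      test <- tibble(method = "welch_t",
                     statistic = if (abs(mean(a) - mean(b)) < 1e-12) 0 else Inf,
                     df = NA_real_,
                     p_value = if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
    } else {
      tt <- stats::t.test(a, b)
      test <- tibble(method = "welch_t", statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value)
    }
  } else {
    fit <- stats::aov(value ~ group, data = df)
    s <- summary(fit)[[1]]
    test <- tibble(method = "oneway_anova",
                   statistic = s[1, "F value"],
                   df = s[1, "Df"],
                   p_value = s[1, "Pr(>F)"])
  }
  list(summary = summ, test = test)
}
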