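make_table <- function(wide, methods = colnames(wide)) {
  tibble::tibble(
    unit = rep(sprintf("u%02d", seq_len(nrow(wide))), times = ncol(wide)),
    method = rep(methods, each = nrow(wide)),
    value = as.numeric(wide)
  )
}

test_that("measurement tables drop incomplete units listwise", {
  raw <- tibble::tibble(
    unit = c("a", "a", "a", "b", "b", "c", "c", "c"),
    method = c("TEM", "PSI", "3D", "TEM", "PSI", "TEM", "PSI", "3D"),
    value = abs(rnorm(8))
  )
  expect_message(tbl <- measurement_table(raw), "Dropped 1")
  expect_equal(sort(unique(tbl$unit)), c("a", "c"))
  expect_equal(attr(tbl, "n_dropped"), 1)
  expect_error(measurement_table(dplyr::mutate(raw, value = -value)))
})

test_that("repeated-measures ANOVA handles the degenerate all-equal case", {
  wide <- matrix(rep(c(1, 2, 3, 4, 5), 3), ncol = 3)
  colnames(wide) <- c("TEM", "PSI", "3D")
  fit <- repeated_measures_anova(make_table(wide))
  expect_equal(fit$f_statistic, 0)
  expect_equal(fit$p_value, 1)
})

test_that("ANOVA df follow (k-1, (k-1)(n-1)), including the 3x9 layout", {
  set.seed(2)
  wide <- matrix(abs(rnorm(27, 10)), ncol = 3,
                 dimnames = list(NULL, c("TEM", "PSI", "3D")))
  fit <- repeated_measures_anova(make_table(wide))
  expect_equal(fit$df_between, 2)
  expect_equal(fit$df_error, 16)
  g <- glance(fit)
  expect_equal(g$df, 2)
  expect_equal(g$df.residual, 16)
})

test_that("ANOVA F matches the brute-force sums-of-squares oracle", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    wide <- matrix(abs(stats::rnorm(n * 3, 10, 2)), ncol = 3,
                   dimnames = list(NULL, c("A", "B", "C")))
    fit <- repeated_measures_anova(make_table(wide))
    oracle <- bf_rm_anova(wide)
    expect_equal(fit$f_statistic, oracle$f, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
    # decomposition identity
    expect_equal(sum(fit$ss), oracle$ss[["total"]], tolerance = 1e-9)
  }
})

test_that("zero within-unit error is flagged as infinite F", {
  wide <- cbind(A = c(1, 2, 3, 4), B = c(2, 3, 4, 5)) # perfect shift
  fit <- repeated_measures_anova(make_table(wide))
  expect_true(fit$infinite_f)
  expect_true(is.infinite(fit$f_statistic))
})

test_that("post-hoc contrasts report percent differences and paired tests", {
  set.seed(4)
  a <- abs(rnorm(10, 10))
  wide <- cbind(A = a, B = 0.70 * a)
  ph <- posthoc_contrasts(make_table(wide))
  expect_equal(ph$pct_diff[ph$method_a == "A" & ph$method_b == "B"], -30,
               tolerance = 1e-9)
  # identical columns: 0 percent, p = 1
  ph0 <- posthoc_contrasts(make_table(cbind(A = a, B = a)))
  expect_equal(ph0$pct_diff, 0)
  expect_equal(ph0$p_value, 1)
  # antisymmetry: (1 + pct(A,B)/100)(1 + pct(B,A)/100) = 1
  wide3 <- cbind(A = a, B = 0.7 * a, C = 1.2 * a)
  tbl_ab <- make_table(wide3)
  tbl_ba <- make_table(wide3[, c(2, 1, 3)])
  p_ab <- posthoc_contrasts(tbl_ab)
  p_ba <- posthoc_contrasts(tbl_ba)
  pct1 <- p_ab$pct_diff[p_ab$method_a == "A" & p_ab$method_b == "B"]
  pct2 <- p_ba$pct_diff[p_ba$method_a == "B" & p_ba$method_b == "A"]
  expect_equal((1 + pct1 / 100) * (1 + pct2 / 100), 1, tolerance = 1e-12)
})

test_that("pairwise correlations match the linear-relation closed forms", {
  a <- c(1, 3, 2, 8, 5)
  tbl <- make_table(cbind(A = a, B = 2 * a, C = -a + 10))
  rr <- method_correlations(tbl)
  expect_equal(rr$r[rr$method_a == "A" & rr$method_b == "B"], 1.0)
  expect_equal(rr$r[rr$method_a == "A" & rr$method_b == "C"], -1.0)
  expect_error(
    method_correlations(make_table(cbind(A = a, B = rep(1, 5)))),
    class = "glom_undefined_correlation")
})

test_that("group comparison covers t-test, ANOVA and degenerate groups", {
  df <- tibble::tibble(ratio = c(1, 2, 3, 1, 2, 3),
                       grp = rep(c("x", "y"), each = 3))
  res <- group_comparison(df, ratio, grp)
  expect_equal(res$test$p_value, 1)
  set.seed(6)
  df2 <- tibble::tibble(
    v = c(rnorm(10, 0, 1), rnorm(10, 10, 1)),
    grp = rep(c("lo", "hi"), each = 10))
  expect_lt(group_comparison(df2, v, grp)$test$p_value, 1e-6)
  df3 <- tibble::tibble(v = rnorm(9), grp = rep(c("a", "b", "c"), each = 3))
  expect_equal(group_comparison(df3, v, grp)$test$method, "oneway_anova")
  expect_warning(
    group_comparison(tibble::tibble(v = c(1, 2, 3), grp = c("a", "a", "b")),
                     v, grp),
    "size 1")
})

test_that("Greenhouse-Geisser correction is reported when requested", {
  set.seed(10)
  wide <- matrix(abs(rnorm(24, 10)), ncol = 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  fit <- repeated_measures_anova(make_table(wide), gg_correction = TRUE)
  eps <- fit$sphericity_correction$epsilon
  expect_gte(eps, 1 / 2) # lower bound 1/(k-1)
  expect_lte(eps, 1 + 1e-9)
  expect_gte(fit$sphericity_correction$p_value, fit$p_value - 1e-12)
})
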