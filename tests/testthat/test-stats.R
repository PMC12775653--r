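test_that("Grubbs' test flags a planted outlier and matches the formula", {
  x <- c(8, 9, 10, 50)
  g <- grubbs_test(x)
  expect_identical(g$index, 4L)
  # long-hand statistic and critical value
  expect_equal(g$G, max(abs(x - mean(x))) / sd(x))
  n <- 4
  tq <- qt(1 - 0.05 / (2 * n), n - 2)
  expect_equal(g$critical, (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)))
  # a tame sample flags nothing
  expect_null(grubbs_test(c(8, 9, 10, 11))$index)
  # constant data has no outliers
  expect_null(grubbs_test(rep(3, 5))$index)
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

test_that("iterative Grubbs screening removes points one at a time", {
  x <- c(10, 11, 9, 10, 12, 11, 10, 9, 100)
  s <- grubbs_screen(x)
  expect_identical(s$excluded, 9L)
  expect_equal(s$clean, x[-9])
  # nothing to remove
  s2 <- grubbs_screen(c(1, 2, 3, 4))
  expect_identical(s2$excluded, integer(0))
})

test_that("Grubbs' null flag rate stays near its nominal level", {
  set.seed(314)
  flags <- replicate(2000, {
    !is.null(grubbs_test(rnorm(10))$index)
  })
  expect_lt(mean(flags), 0.07)
  expect_gt(mean(flags), 0.02)
})

test_that("Welch t test matches the long-hand computation", {
  set.seed(8)
  a <- rnorm(12, 1, 1.5)
  b <- rnorm(9, 0, 0.7)
  r <- group_ttest(a, b)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df_hand))
  expect_equal(r$estimate, mean(a) - mean(b))
  expect_identical(r$test, "Welch t")
  # swapping the groups flips the sign, not the p value
  r2 <- group_ttest(b, a)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
})

test_that("paired t test equals a one-sample test on differences", {
  set.seed(9)
  a <- rnorm(10, 0.5)
  b <- rnorm(10)
  r <- group_ttest(a, b, paired = TRUE)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, 9)
  expect_error(group_ttest(a, b[1:5], paired = TRUE), "equal lengths")
})

test_that("Grubbs pre-screening is recorded on the comparison", {
  a <- c(rnorm(10, 0, 0.2) + 5, 50)
  b <- rnorm(10, 4.8, 0.2)
  r <- group_ttest(a, b, grubbs_alpha = 0.05)
  expect_identical(r$excluded_a, 11L)
  expect_identical(r$n_a, 10L)
})

test_that("two-condition repeated-measures F equals the squared paired t", {
  set.seed(12)
  y <- cbind(rnorm(9, 1), rnorm(9, 1.4))
  a <- rm_anova_gg(y)
  tt <- group_ttest(y[, 1], y[, 2], paired = TRUE)
  expect_equal(a$F, tt$statistic^2)
  expect_equal(a$epsilon, 1)  # two conditions are always spherical
  expect_equal(a$p_value, tt$p_value)
})

test_that("Greenhouse-Geisser correction matches an independent package", {
  set.seed(13)
  y <- matrix(rnorm(24), 8, 3)
  y[, 3] <- y[, 3] + 0.8 * y[, 1]  # induce non-sphericity
  a <- rm_anova_gg(y)
  mod <- stats::lm(y ~ 1)
  idata <- data.frame(cond = factor(1:3))
  s <- summary(car::Anova(mod, idata = idata, idesign = ~cond, type = 3),
               multivariate = FALSE)
  eps_ref <- s$pval.adjustments["cond", "GG eps"]
  p_ref <- s$pval.adjustments["cond", "Pr(>F[GG])"]
  f_ref <- s$univariate.tests["cond", "F value"]
  expect_equal(a$epsilon, unname(eps_ref), tolerance = 1e-10)
  expect_equal(a$F, unname(f_ref), tolerance = 1e-10)
  expect_equal(a$p_value, unname(p_ref), tolerance = 1e-10)
})

test_that("repeated-measures ANOVA validates input and reports Tukey", {
  set.seed(14)
  y <- matrix(rnorm(15), 5, 3)
  a <- rm_anova_gg(y)
  expect_identical(nrow(a$tukey), 3L)
  expect_true(all(a$tukey$p_adj >= 0 & a$tukey$p_adj <= 1))
  expect_equal(a$tukey$diff,
               c(mean(y[, 2]) - mean(y[, 1]),
                 mean(y[, 3]) - mean(y[, 1]),
                 mean(y[, 3]) - mean(y[, 2])))
  yna <- y; yna[2, 2] <- NA
  expect_error(rm_anova_gg(yna), "complete")
  expect_error(rm_anova_gg(y[, 1, drop = FALSE]), "2 conditions")
  expect_error(rm_anova_gg(y[1, , drop = FALSE]), "2 subjects")
  # identical conditions: no effect, p = 1
  same <- matrix(rep(rnorm(4), 3), 4, 3)
  a0 <- rm_anova_gg(same)
  expect_equal(a0$F, 0)
  expect_equal(a0$p_value, 1)
})

test_that("Pearson correlation matches the direct formula", {
  set.seed(15)
  x <- rnorm(20)
  y <- 0.6 * x + rnorm(20, 0, 0.5)
  r <- pearson_cor(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_hand)
  expect_equal(r$r_squared, r_hand^2)
  t_hand <- r_hand * sqrt(18 / (1 - r_hand^2))
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 18))
  expect_true(r$defined)
  # degenerate input is flagged, not silently numeric
  z <- pearson_cor(rep(1, 5), rnorm(5))
  expect_false(z$defined)
  expect_true(is.na(z$r))
  expect_error(pearson_cor(1:3, 1:4), "lengths differ")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})
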