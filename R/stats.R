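#' Grubbs' test for a single outlier
#'
#' Two-sided Grubbs statistic \eqn{G = \max_i |x_i - \bar x| / s} compared
#' against the t-based critical value
#' \eqn{\frac{n-1}{\sqrt n}\sqrt{t^2 / (n - 2 + t^2)}} with
#' \eqn{t = t_{\alpha/(2n),\, n-2}}. At most one point is flagged per call;
#' use [grubbs_screen()] for the iterative exclusion procedure. Constant
#' data (zero variance) flags nothing.
#'
#' @param x numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `index` (flagged position, or `NULL`), `G`,
#'   `critical`.
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stop("Grubbs' test needs at least 3 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(list(index = NULL, G = 0,
                                           critical = NA_real_))
  dev <- abs(x - mean(x))
  G <- max(dev) / s
  tq <- qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(index = if (G > crit) which.max(dev) else NULL,
       G = G, critical = crit)
}

#' Iterative Grubbs outlier screening
#'
#' Repeatedly applies [grubbs_test()], removing the flagged point each
#' round, until nothing is flagged or fewer than 3 points remain. Excluded
#' indices (in the original vector) are recorded, never silently dropped.
#'
#' @inheritParams grubbs_test
#' @return list with `clean` (retained values), `excluded` (original
#'   indices of removed points).
#' @export
grubbs_screen <- function(x, alpha = 0.05) {
  keep <- seq_along(x)
  excluded <- integer(0)
  while (length(keep) >= 3) {
    g <- grubbs_test(x[keep], alpha)
    if (is.null(g$index)) break
    excluded <- c(excluded, keep[g$index])
    keep <- keep[-g$index]
  }
  list(clean = x[keep], excluded = excluded)
}

#' Two-tailed t test between groups
#'
#' Unpaired comparisons use Welch's unequal-variance form; paired
#' comparisons use the paired Student t. Optional Grubbs pre-screening
#' records the excluded indices on the result.
#'
#' @param a,b numeric vectors (equal lengths when `paired`).
#' @param paired paired comparison (e.g. tumor vs contralateral brain in
#'   the same subjects)?
#' @param var_equal pooled-variance Student form for unpaired tests
#'   (default `FALSE`, Welch).
#' @param grubbs_alpha if non-`NULL`, screen each group (or the paired
#'   differences) with iterative Grubbs at this level first.
#' @return A `group_comparison` list: `test`, `statistic`, `df`, `p_value`,
#'   `estimate`, `excluded_a`, `excluded_b`, `n_a`, `n_b`.
#' @export
group_ttest <- function(a, b, paired = FALSE, var_equal = FALSE,
                        grubbs_alpha = NULL) {
  excluded_a <- excluded_b <- integer(0)
  if (paired && length(a) != length(b))
    stop("paired test needs equal lengths")
  if (!is.null(grubbs_alpha)) {
    if (paired) {
      g <- grubbs_screen(a - b, grubbs_alpha)
      if (length(g$excluded)) {
        excluded_a <- excluded_b <- g$excluded
        a <- a[-g$excluded]; b <- b[-g$excluded]
      }
    } else {
      ga <- grubbs_screen(a, grubbs_alpha)
      gb <- grubbs_screen(b, grubbs_alpha)
      excluded_a <- ga$excluded; excluded_b <- gb$excluded
      a <- ga$clean; b <- gb$clean
    }
  }
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  tt <- t.test(a, b, paired = paired, var.equal = var_equal,
               alternative = "two.sided")
  structure(list(test = if (paired) "paired t" else
                   if (var_equal) "pooled t" else "Welch t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 estimate = unname(if (paired) tt$estimate else
                                     diff(rev(tt$estimate))),
                 excluded_a = excluded_a, excluded_b = excluded_b,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' One-way repeated-measures ANOVA with Geisser-Greenhouse correction
#'
#' Within-subject one-way ANOVA on a complete subjects-by-conditions
#' matrix. The Greenhouse-Geisser sphericity estimate
#' \eqn{\hat\varepsilon = (\mathrm{tr}\,A)^2 / ((k-1)\,\mathrm{tr}\,A^2)},
#' with \eqn{A} the double-centered condition covariance matrix, scales
#' both numerator and denominator degrees of freedom of the omnibus F.
#' Pairwise condition comparisons use Tukey's HSD on the studentized-range
#' distribution with the same GG-adjusted error degrees of freedom.
#'
#' @param y numeric matrix, rows = subjects, columns = conditions; must be
#'   complete (no `NA`; missing subjects are excluded upstream, not
#'   imputed).
#' @return list with `F`, `df1`, `df2` (uncorrected), `epsilon`,
#'   `p_value` (GG-corrected), `ms_error`, and `tukey` (data frame of
#'   pairwise differences, q statistics and adjusted p values).
#' @export
rm_anova_gg <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("matrix must be complete; exclude missing subjects")
  n <- nrow(y); k <- ncol(y)
  if (k < 2) stop("need at least 2 conditions")
  if (n < 2) stop("need at least 2 subjects")
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  grand <- mean(y)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- y - outer(subj_means, cond_means, "+") + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  F_stat <- if (ss_err == 0 && ss_cond == 0) 0 else
    (ss_cond / df1) / ms_err
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(y)
  Cc <- diag(k) - matrix(1 / k, k, k)
  A <- Cc %*% S %*% Cc
  eps <- if (sum(A * A) == 0) 1 else sum(diag(A))^2 / (df1 * sum(A * A))
  eps <- min(max(eps, 1 / df1), 1)
  p <- if (ss_err == 0) {
    if (ss_cond == 0) 1 else 0
  } else pf(F_stat, eps * df1, eps * df2, lower.tail = FALSE)
  if (ss_cond == 0 && ss_err > 0 && F_stat == 0) p <- 1
  pairs <- utils::combn(k, 2)
  se <- sqrt(ms_err / n)
  tukey <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    diff = cond_means[pairs[2, ]] - cond_means[pairs[1, ]])
  tukey$q <- if (se > 0) abs(tukey$diff) / se else
    ifelse(tukey$diff == 0, 0, Inf)
  tukey$p_adj <- ptukey(tukey$q, nmeans = k, df = eps * df2,
                        lower.tail = FALSE)
  list(F = F_stat, df1 = df1, df2 = df2, epsilon = eps, p_value = p,
       ms_error = ms_err, tukey = tukey)
}

#' Pearson correlation with R-squared
#'
#' Product-moment correlation with a two-tailed p value from the t
#' transform (via `stats::cor.test`). Zero variance in either variable is
#' flagged as undefined rather than returned as a number.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `r_squared`, `p_value`, `n`, `defined`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                n = length(x), defined = FALSE))
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(x),
       defined = TRUE)
}
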