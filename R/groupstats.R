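#' Group-level statistics for paired parameter contrasts
#'
#' @description
#' Thin, convention-fixing wrappers around the classical tests used to
#' contrast fitted parameters between retro-cue and control conditions.
#' Because fitted parameters are typically non-normal across participants,
#' the pipeline relies on robust summaries (medians with bootstrap standard
#' errors) and non-parametric tests; the paired t test is used for mean
#' absolute error across data sets. All return a one-row tibble with columns
#' `method`, `statistic`, `df`, `p_value`, `n`.
#'
#' * `paired_t()` — classical paired t on the differences (`df = n - 1`,
#'   two-sided). If every difference is exactly zero the statistic is
#'   reported as 0 with p = 1 (the undefined-0/0 case, by convention).
#' * `wilcoxon_signed_rank()` — two-sided Wilcoxon signed-rank with zero
#'   differences dropped and midranks for ties; exact distribution for
#'   `n <= 25` without ties, normal approximation with continuity correction
#'   otherwise.
#' * `sign_test()` — two-sided exact binomial test on the signs of the
#'   differences, ties dropped (p capped at 1).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row tibble (`GroupResult`).
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1))   # differences 1, 2, 3: t = 3.464, df = 2
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (all(d == 0)) {
    return(group_result("paired t", 0, length(d) - 1, 1, length(d)))
  }
  if (sd(d) == 0) {
    abort("differences have zero variance; the t statistic is undefined.")
  }
  tt <- t.test(x, y, paired = TRUE)
  group_result("paired t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, length(d))
}

#' @rdname paired_t
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- (x - y)[x != y]
  if (length(d) == 0) abort("all differences are zero.")
  if (length(d) < 5) {
    warn("fewer than 5 non-zero differences; the signed-rank test has little power.")
  }
  ties <- any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, exact = length(d) <= 25 && !ties, correct = TRUE))
  group_result("wilcoxon signed-rank", unname(wt$statistic), NA_real_,
               wt$p.value, length(d))
}

#' @rdname paired_t
#' @export
sign_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  s <- sign(x - y)
  s <- s[s != 0]
  if (length(s) == 0) abort("all pairs are tied; the sign test is undefined.")
  bt <- binom.test(sum(s > 0), length(s), p = 0.5)
  group_result("sign test", sum(s > 0), NA_real_, min(bt$p.value, 1), length(s))
}

group_result <- function(method, statistic, df, p, n) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_value = p, n = n)
}

#' Bootstrap standard error of the median
#'
#' Standard deviation of the medians of `reps` resamples drawn with
#' replacement; the conventional error bar for median parameter estimates.
#'
#' @param x Numeric vector (`n >= 2`).
#' @param reps Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return The bootstrap standard error (scalar).
#' @export
bootstrap_median_se <- function(x, reps = 1000L, seed = NULL) {
  stopifnot(length(x) >= 2, reps >= 2)
  draw <- function() {
    idx <- matrix(sample.int(length(x), length(x) * reps, replace = TRUE),
                  nrow = reps)
    sd(apply(idx, 1, function(i) median(x[i])))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Correlation between fitted parameters across experiments, with ANCOVA
#'
#' @description
#' Correlates two per-data-set median parameter values across experiment x
#' condition points, after z-scoring each variable across all points (the
#' standardization used for cross-experiment parameter scatter). Reports the
#' Pearson correlation with its two-sided t-based p value, and an ANCOVA —
#' the ordinary least squares model `y ~ x + condition` (common slope,
#' condition intercepts) — with a partial F test on the condition factor.
#'
#' @param x,y Numeric vectors of per-data-set medians.
#' @param condition Factor/character vector of condition labels (e.g.
#'   `"retrocue"` / `"control"`) of the same length.
#' @param z_score Standardize each variable before analysis? (default TRUE)
#' @return A one-row tibble with `r`, `p_value`, `n`, `ancova_f`,
#'   `ancova_df1`, `ancova_df2`, `ancova_p`.
#' @export
pearson_ancova <- function(x, y, condition, z_score = TRUE) {
  stopifnot(length(x) == length(y), length(x) == length(condition),
            length(x) >= 4)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y; correlation undefined.")
  }
  if (z_score) {
    x <- (x - mean(x)) / sd(x)
    y <- (y - mean(y)) / sd(y)
  }
  ct <- cor.test(x, y)
  fit0 <- lm(y ~ x)
  fit1 <- lm(y ~ x + factor(condition))
  av <- anova(fit0, fit1)
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
    ancova_f = av$F[2], ancova_df1 = av$Df[2], ancova_df2 = av$Res.Df[2],
    ancova_p = av$`Pr(>F)`[2]
  )
}
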