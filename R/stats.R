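# Statistical machinery shared by all analysis stages: exact 2x2 tests with
# Haldane-corrected odds ratios, BH-FDR, rank tests, one-way ANOVA with
# Tukey HSD, add-one permutation p-values, correlation, and the
# patient-random-intercept mixed-model association test.

#' Construct a test-result object
#'
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value in `[0, 1]`.
#' @param estimate Effect estimate (e.g. odds ratio, slope, correlation).
#' @param method Short description of the test performed.
#' @param ... Further named fields stored on the object.
#' @return A list of class `tcr_test`.
#' @keywords internal
tcr_test <- function(statistic, p_value, estimate, method, ...) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = statistic, p_value = p_value,
                 estimate = estimate, method = method, ...),
            class = "tcr_test")
}

#' @export
print.tcr_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat("  estimate = ", format(x$estimate, digits = 4),
      ", statistic = ", format(x$statistic, digits = 4),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

# Two-sided hypergeometric p for a 2x2 table with margins (m, n) and k
# draws, observed first cell a: sum of the probabilities of all tables with
# the same margins whose probability does not exceed the observed one
# (small relative slack absorbs floating-point ties).
.fisher_p_two_sided <- function(a, m, n, k) {
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  sum(dens[dens <= dens[a - support[1] + 1L] * (1 + 1e-7)])
}

# Sample odds ratio with the Haldane correction (0.5 added to every cell)
# applied only when some cell is zero.
.haldane_or <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the conditional hypergeometric null, computed by
#' enumeration of all tables with the observed margins (the "probability
#' less than or equal to the observed table" rule). The reported estimate
#' is the sample odds ratio `(a d)/(b c)`, with the Haldane correction
#' (+0.5 to all cells) applied only when some cell is zero.
#'
#' @param a,b,c,d The table cells, row-major: `a` shared/success in both
#'   classifications. `a` may also be a 2x2 matrix, in which case `b,c,d`
#'   are ignored.
#' @return A [tcr_test] with `estimate` the (Haldane-corrected) sample odds
#'   ratio, `statistic` the observed first cell, and `table` the input.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 85)$estimate  # (5*85)/(5*5) = 17
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- unname(c(a, b, c, d))
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("table cells must be nonnegative integers")
  }
  if (sum(cells) < 1) stop("all-zero 2x2 table")
  p <- .fisher_p_two_sided(a, a + b, c + d, a + c)
  tcr_test(statistic = a, p_value = min(1, p),
           estimate = .haldane_or(a, b, c, d),
           method = "Fisher's exact test (two-sided)",
           table = matrix(cells, 2, 2, byrow = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value by enumeration for small samples without ties
#' (`n_x + n_y <= 12`), otherwise the normal approximation with midranks,
#' tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return A [tcr_test] with `statistic` the U statistic for `x`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tcr_test(statistic = unname(wt$statistic), p_value = wt$p.value,
           estimate = stats::median(x) - stats::median(y),
           method = paste0("Mann-Whitney U (two-sided, ",
                           if (exact) "exact" else "normal approximation",
                           ")"))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' If the pooled within-group variance is zero (all values identical within
#' every group and across groups) the comparison is degenerate and all
#' p-values are reported as 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, one per observation; at least two groups
#'   with at least two observations each.
#' @return A list with `anova` (a [tcr_test] holding F and its p-value) and
#'   `pairs` (tibble: `contrast`, `diff`, `p_adj` from the studentized
#'   range distribution).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  lev <- levels(groups)
  combos <- utils::combn(lev, 2)
  contrasts <- paste(combos[2, ], combos[1, ], sep = "-")
  if (stats::var(values) == 0) {
    pairs <- tibble::tibble(contrast = contrasts, diff = 0, p_adj = 1)
    return(list(anova = tcr_test(0, 1, 0, "one-way ANOVA (degenerate: zero variance)"),
                pairs = pairs))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$groups
  pairs <- tibble::tibble(contrast = rownames(tuk),
                          diff = tuk[, "diff"],
                          p_adj = pmin(1, tuk[, "p adj"]))
  list(anova = tcr_test(statistic = tab["groups", "F value"],
                        p_value = tab["groups", "Pr(>F)"],
                        estimate = tab["groups", "F value"],
                        method = "one-way ANOVA"),
       pairs = pairs)
}

#' Permutation p-value with the add-one rule
#'
#' `p = (1 + #\{draws >= observed\}) / (1 + n_draws)`; never zero, so an
#' observation exceeding all of 1000 null draws is reported as
#' `1/1001 < 0.001`.
#'
#' @param observed Observed statistic.
#' @param null_draws Statistic under the permutation null (>= 1 draw).
#' @return p-value in `(0, 1]`.
#' @export
permutation_p <- function(observed, null_draws) {
  if (length(null_draws) < 1) stop("need at least one null draw")
  (1 + sum(null_draws >= observed)) / (1 + length(null_draws))
}

#' Mixed-model association with a patient random intercept
#'
#' Fits `y ~ x + (1 | group)` by maximum likelihood and tests the slope by
#' a likelihood-ratio test against the intercept-only model with the same
#' random effect. If the fit is singular or fails, the function falls back
#' to ordinary least squares on patient-demeaned `y` and `x` (flagged in
#' the `method` field).
#'
#' @param y,x Numeric vectors, one value per sample.
#' @param group Patient identifier per sample; at least two patients, at
#'   least two of them with two or more samples.
#' @return A [tcr_test] with `estimate` the slope of `y` on `x`.
#' @export
lmm_association <- function(y, x, group) {
  stopifnot(length(y) == length(x), length(y) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2 || sum(table(group) >= 2) < 2) {
    stop("need >= 2 patients, at least two of them with repeated samples")
  }
  fit <- tryCatch({
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | group), REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | group), REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    if (lme4::isSingular(full, tol = 1e-5)) stop("singular fit")
    lrt <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null)))
    tcr_test(statistic = lrt,
             p_value = stats::pchisq(max(0, lrt), df = 1, lower.tail = FALSE),
             estimate = unname(lme4::fixef(full)["x"]),
             method = "linear mixed model (patient random intercept, LRT)")
  }, error = function(e) NULL)
  if (!is.null(fit)) return(fit)

  # fallback: patient-demeaned OLS
  yd <- y - stats::ave(y, group)
  xd <- x - stats::ave(x, group)
  if (stats::var(xd) == 0) {
    return(tcr_test(NA_real_, 1, 0,
                    "patient-demeaned OLS (no within-patient variation in x)"))
  }
  ols <- stats::lm(yd ~ xd)
  co <- suppressWarnings(summary(ols))$coefficients
  p <- if (nrow(co) < 2 || !is.finite(co["xd", 4])) 0 else co["xd", 4]
  tcr_test(statistic = co["xd", 3], p_value = p, estimate = co["xd", 1],
           method = "patient-demeaned OLS (singular mixed-model fallback)")
}

#' Correlation test
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param method `"pearson"` or `"spearman"`.
#' @return A [tcr_test] with `estimate` the correlation coefficient.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tcr_test(statistic = unname(ct$statistic), p_value = ct$p.value,
           estimate = unname(ct$estimate),
           method = paste0(method, " correlation"))
}
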