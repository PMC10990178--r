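# Statistical workflow for two-group cohort comparisons across speeds:
# assumption checks, characteristic comparisons, mixed (between x within)
# repeated-measures ANOVA with sphericity handling, Holm post-hocs,
# Cohen's d and confidence intervals of mean differences.

#' Statistics configuration
#'
#' @param alpha Significance level (default 0.05); also gates the
#'   Greenhouse-Geisser correction via Mauchly's test.
#' @param ci_level Confidence level for mean-difference intervals.
#' @param d_thresholds Increasing `(small, moderate, large)` magnitude
#'   bounds for classifying Cohen's d (default 0.2, 0.5, 0.8).
#' @param normality `"lilliefors"` (composite-null Kolmogorov-Smirnov with
#'   parameters estimated from the data; default) or `"ks"` (plain KS
#'   against the fitted normal, anticonservative).
#' @param levene_center Centering for Levene's test: `"mean"` (classic,
#'   default) or `"median"` (Brown-Forsythe variant).
#' @param welch Use Welch (unpooled) intervals/tests for two-group mean
#'   differences instead of the pooled-variance default.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, ci_level = 0.95,
                         d_thresholds = c(0.2, 0.5, 0.8),
                         normality = c("lilliefors", "ks"),
                         levene_center = c("mean", "median"),
                         welch = FALSE) {
  stopifnot(alpha > 0, alpha < 1, ci_level > 0, ci_level < 1,
            length(d_thresholds) == 3, all(diff(d_thresholds) > 0))
  structure(list(alpha = alpha, ci_level = ci_level,
                 d_thresholds = d_thresholds,
                 normality = match.arg(normality),
                 levene_center = match.arg(levene_center),
                 welch = isTRUE(welch)),
            class = "stats_config")
}

#' Cohen's d from group summary statistics
#'
#' Standardised mean difference using the pooled standard deviation,
#' `d = (mean2 - mean1) / s_p` with
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`. The sign
#' convention is second-listed group minus first-listed group. No
#' small-sample (Hedges) correction is applied.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return Cohen's d (scalar).
#' @export
#' @examples
#' cohens_d(179, 7, 35, 174, 8, 45)
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0)
    stop("undefined effect: zero pooled standard deviation", call. = FALSE)
  (mean2 - mean1) / sqrt(sp2)
}

#' Classify an effect size magnitude
#'
#' @param d Cohen's d (vectorised).
#' @param thresholds Increasing `(small, moderate, large)` bounds.
#' @return Character vector: `"trivial"`, `"small"`, `"moderate"` or
#'   `"large"` by `|d|` against the bounds.
#' @export
classify_d <- function(d, thresholds = c(0.2, 0.5, 0.8)) {
  cut(abs(d), breaks = c(-Inf, thresholds, Inf),
      labels = c("trivial", "small", "moderate", "large"),
      right = FALSE) |> as.character()
}

#' Holm step-down multiple-testing adjustment
#'
#' Order the m raw p-values increasingly, multiply the i-th smallest by
#' (m - i + 1), enforce monotonicity by running maximum, and cap at 1.
#' Controls the family-wise error rate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1L) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mean difference with confidence interval
#'
#' Two-sample interval on `mean(x) - mean(y)` (first-listed group minus
#' second-listed). Pooled-variance t by default; Welch when configured.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param level Confidence level.
#' @param welch Use the Welch-Satterthwaite interval.
#' @return A list with `delta`, `ci_low`, `ci_high`, `se`, `df`,
#'   `t`, and two-sided `p`.
#' @export
mean_diff_ci <- function(x, y, level = 0.95, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient data: each group needs n >= 2", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  delta <- mean(x) - mean(y)
  if (welch) {
    v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0)
    stop("undefined interval: zero pooled variance", call. = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tstat <- delta / se
  list(delta = delta, ci_low = delta - tcrit * se,
       ci_high = delta + tcrit * se, se = se, df = df, t = tstat,
       p = 2 * stats::pt(-abs(tstat), df))
}

#' Power of a two-sample t test for a standardised effect
#'
#' Generic helper for unequal group sizes: power of the two-sided pooled t
#' test to detect Cohen's d, via the noncentral t distribution with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))`. Not an inferential surface
#' of the pipeline; provided for design sanity checks.
#'
#' @param d Standardised mean difference.
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}

# -- assumption checks -------------------------------------------------------

#' Composite-null Kolmogorov-Smirnov (Lilliefors) normality test
#'
#' KS distance of the standardised sample against the standard normal, with
#' the null distribution of the statistic obtained by parametric bootstrap
#' (parameters re-estimated in each replicate), which is what the
#' Lilliefors correction amounts to. The bootstrap uses an internal fixed
#' stream and restores the caller's RNG state, so results are deterministic
#' and do not perturb user seeds.
#'
#' @param x Numeric sample, n >= 4.
#' @param B Bootstrap replicates (default 2000).
#' @return A list with `statistic` (D) and `p`.
#' @export
lilliefors_test <- function(x, B = 2000) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("insufficient data for a normality test", call. = FALSE)
  d_stat <- function(v) {
    z <- sort((v - mean(v)) / stats::sd(v))
    pz <- stats::pnorm(z)
    i <- seq_along(z)
    max(i / n - pz, pz - (i - 1) / n)
  }
  D <- d_stat(x)
  state <- preserve_rng()
  on.exit(restore_rng(state))
  set.seed(16180L)
  sims <- vapply(seq_len(B), function(i) d_stat(stats::rnorm(n)), numeric(1))
  list(statistic = D, p = (1 + sum(sims >= D)) / (B + 1))
}

#' Plain Kolmogorov-Smirnov test against the fitted normal
#'
#' Anticonservative when parameters are estimated from the same data; kept
#' for comparability with software that reports it.
#'
#' @param x Numeric sample.
#' @return A list with `statistic` and `p`.
#' @export
ks_normality_test <- function(x) {
  x <- x[is.finite(x)]
  res <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Levene's test of homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group centre (mean for the
#' classic test, median for the Brown-Forsythe variant).
#'
#' @param x Numeric response.
#' @param g Grouping factor (2+ levels).
#' @param center `"mean"` or `"median"`.
#' @return A list with `statistic` (F), `df1`, `df2`, `p`.
#' @export
levene_test <- function(x, g, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  ctr <- tapply(x, g, if (center == "mean") mean else stats::median)
  dev <- abs(x - ctr[g])
  fit <- stats::oneway.test(dev ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = fit$p.value)
}

# save/restore the global RNG state around internal deterministic streams
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# -- characteristic comparison ----------------------------------------------

#' Compare a participant characteristic between the two groups of an axis
#'
#' Runs the normality check on the variable, Levene's homogeneity test
#' across the two groups, then a one-way ANOVA when normality holds at
#' `alpha` or a Kruskal-Wallis test (the "non-parametric ANOVA") otherwise.
#' Cohen's d is reported with the second-listed category minus first-listed
#' sign convention.
#'
#' @param profiles A participant data frame (one row per participant) with
#'   the axis factor column and the numeric variable.
#' @param axis One of `"axis_ei"`, `"axis_sn"`, `"axis_tf"`, `"axis_jp"`.
#' @param variable Name of the numeric column to compare.
#' @param cfg A [stats_config()].
#' @return A list with group summaries (`groups`), `normality_p`,
#'   `homogeneity_p`, `omnibus_p`, `test` used, and `d` with `d_class`.
#' @export
characteristic_comparison <- function(profiles, axis, variable,
                                      cfg = stats_config()) {
  axis <- match.arg(axis, AXIS_COLUMNS)
  g <- droplevels(as.factor(profiles[[axis]]))
  x <- profiles[[variable]]
  if (nlevels(g) != 2 || any(table(g) < 2))
    stop("insufficient data: axis must have two groups with n >= 2",
         call. = FALSE)
  norm <- if (cfg$normality == "lilliefors") lilliefors_test(x)
          else ks_normality_test(x)
  lev <- levene_test(x, g, cfg$levene_center)
  normal_ok <- norm$p > cfg$alpha
  if (normal_ok) {
    fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
    omnibus_p <- fit$p.value
    test <- "anova"
    omnibus_stat <- unname(fit$statistic)
  } else {
    fit <- stats::kruskal.test(x, g)
    omnibus_p <- fit$p.value
    test <- "kruskal-wallis"
    omnibus_stat <- unname(fit$statistic)
  }
  x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
  d <- cohens_d(mean(x1), stats::sd(x1), length(x1),
                mean(x2), stats::sd(x2), length(x2))
  groups <- data.frame(group = levels(g), n = as.vector(table(g)),
                       mean = c(mean(x1), mean(x2)),
                       sd = c(stats::sd(x1), stats::sd(x2)))
  list(axis = axis, variable = variable, groups = groups,
       normality_p = norm$p, homogeneity_p = lev$p,
       omnibus_stat = omnibus_stat, omnibus_p = omnibus_p, test = test,
       d = d, d_class = classify_d(d, cfg$d_thresholds))
}

# -- mixed repeated-measures ANOVA ------------------------------------------

# orthonormal within-subject contrasts (p x (p-1))
orthonormal_contrasts <- function(p) {
  C <- stats::contr.helmert(p)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# wide participant x speed matrix for one variable; complete cases only
cohort_wide <- function(cohort, axis, variable) {
  keep <- cohort$complete
  cc <- cohort[keep, , drop = FALSE]
  speeds <- sort(unique(cc$speed))
  ids <- unique(cc$participant_id)
  Y <- matrix(NA_real_, length(ids), length(speeds),
              dimnames = list(ids, speeds))
  Y[cbind(match(cc$participant_id, ids), match(cc$speed, speeds))] <-
    cc[[variable]]
  if (anyNA(Y))
    stop("insufficient data: unbalanced within-subject records after ",
         "complete-case filtering", call. = FALSE)
  g <- droplevels(as.factor(
    cc[[axis]][match(ids, cc$participant_id)]))
  list(Y = Y, g = g, speeds = speeds)
}

#' Mixed (between x within) repeated-measures ANOVA
#'
#' Two-group between-subjects factor (an axis) crossed with the
#' within-subjects speed factor. The between effect is the classic
#' split-plot test on subject means; within effects (speed main effect and
#' interaction) are computed from orthonormalised within-subject contrasts
#' with sum-to-zero group coding, i.e. Type III sums of squares for the
#' unbalanced between factor. Mauchly's test is run on the pooled
#' within-group covariance of the contrast scores; when it rejects at
#' `alpha`, Greenhouse-Geisser corrected degrees of freedom are used for
#' the within-effect p-values.
#'
#' @param cohort A `cohort_table` from [build_cohort_table()].
#' @param axis Between-subjects axis column name.
#' @param variable Derived-variable column to analyse.
#' @param cfg A [stats_config()].
#' @return An object of class `mixed_anova`: a list with an `effects` data
#'   frame (`effect, df1, df2, F, p`, corrected dfs where applicable),
#'   `epsilon` (Greenhouse-Geisser), `mauchly_W`, `mauchly_p`,
#'   `sphericity_corrected`, and the group sizes.
#' @export
mixed_anova <- function(cohort, axis, variable, cfg = stats_config()) {
  axis <- match.arg(axis, AXIS_COLUMNS)
  w <- cohort_wide(cohort, axis, variable)
  Y <- w$Y; g <- w$g
  if (nlevels(g) != 2 || any(table(g) < 2))
    stop("insufficient data: axis must have two groups with n >= 2",
         call. = FALSE)
  N <- nrow(Y); p <- ncol(Y); d <- p - 1L

  # between-subjects part: one-way ANOVA on subject means, scaled by p
  m_subj <- rowMeans(Y)
  grand <- mean(m_subj)
  gmeans <- tapply(m_subj, g, mean)
  nj <- table(g)
  ss_group <- p * sum(nj * (gmeans - grand)^2)
  ss_subj <- p * sum((m_subj - gmeans[g])^2)
  df_group <- 1L; df_subj <- N - 2L
  F_group <- (ss_group / df_group) / (ss_subj / df_subj)
  p_group <- stats::pf(F_group, df_group, df_subj, lower.tail = FALSE)

  # within-subjects part via orthonormal contrasts, sum-to-zero group coding
  C <- orthonormal_contrasts(p)
  Z <- Y %*% C
  xg <- ifelse(g == levels(g)[1], 1, -1)
  X <- cbind(intercept = 1, group = xg)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z - X %*% B)                 # residual SSP, df = N - 2
  hyp_ss <- function(j) {                     # Type III SS for row j of B
    L <- matrix(0, 1, 2); L[1, j] <- 1
    H <- t(L %*% B) %*% solve(L %*% XtXi %*% t(L)) %*% (L %*% B)
    sum(diag(H))
  }
  ss_speed <- hyp_ss(1)
  ss_inter <- hyp_ss(2)
  ss_err <- sum(diag(E))
  df_w1 <- d; df_w2 <- d * (N - 2L)
  F_speed <- (ss_speed / df_w1) / (ss_err / df_w2)
  F_inter <- (ss_inter / df_w1) / (ss_err / df_w2)

  # sphericity on the pooled within-group covariance of contrast scores
  S <- E / (N - 2L)
  if (d > 1L) {
    eps <- sum(diag(S))^2 / (d * sum(S * S))  # Greenhouse-Geisser
    W <- det(S) / (sum(diag(S)) / d)^d
    ne <- N - 2L
    chi <- -(ne - (2 * d^2 + d + 2) / (6 * d)) * log(W)
    df_m <- d * (d + 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi, df_m, lower.tail = FALSE)
  } else {
    eps <- 1; W <- 1; mauchly_p <- NA_real_
  }
  corrected <- is.finite(mauchly_p) && mauchly_p <= cfg$alpha
  ce <- if (corrected) eps else 1
  p_speed <- stats::pf(F_speed, df_w1 * ce, df_w2 * ce, lower.tail = FALSE)
  p_inter <- stats::pf(F_inter, df_w1 * ce, df_w2 * ce, lower.tail = FALSE)

  effects <- data.frame(
    effect = c("group", "speed", "group:speed"),
    ss = c(ss_group, ss_speed, ss_inter),
    df1 = c(df_group, df_w1 * ce, df_w1 * ce),
    df2 = c(df_subj, df_w2 * ce, df_w2 * ce),
    F = c(F_group, F_speed, F_inter),
    p = c(p_group, p_speed, p_inter)
  )
  structure(list(axis = axis, variable = variable, effects = effects,
                 epsilon = eps, mauchly_W = W, mauchly_p = mauchly_p,
                 sphericity_corrected = corrected,
                 n = as.vector(nj), groups = levels(g),
                 ss_error_within = ss_err, ss_subjects = ss_subj),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA: %s by %s x speed\n",
              x$variable, x$axis))
  cat(sprintf("  groups: %s (n = %s)\n",
              paste(x$groups, collapse = "/"),
              paste(x$n, collapse = "/")))
  cat(sprintf("  Greenhouse-Geisser epsilon = %.3f (Mauchly p = %s%s)\n",
              x$epsilon, format.pval(x$mauchly_p, digits = 3),
              if (x$sphericity_corrected) "; correction applied" else ""))
  print(transform(x$effects, F = round(F, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Per-speed post-hoc group contrasts with Holm adjustment
#'
#' For each speed, compares the two axis groups with a two-sample t test
#' (pooled variance unless `cfg$welch`), reporting the mean difference
#' (first-listed category minus second-listed, matching the reporting
#' convention for these contrasts), its confidence interval, Cohen's d with
#' the same orientation (computed from per-speed pooled SDs), and raw plus
#' Holm-adjusted p-values across the speeds.
#'
#' @inheritParams mixed_anova
#' @return A data frame with one row per speed: `speed, n1, n2, delta,
#'   ci_low, ci_high, d, d_class, p_raw, p_adjusted`.
#' @export
posthoc_pairwise <- function(cohort, axis, variable, cfg = stats_config()) {
  axis <- match.arg(axis, AXIS_COLUMNS)
  w <- cohort_wide(cohort, axis, variable)
  speeds <- w$speeds
  lv <- levels(w$g)
  rows <- lapply(seq_along(speeds), function(k) {
    x <- w$Y[w$g == lv[1], k]
    y <- w$Y[w$g == lv[2], k]
    ci <- mean_diff_ci(x, y, level = cfg$ci_level, welch = cfg$welch)
    d <- -cohens_d(mean(x), stats::sd(x), length(x),
                   mean(y), stats::sd(y), length(y))  # first minus second
    data.frame(speed = speeds[k], n1 = length(x), n2 = length(y),
               delta = ci$delta, ci_low = ci$ci_low, ci_high = ci$ci_high,
               d = d, d_class = classify_d(d, cfg$d_thresholds),
               p_raw = ci$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  attr(out, "contrast") <- paste(lv[1], "-", lv[2])
  out
}
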