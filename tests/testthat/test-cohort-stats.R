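# Effect sizes, Holm adjustment, intervals, assumption checks, and the
# mixed repeated-measures ANOVA against an independent oracle.

test_that("Cohen's d matches pooled-SD arithmetic and sign convention", {
  expect_equal(cohens_d(5, 1, 10, 5, 1, 10), 0)
  # second-listed minus first-listed: frozen reference value
  expect_equal(round(cohens_d(179, 7, 35, 174, 8, 45), 2), -0.66)
  # rounded-table inputs give the direct formula value, not the printed one
  expect_equal(cohens_d(72, 9, 35, 68, 9, 45), -4 / 9, tolerance = 1e-12)
  expect_error(cohens_d(1, 0, 10, 1, 0, 10), "zero pooled")
  expect_error(cohens_d(1, 1, 1, 2, 1, 10), "n1")
})

test_that("effect-size classification uses the 0.2/0.5/0.8 bounds", {
  expect_equal(classify_d(c(0.1, -0.3, 0.66, -1.02)),
               c("trivial", "small", "moderate", "large"))
  expect_equal(classify_d(c(0.2, 0.5, 0.8)),
               c("small", "moderate", "large"))
})

test_that("Holm adjustment: hand-stepped cases, oracle, and invariances", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  # equal raw p: all become min(m*p, 1)
  expect_equal(holm_adjust(rep(0.02, 3)), rep(0.06, 3))
  expect_equal(holm_adjust(rep(0.5, 3)), rep(1, 3))

  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"))   # independent reference
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])  # order-invariant
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mean difference CI matches hand computation and properties", {
  ci <- mean_diff_ci(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ci$delta, -1)
  # hand: sp = 1, se = sqrt(2/3), t(4, .975) = 2.776445
  expect_equal(ci$ci_low, -3.267, tolerance = 1e-3)
  expect_equal(ci$ci_high, 1.267, tolerance = 1e-3)

  # identical groups: delta 0, symmetric CI
  ci0 <- mean_diff_ci(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ci0$delta, 0)
  expect_equal(ci0$ci_low, -ci0$ci_high)

  # width shrinks like 1/sqrt(n)
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  w1 <- with(mean_diff_ci(x, y), ci_high - ci_low)
  w2 <- with(mean_diff_ci(rep(x, 4), rep(y, 4)), ci_high - ci_low)
  expect_equal(w1 / w2, 2, tolerance = 0.05)

  # agrees with the standard pooled t interval
  tt <- t.test(x, y, var.equal = TRUE)
  ci2 <- mean_diff_ci(x, y)
  expect_equal(unname(tt$conf.int), c(ci2$ci_low, ci2$ci_high),
               ignore_attr = TRUE)
  expect_equal(tt$p.value, ci2$p)
  expect_error(mean_diff_ci(1, c(1, 2)), "insufficient")
})

test_that("two-sample power helper matches power.t.test at equal n", {
  # independent reference for the balanced case
  ref <- power.t.test(n = 40, delta = 0.5, sd = 1, sig.level = 0.05)$power
  expect_equal(power_two_sample(0.5, 40, 40), ref, tolerance = 1e-4)
  expect_equal(power_two_sample(0, 30, 20), 0.05, tolerance = 1e-10)
  expect_gt(power_two_sample(0.8, 47, 33), power_two_sample(0.5, 47, 33))
})

test_that("normality and homogeneity checks behave sensibly", {
  set.seed(21)
  x_norm <- rnorm(120)
  x_exp <- rexp(200)
  expect_gt(lilliefors_test(x_norm)$p, 0.05)
  expect_lt(lilliefors_test(x_exp)$p, 0.01)
  # deterministic and RNG-state preserving
  s1 <- .Random.seed
  r1 <- lilliefors_test(x_norm)
  expect_identical(.Random.seed, s1)
  expect_identical(r1, lilliefors_test(x_norm))
  # plain KS variant runs and is less conservative
  expect_gt(ks_normality_test(x_norm)$p, lilliefors_test(x_norm)$p - 1e-9)

  g <- rep(c("a", "b"), each = 100)
  x_eq <- rnorm(200)
  x_ne <- c(rnorm(100, 0, 1), rnorm(100, 0, 3))
  expect_gt(levene_test(x_eq, g)$p, 0.05)
  expect_lt(levene_test(x_ne, g)$p, 1e-6)
})

test_that("characteristic comparison: F equals squared pooled t, gates on normality", {
  set.seed(14)
  profiles <- data.frame(
    axis_sn = factor(rep(c("S", "N"), c(20, 15)), levels = c("S", "N")),
    height = c(rnorm(20, 177, 8), rnorm(15, 176, 7))
  )
  cc <- characteristic_comparison(profiles, "axis_sn", "height")
  expect_equal(cc$test, "anova")
  tt <- t.test(height ~ axis_sn, profiles, var.equal = TRUE)
  expect_equal(cc$omnibus_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cc$omnibus_p, tt$p.value, tolerance = 1e-10)
  # d convention: second-listed minus first-listed
  m <- tapply(profiles$height, profiles$axis_sn, mean)
  expect_equal(sign(cc$d), sign(unname(m["N"] - m["S"])))

  # strongly non-normal data routed to Kruskal-Wallis
  profiles$skew <- rexp(35)^2
  cc2 <- characteristic_comparison(profiles, "axis_sn", "skew")
  expect_equal(cc2$test, "kruskal-wallis")
  expect_error(characteristic_comparison(
    data.frame(axis_sn = factor(c("S", "S", "N"), levels = c("S", "N")),
               height = c(1, 2, 3)), "axis_sn", "height"), "insufficient")
})

test_that("mixed ANOVA reproduces the independent sums-of-squares oracle", {
  for (shift in list(c(0, 0), c(0.02, 0), c(0.015, 0.008))) {
    tab <- toy_cohort(n_per_group = 4, group_shift = shift[1],
                      inter_shift = shift[2])
    ma <- mixed_anova(tab, "axis_sn", "y")
    oracle <- split_plot_oracle(tab)
    expect_equal(ma$effects$F[ma$effects$effect == "group"],
                 oracle$F_group, tolerance = 1e-10)
    expect_equal(ma$effects$F[ma$effects$effect == "speed"],
                 oracle$F_speed, tolerance = 1e-10)
    expect_equal(ma$effects$F[ma$effects$effect == "group:speed"],
                 oracle$F_inter, tolerance = 1e-10)
  }
})

test_that("mixed ANOVA agrees with stats::aov on balanced data", {
  tab <- toy_cohort(n_per_group = 5, group_shift = 0.01, seed = 3)
  ma <- mixed_anova(tab, "axis_sn", "y")
  fit <- summary(stats::aov(y ~ axis_sn * factor(speed) +
                              Error(participant_id / factor(speed)),
                            data = tab))
  f_between <- fit[[1]][[1]]["axis_sn", "F value"]
  f_within <- fit[[2]][[1]][c("factor(speed)", "axis_sn:factor(speed)"),
                            "F value"]
  expect_equal(ma$effects$F, unname(c(f_between, f_within)),
               tolerance = 1e-8)
})

test_that("shifted duplicate group: zero interaction, positive group effect", {
  tab <- toy_cohort(n_per_group = 4, seed = 7)
  # make group N an exact +0.05 copy of group S
  ys <- tab$y[tab$axis_sn == "S"]
  tab$y[tab$axis_sn == "N"] <- ys + 0.05
  ma <- mixed_anova(tab, "axis_sn", "y")
  expect_lt(ma$effects$F[3], 1e-20)
  expect_gt(ma$effects$F[1], 100)
})

test_that("two within-levels give epsilon = 1 (sphericity trivial)", {
  tab <- toy_cohort(n_per_group = 4)
  tab2 <- tab[tab$speed != 5.0, ]
  ma <- mixed_anova(tab2, "axis_sn", "y")
  expect_equal(ma$epsilon, 1)
  expect_true(is.na(ma$mauchly_p))
  expect_false(ma$sphericity_corrected)
})

test_that("Greenhouse-Geisser correction engages when sphericity fails", {
  set.seed(19)
  n <- 30
  # strongly heterogeneous difference variances violate sphericity
  tab <- toy_cohort(n_per_group = n, seed = 19)
  ids <- unique(tab$participant_id)
  bump <- rnorm(length(ids), 0, 0.15)
  tab$y[tab$speed == 5.0] <- tab$y[tab$speed == 5.0] +
    bump[match(tab$participant_id[tab$speed == 5.0], ids)]
  ma <- mixed_anova(tab, "axis_sn", "y")
  expect_lt(ma$mauchly_p, 0.05)
  expect_true(ma$sphericity_corrected)
  expect_lt(ma$epsilon, 1)
  expect_gt(ma$epsilon, 0.5)
  # corrected df actually shrink
  expect_lt(ma$effects$df1[2], 2)
})

test_that("post-hoc pairwise: per-speed contrasts with Holm family", {
  tab <- toy_cohort(n_per_group = 8, group_shift = 0.015, seed = 23)
  ph <- posthoc_pairwise(tab, "axis_sn", "y")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adjusted, holm_adjust(ph$p_raw))
  expect_true(all(ph$p_adjusted >= ph$p_raw))
  # delta and d share the first-minus-second orientation
  expect_true(all(sign(ph$delta) == sign(ph$d)))
  # per-speed delta equals the plain group mean difference
  for (k in seq_len(3)) {
    sp <- sort(unique(tab$speed))[k]
    sub <- tab[tab$speed == sp, ]
    m <- tapply(sub$y, sub$axis_sn, mean)
    expect_equal(ph$delta[k], unname(m["S"] - m["N"]))
  }
})
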