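# Shared fixtures and independent oracles, built in code at test time.

# random valid model inputs for property tests; respects the model domain
random_model_inputs <- function(n, seed = 42) {
  set.seed(seed)
  out <- data.frame(t_c = numeric(0), t_f = numeric(0), mass = numeric(0),
                    leg_len = numeric(0), speed = numeric(0))
  while (nrow(out) < n) {
    cand <- data.frame(
      t_c = runif(n, 0.16, 0.34),
      t_f = runif(n, 0.0, 0.18),
      mass = runif(n, 50, 95),
      leg_len = runif(n, 0.82, 1.05),
      speed = runif(n, 3.0, 5.5)
    )
    ok <- cand$speed * cand$t_c / 2 < cand$leg_len * 0.98
    out <- rbind(out, cand[ok, ])
  }
  out[seq_len(n), ]
}

# small balanced toy cohort for ANOVA oracle comparisons: n subjects per
# group, 3 speeds, known structure plus deterministic noise
toy_cohort <- function(n_per_group = 4, group_shift = 0, inter_shift = 0,
                       seed = 11) {
  set.seed(seed)
  speeds <- c(3.3, 4.2, 5.0)
  n <- 2 * n_per_group
  ids <- sprintf("T%02d", seq_len(n))
  grp <- rep(c("S", "N"), each = n_per_group)
  rows <- expand.grid(participant_id = ids, speed = speeds,
                      stringsAsFactors = FALSE)
  rows$axis_sn <- factor(grp[match(rows$participant_id, ids)],
                         levels = c("S", "N"))
  base <- 0.30 - 0.02 * match(rows$speed, speeds)
  rows$y <- base +
    ifelse(rows$axis_sn == "S", group_shift, 0) +
    ifelse(rows$axis_sn == "S", inter_shift * (match(rows$speed, speeds) - 2),
           0) +
    rnorm(nrow(rows), 0, 0.01)
  rows$complete <- TRUE
  rows
}

# independent split-plot sums-of-squares oracle (balanced designs only);
# textbook cell-mean formulas, coded separately from the implementation
split_plot_oracle <- function(cohort, variable = "y") {
  y <- cohort[[variable]]
  subj <- cohort$participant_id
  grp <- cohort$axis_sn
  spd <- factor(cohort$speed)
  p <- nlevels(spd)
  N <- length(unique(subj))
  gm <- mean(y)
  subj_means <- tapply(y, subj, mean)
  subj_grp <- tapply(as.character(grp), subj, function(g) g[1])
  grp_means <- tapply(y, grp, mean)
  spd_means <- tapply(y, spd, mean)
  cell_means <- tapply(y, list(grp, spd), mean)

  nj <- table(factor(subj_grp, levels = levels(grp)))
  ss_group <- p * sum(nj * (tapply(subj_means, subj_grp, mean)[levels(grp)] -
                              gm)^2)
  ss_subj <- p * sum((subj_means - grp_means[subj_grp])^2)
  ss_speed <- N * sum((spd_means - gm)^2)
  ss_inter <- sum(outer(as.vector(nj), rep(1, p)) *
                  (cell_means - outer(grp_means[levels(grp)], rep(1, p)) -
                   outer(rep(1, nlevels(grp)), spd_means) + gm)^2)
  fitted <- subj_means[subj] + cell_means[cbind(as.character(grp),
                                               as.character(spd))] -
    grp_means[as.character(grp)]
  ss_err <- sum((y - fitted)^2)

  df_subj <- N - 2
  df_w <- (p - 1) * (N - 2)
  list(
    F_group = (ss_group / 1) / (ss_subj / df_subj),
    F_speed = (ss_speed / (p - 1)) / (ss_err / df_w),
    F_inter = (ss_inter / (p - 1)) / (ss_err / df_w)
  )
}

# build participants/trials data frames for a tiny hand-made cohort
tiny_files <- function(dir) {
  participants <- data.frame(
    participant_id = c("A", "B"),
    sex = c("M", "F"), age_y = c(30, 28),
    height_cm = c(178, 170), mass_kg = c(70, 60), weekly_hours = c(6, 8),
    axis_ei = c("E", "I"), axis_sn = c("S", "N"),
    axis_tf = c("T", "F"), axis_jp = c("J", "P")
  )
  trials <- expand.grid(participant_id = c("A", "B"),
                        requested_speed_ms = c(3.3, 4.2, 5.0),
                        step_index = 1:3, stringsAsFactors = FALSE)
  trials <- trials[order(trials$participant_id, trials$requested_speed_ms), ]
  trials$measured_speed_ms <- trials$requested_speed_ms
  trials$tc_ms <- 250 - 20 * match(trials$requested_speed_ms, c(3.3, 4.2, 5.0)) +
    2 * trials$step_index
  trials$tf_ms <- 90 + 10 * match(trials$requested_speed_ms, c(3.3, 4.2, 5.0)) +
    trials$step_index
  pp <- file.path(dir, "participants.csv")
  tp <- file.path(dir, "trials.csv")
  write.csv(participants, pp, row.names = FALSE)
  write.csv(trials, tp, row.names = FALSE)
  list(participants = pp, trials = tp)
}
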