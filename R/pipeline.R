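# End-to-end orchestration: ingest -> derive -> analyze -> report, with a
# run manifest that makes every reported number traceable to its inputs.

BIOMECH_VARS <- c("tc", "tf", "duty_factor", "sf", "kleg", "fmax", "delta_l")
CHARACTERISTIC_VARS <- c("age", "height", "mass", "weekly_hours")

# reporting-unit view of a cohort table: ms, cm, kN/m; names unchanged
cohort_reporting_units <- function(cohort) {
  out <- cohort
  out$tc <- cohort$tc * 1000        # ms
  out$tf <- cohort$tf * 1000        # ms
  out$ts <- cohort$ts * 1000        # ms
  out$delta_z <- cohort$delta_z * 100  # cm
  out$delta_l <- cohort$delta_l * 100  # cm
  out$kleg <- cohort$kleg / 1000    # kN/m
  out
}

#' Run the full statistical analysis on ingested files
#'
#' Reads the participants and trials files, applies the trial-acceptance
#' rule, aggregates timings, derives the spring-mass variables, and runs
#' the characteristic comparisons, mixed ANOVAs and Holm-adjusted
#' post-hocs for every personality axis. Writes `cohort.csv`,
#' `results_characteristics.csv`, `results_anova.csv`,
#' `results_posthoc.csv` and `manifest.json` into `out_dir`. Post-hoc
#' deltas are in reporting units (ms, cm, kN/m, Hz, duty-factor fraction).
#'
#' @param participants_path,trials_path Input CSV paths
#'   ([read_participants()] / [read_trials()] schemas).
#' @param out_dir Output directory, created if needed.
#' @param stats_cfg A [stats_config()].
#' @param model_cfg A [model_config()].
#' @param seed Optional seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @return Invisibly, a list with the cohort table and the three result
#'   data frames.
#' @export
run_analysis <- function(participants_path, trials_path, out_dir,
                         stats_cfg = stats_config(),
                         model_cfg = model_config(), seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- read_participants(participants_path)
  trials <- read_trials(trials_path)
  timings <- aggregate_trials(trials)
  cohort <- build_cohort_table(profiles, timings, cfg = model_cfg)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  rep_cohort <- cohort_reporting_units(cohort)

  prof1 <- cohort[!duplicated(cohort$participant_id), ]
  prof1$height <- prof1$height * 100  # report cm
  chr <- do.call(rbind, lapply(AXIS_COLUMNS, function(ax) {
    do.call(rbind, lapply(CHARACTERISTIC_VARS, function(v) {
      cc <- characteristic_comparison(prof1, ax, v, stats_cfg)
      data.frame(axis = ax, variable = v,
                 group1 = cc$groups$group[1], n1 = cc$groups$n[1],
                 mean1 = cc$groups$mean[1], sd1 = cc$groups$sd[1],
                 group2 = cc$groups$group[2], n2 = cc$groups$n[2],
                 mean2 = cc$groups$mean[2], sd2 = cc$groups$sd[2],
                 d = cc$d, d_class = cc$d_class, test = cc$test,
                 normality_p = cc$normality_p,
                 homogeneity_p = cc$homogeneity_p,
                 omnibus_p = cc$omnibus_p, stringsAsFactors = FALSE)
    }))
  }))

  anova_res <- do.call(rbind, lapply(AXIS_COLUMNS, function(ax) {
    do.call(rbind, lapply(BIOMECH_VARS, function(v) {
      ma <- mixed_anova(rep_cohort, ax, v, stats_cfg)
      cbind(data.frame(axis = ax, variable = v), ma$effects,
            data.frame(epsilon = ma$epsilon, mauchly_p = ma$mauchly_p,
                       gg_corrected = ma$sphericity_corrected))
    }))
  }))

  posthoc_res <- do.call(rbind, lapply(AXIS_COLUMNS, function(ax) {
    do.call(rbind, lapply(BIOMECH_VARS, function(v) {
      ph <- posthoc_pairwise(rep_cohort, ax, v, stats_cfg)
      cbind(data.frame(axis = ax, variable = v,
                       contrast = attr(ph, "contrast")), ph)
    }))
  }))

  utils::write.csv(chr, file.path(out_dir, "results_characteristics.csv"),
                   row.names = FALSE)
  utils::write.csv(anova_res, file.path(out_dir, "results_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(posthoc_res, file.path(out_dir, "results_posthoc.csv"),
                   row.names = FALSE)

  manifest <- list(
    software = paste0("springgait ",
                      as.character(utils::packageVersion("springgait"))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    alpha = stats_cfg$alpha,
    inputs = list(
      participants = list(path = participants_path,
                          md5 = unname(tools::md5sum(participants_path))),
      trials = list(path = trials_path,
                    md5 = unname(tools::md5sum(trials_path)))
    ),
    counts = list(
      participants = nrow(profiles),
      trials_total = attr(timings, "n_trials"),
      trials_rejected = attr(timings, "n_rejected"),
      cohort_rows = nrow(cohort),
      complete_participants =
        length(unique(cohort$participant_id[cohort$complete]))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, characteristics = chr,
                 anova = anova_res, posthoc = posthoc_res,
                 manifest = manifest))
}

fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' Render a human-readable analysis report
#'
#' Formats the result files of [run_analysis()] as markdown tables using
#' the field's reporting conventions: timings in ms, duty factor as a
#' percentage with one decimal, leg stiffness in kN/m with one decimal,
#' mean differences as `delta [lo, hi]`.
#'
#' @param out_dir Directory containing the result CSVs.
#' @param alpha Significance threshold used to select post-hoc lines.
#' @return A character vector of report lines, invisibly; the report is
#'   also printed with `cat()`.
#' @export
render_report <- function(out_dir, alpha = 0.05) {
  need <- file.path(out_dir, c("results_characteristics.csv",
                               "results_anova.csv", "results_posthoc.csv"))
  if (!all(file.exists(need)))
    stop("missing result files in ", out_dir, call. = FALSE)
  chr <- utils::read.csv(need[1])
  av <- utils::read.csv(need[2])
  ph <- utils::read.csv(need[3])

  unit <- c(tc = "ms", tf = "ms", duty_factor = "%", sf = "Hz",
            kleg = "kN/m", fmax = "N", delta_l = "cm")
  fmt_var <- function(v, x) switch(v,
    duty_factor = sprintf("%.1f", 100 * x),
    tc = , tf = sprintf("%.0f", x),
    sf = sprintf("%.2f", x),
    kleg = , delta_l = sprintf("%.1f", x),
    fmax = sprintf("%.0f", x),
    sprintf("%.2f", x))

  lines <- c("# Cohort analysis report", "",
             "## Participant characteristics", "",
             "| Axis | Variable | Group 1 | Group 2 | d | p |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(chr))) {
    r <- chr[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s: %.1f ± %.1f (n=%d) | %s: %.1f ± %.1f (n=%d) | %.2f | %s |",
      r$axis, r$variable, r$group1, r$mean1, r$sd1, r$n1,
      r$group2, r$mean2, r$sd2, r$n2, r$d, fmt_p(r$omnibus_p)))
  }

  lines <- c(lines, "", "## Mixed ANOVA (axis x speed)", "",
             "| Axis | Variable | Effect | F | df | p |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(av))) {
    r <- av[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %.2f | (%.2f, %.2f) | %s |",
      r$axis, r$variable, r$effect, r$F, r$df1, r$df2, fmt_p(r$p)))
  }

  sig <- ph[ph$p_adjusted <= alpha, , drop = FALSE]
  lines <- c(lines, "", "## Significant post-hoc contrasts", "")
  if (nrow(sig) == 0) {
    lines <- c(lines, "(none at the chosen alpha)")
  } else {
    for (i in seq_len(nrow(sig))) {
      r <- sig[i, ]
      u <- unit[[r$variable]]
      lines <- c(lines, sprintf(
        "- %s, %s at %.1f m/s (%s): Δ = %s %s [%s %s, %s %s]; d = %.2f (%s); adj. p = %s",
        r$axis, r$variable, r$speed, r$contrast,
        fmt_var(r$variable, r$delta), u,
        fmt_var(r$variable, r$ci_low), u,
        fmt_var(r$variable, r$ci_high), u,
        r$d, r$d_class, fmt_p(r$p_adjusted)))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
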