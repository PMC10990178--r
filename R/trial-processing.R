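# Ingestion of raw trial/step records, the +/-5% trial-acceptance rule,
# aggregation to one (t_c, t_f) pair per participant x speed, and assembly
# of the long-format cohort table feeding the statistics.

AXIS_COLUMNS <- c("axis_ei", "axis_sn", "axis_tf", "axis_jp")
AXIS_LEVELS <- list(
  axis_ei = c("E", "I"),
  axis_sn = c("S", "N"),
  axis_tf = c("T", "F"),
  axis_jp = c("J", "P")
)

#' Trial speed acceptance rule
#'
#' A trial is accepted when the measured speed lies within +/-5% of the
#' requested speed (inclusive boundary).
#'
#' @param requested Requested protocol speed, m/s (vectorised).
#' @param measured Speed measured over the timed segment, m/s (vectorised).
#' @param tolerance Relative tolerance, default 0.05.
#' @return Logical vector: `TRUE` for accepted trials.
#' @export
#' @examples
#' validate_trial_speed(3.3, c(3.3, 3.47, 3.465))
validate_trial_speed <- function(requested, measured, tolerance = 0.05) {
  if (any(!is.finite(requested)) || any(requested <= 0) ||
      any(!is.finite(measured)) || any(measured <= 0))
    stop("speeds must be positive and finite", call. = FALSE)
  # inclusive boundary, robust to floating-point representation of the 5%
  abs(measured - requested) <= tolerance * requested * (1 + 1e-9)
}

#' Average step timings over a trial
#'
#' Aggregates the ordered step records of one accepted trial to a single
#' (t_c, t_f) pair by arithmetic mean, as measured over the timed 20-m
#' segment.
#'
#' @param t_c,t_f Numeric vectors of per-step contact and flight times,
#'   seconds, equal length and non-empty.
#' @return A list with scalar elements `t_c` and `t_f`.
#' @export
aggregate_trial <- function(t_c, t_f) {
  if (length(t_c) == 0L || length(t_f) != length(t_c))
    stop("step lists must be non-empty and of equal length", call. = FALSE)
  check_step_timing(t_c, t_f)
  list(t_c = mean(t_c), t_f = mean(t_f))
}

#' Read a participants file
#'
#' Expects columns `participant_id, sex, age_y, height_cm, mass_kg,
#' weekly_hours, axis_ei, axis_sn, axis_tf, axis_jp` with axis labels
#' `E/I`, `S/N`, `T/F`, `J/P`. Heights are converted to metres and a
#' derived `leg_len` column (0.53 x height) is added.
#'
#' @param path Path to a CSV file.
#' @return A data frame of participant profiles (SI units).
#' @export
read_participants <- function(path) {
  # read everything as character first: "T"/"F" axis labels must not be
  # type-converted to logicals
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("participant_id", "sex", "age_y", "height_cm", "mass_kg",
                "weekly_hours", AXIS_COLUMNS)
  for (v in c("age_y", "height_cm", "mass_kg", "weekly_hours"))
    if (!is.null(df[[v]])) df[[v]] <- as.numeric(df[[v]])
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("participants file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id in participants file", call. = FALSE)
  for (ax in AXIS_COLUMNS) {
    bad <- !df[[ax]] %in% AXIS_LEVELS[[ax]]
    if (any(bad))
      stop(sprintf("invalid %s label at row(s) %s (allowed: %s)", ax,
                   paste(which(bad), collapse = ","),
                   paste(AXIS_LEVELS[[ax]], collapse = "/")), call. = FALSE)
    df[[ax]] <- factor(df[[ax]], levels = AXIS_LEVELS[[ax]])
  }
  if (any(df$height_cm <= 0) || any(df$mass_kg <= 0))
    stop("non-positive height or mass in participants file", call. = FALSE)
  data.frame(
    participant_id = as.character(df$participant_id),
    sex = df$sex,
    age = df$age_y,
    height = df$height_cm / 100,
    mass = df$mass_kg,
    leg_len = leg_length(df$height_cm / 100),
    weekly_hours = df$weekly_hours,
    df[AXIS_COLUMNS],
    stringsAsFactors = FALSE
  )
}

#' Read a trials file
#'
#' Expects columns `participant_id, requested_speed_ms, measured_speed_ms,
#' step_index, tc_ms, tf_ms`. An optional `granularity` column
#' (`"step"` or `"aggregated"`) marks whether rows are individual steps or
#' pre-averaged trial values; absent, `"step"` is assumed.
#'
#' @param path Path to a CSV file.
#' @return A data frame of step records with timings converted to seconds
#'   (`tc`, `tf`).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "requested_speed_ms", "measured_speed_ms",
                "step_index", "tc_ms", "tf_ms")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trials file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(df$granularity)) df$granularity <- "step"
  bad <- !df$granularity %in% c("step", "aggregated")
  if (any(bad))
    stop("invalid granularity at row(s) ", paste(which(bad), collapse = ","),
         call. = FALSE)
  data.frame(
    participant_id = as.character(df$participant_id),
    requested_speed = df$requested_speed_ms,
    measured_speed = df$measured_speed_ms,
    step_index = df$step_index,
    tc = df$tc_ms / 1000,
    tf = df$tf_ms / 1000,
    granularity = df$granularity,
    stringsAsFactors = FALSE
  )
}

#' Filter and aggregate trials to per-participant, per-speed timings
#'
#' Applies [validate_trial_speed()] to each participant x requested-speed
#' trial and averages the steps of accepted trials. Pre-aggregated rows
#' (granularity `"aggregated"`) pass through unchanged.
#'
#' @param trials A data frame from [read_trials()].
#' @param tolerance Relative speed tolerance, default 0.05.
#' @return A data frame with one row per accepted participant x speed
#'   (`participant_id, speed, tc, tf`), with attributes `n_trials` and
#'   `n_rejected` recording the acceptance bookkeeping.
#' @export
aggregate_trials <- function(trials, tolerance = 0.05) {
  if (!is.null(trials$granularity) &&
      all(trials$granularity == "aggregated")) {
    # fast path: rows are already one-per-trial
    if (anyDuplicated(paste(trials$participant_id, trials$requested_speed)))
      stop("aggregated trials must have exactly one row per ",
           "participant x speed", call. = FALSE)
    ok <- validate_trial_speed(trials$requested_speed,
                               trials$measured_speed, tolerance)
    res <- data.frame(participant_id = trials$participant_id[ok],
                      speed = trials$requested_speed[ok],
                      tc = trials$tc[ok], tf = trials$tf[ok],
                      stringsAsFactors = FALSE)
    attr(res, "n_trials") <- nrow(trials)
    attr(res, "n_rejected") <- sum(!ok)
    return(res)
  }
  key <- interaction(trials$participant_id, trials$requested_speed,
                     drop = TRUE)
  pieces <- split(trials, key)
  out <- lapply(pieces, function(tr) {
    if (length(unique(tr$measured_speed)) > 1L)
      stop("inconsistent measured_speed within a trial for participant ",
           tr$participant_id[1], call. = FALSE)
    ok <- validate_trial_speed(tr$requested_speed[1], tr$measured_speed[1],
                               tolerance)
    if (!ok) return(NULL)
    agg <- if (all(tr$granularity == "aggregated")) {
      if (nrow(tr) != 1L)
        stop("aggregated trials must have exactly one row (participant ",
             tr$participant_id[1], ")", call. = FALSE)
      list(t_c = tr$tc, t_f = tr$tf)
    } else {
      aggregate_trial(tr$tc, tr$tf)
    }
    data.frame(participant_id = tr$participant_id[1],
               speed = tr$requested_speed[1],
               tc = agg$t_c, tf = agg$t_f, stringsAsFactors = FALSE)
  })
  keep <- !vapply(out, is.null, logical(1))
  res <- do.call(rbind, out[keep])
  if (is.null(res))
    res <- data.frame(participant_id = character(), speed = numeric(),
                      tc = numeric(), tf = numeric())
  rownames(res) <- NULL
  attr(res, "n_trials") <- length(pieces)
  attr(res, "n_rejected") <- sum(!keep)
  res
}

#' Build the long-format cohort table
#'
#' Joins participant profiles to aggregated per-speed timings and evaluates
#' the full spring-mass bundle on every row. Participants missing any of
#' the protocol speeds are flagged (`complete = FALSE`) and excluded from
#' repeated-measures analysis downstream, but retained for descriptives.
#'
#' @param profiles Data frame from [read_participants()].
#' @param timings Data frame from [aggregate_trials()] (or equivalent, with
#'   `participant_id, speed, tc, tf` in SI units).
#' @param cfg A [model_config()].
#' @param speeds Protocol speeds defining completeness; default: all speeds
#'   present in `timings`.
#' @return A data frame of class `cohort_table`: one row per
#'   participant x speed with profile columns, timings and the seven
#'   derived variables.
#' @export
build_cohort_table <- function(profiles, timings, cfg = model_config(),
                               speeds = sort(unique(timings$speed))) {
  if (anyDuplicated(paste(timings$participant_id, timings$speed)))
    stop("data-integrity error: duplicate participant x speed in timings",
         call. = FALSE)
  unknown <- setdiff(timings$participant_id, profiles$participant_id)
  if (length(unknown))
    stop("data-integrity error: unknown participant_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  idx <- match(timings$participant_id, profiles$participant_id)
  tab <- cbind(profiles[idx, , drop = FALSE],
               timings[c("speed", "tc", "tf")])
  derived <- spring_mass(tab$tc, tab$tf, mass = tab$mass, speed = tab$speed,
                         leg_len = tab$leg_len, cfg = cfg)
  tab <- cbind(tab, derived)

  n_speeds <- tapply(tab$speed, tab$participant_id,
                     function(s) sum(speeds %in% s))
  tab$complete <- n_speeds[tab$participant_id] == length(speeds)
  tab <- tab[order(tab$participant_id, tab$speed), ]
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a cohort table in reporting units
#'
#' Emits the long-format cohort CSV with the field's reporting conventions:
#' milliseconds for timings, Hz for step frequency, dimensionless duty
#' factor, newtons for peak force, centimetres for displacements, kN/m for
#' leg stiffness.
#'
#' @param cohort A `cohort_table` from [build_cohort_table()].
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    participant_id = cohort$participant_id,
    speed_ms = cohort$speed,
    tc_ms = cohort$tc * 1000,
    tf_ms = cohort$tf * 1000,
    sf_hz = cohort$sf,
    ts_ms = cohort$ts * 1000,
    df_frac = cohort$duty_factor,
    fmax_n = cohort$fmax,
    dz_cm = cohort$delta_z * 100,
    dl_cm = cohort$delta_l * 100,
    kleg_knm = cohort$kleg / 1000
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
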