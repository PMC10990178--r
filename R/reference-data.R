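# Built-in reference group summaries for a cohort of 80 recreational
# runners (two groups on the sensing-intuition axis, n = 47 / 33, measured
# at 3.3, 4.2 and 5.0 m/s). These printed summary statistics are the
# calibration inputs of the synthetic-cohort generator and the package's
# desk-check targets; they are not re-estimated at run time.

#' Reference cohort summary statistics
#'
#' Returns the published group-level summaries the simulator is calibrated
#' against: per-axis participant characteristics (mean +/- SD of age,
#' height, body mass and weekly running hours for both categories of each
#' of the four personality axes) and per-group, per-speed spring-mass
#' summaries (step frequency, leg stiffness, peak vertical ground reaction
#' force, leg compression) for the sensing/intuition split.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{characteristics}{data frame: `axis, group, n, age_mean, age_sd,
#'       height_cm_mean, height_cm_sd, mass_kg_mean, mass_kg_sd,
#'       hours_mean, hours_sd`.}
#'     \item{spring_mass}{data frame: `group, speed, sf_mean, sf_sd,
#'       kleg_knm_mean, kleg_knm_sd, fmax_n_mean, fmax_n_sd, dl_cm_mean,
#'       dl_cm_sd`.}
#'     \item{sex}{named counts of males and females.}
#'     \item{n_total}{total cohort size (80).}
#'   }
#' @export
reference_cohort_summary <- function() {
  characteristics <- data.frame(
    axis  = rep(c("axis_ei", "axis_sn", "axis_tf", "axis_jp"), each = 2),
    group = c("E", "I", "S", "N", "T", "F", "J", "P"),
    n     = c(37, 43, 47, 33, 35, 45, 41, 39),
    age_mean  = c(30, 29, 30, 28, 29, 29, 29, 30),
    age_sd    = c(12, 10, 12, 10, 11, 11, 12, 10),
    height_cm_mean = c(176, 177, 177, 176, 179, 174, 177, 175),
    height_cm_sd   = c(8, 7, 8, 7, 7, 8, 8, 8),
    mass_kg_mean   = c(70, 71, 70, 70, 72, 68, 70, 70),
    mass_kg_sd     = c(9, 10, 10, 9, 9, 9, 10, 9),
    hours_mean = c(6, 8, 6, 7, 7, 6, 7, 6),
    hours_sd   = c(4, 5, 5, 5, 6, 4, 5, 5),
    stringsAsFactors = FALSE
  )
  spring_mass <- data.frame(
    group = rep(c("S", "N"), each = 3),
    speed = rep(c(3.3, 4.2, 5.0), 2),
    sf_mean = c(2.7, 2.8, 3.0, 2.7, 2.8, 2.9),
    sf_sd   = c(0.1, 0.2, 0.2, 0.1, 0.1, 0.1),
    kleg_knm_mean = c(8.1, 8.1, 8.3, 9.3, 9.0, 9.4),
    kleg_knm_sd   = c(1.7, 1.6, 1.6, 1.4, 1.4, 1.9),
    fmax_n_mean = c(1454, 1612, 1752, 1554, 1699, 1860),
    fmax_n_sd   = c(226, 231, 249, 192, 213, 241),
    dl_cm_mean = c(18, 20, 22, 17, 19, 20),
    dl_cm_sd   = c(2, 2, 3, 1, 2, 2),
    stringsAsFactors = FALSE
  )
  list(characteristics = characteristics, spring_mass = spring_mass,
       sex = c(male = 67, female = 13), n_total = 80)
}
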