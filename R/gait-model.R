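# Closed-form derivation of temporal and spring-mass gait variables from
# step timing, plus the numerical inverse used for simulator calibration.
# All quantities are strict SI internally (s, m, kg, N, N/m); millisecond /
# centimetre / kN conversions happen only at I/O boundaries.

#' Model configuration
#'
#' Physical constants of the spring-mass model. The only tunable is the
#' gravitational acceleration `g`, defaulting to the sport-science
#' convention of 9.81 m/s^2.
#'
#' @param g Gravitational acceleration in m/s^2. Must be positive.
#' @return An object of class `model_config`.
#' @export
#' @examples
#' model_config()
model_config <- function(g = 9.81) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("`g` must be a single positive number", call. = FALSE)
  structure(list(g = g), class = "model_config")
}

#' Estimate leg length from body height
#'
#' Leg length is estimated as 0.53 of standing body height, the standard
#' anthropometric scaling used with the sine-wave spring-mass model. A
#' directly measured leg length can be supplied downstream instead.
#'
#' @param height Body height in metres (vectorised).
#' @return Leg length in metres.
#' @export
#' @examples
#' leg_length(1.78)
leg_length <- function(height) {
  if (!is.numeric(height) || any(!is.finite(height)) || any(height <= 0))
    stop("`height` must be positive and finite", call. = FALSE)
  0.53 * height
}

# shared validation of a (t_c, t_f) pair; vectorised, recycling checked upstream
check_step_timing <- function(t_c, t_f) {
  if (!is.numeric(t_c) || !is.numeric(t_f))
    stop("step timings must be numeric", call. = FALSE)
  if (any(!is.finite(t_c)) || any(!is.finite(t_f)))
    stop("step timings must be finite", call. = FALSE)
  if (any(t_c <= 0))
    stop("contact time `t_c` must be > 0", call. = FALSE)
  if (any(t_f < 0))
    stop("flight time `t_f` must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Temporal gait variables from contact and flight time
#'
#' Computes step frequency `SF = 1 / (t_c + t_f)`, swing time
#' `t_s = 2 t_f + t_c` (one foot off the ground within a stride: two
#' consecutive flight phases plus the contralateral contact), and duty
#' factor `DF = t_c / (t_c + t_s)`, the fraction of the stride spent on the
#' ground. `DF = 0.5` marks the walking boundary (`t_f = 0`); running has
#' `DF < 0.5`.
#'
#' @param t_c Ground contact time in seconds (vectorised).
#' @param t_f Flight time in seconds (vectorised).
#' @return A data frame with columns `sf` (Hz), `ts` (s), `duty_factor`
#'   (dimensionless fraction in (0, 0.5]).
#' @export
#' @examples
#' temporal_vars(0.25, 0.12)
temporal_vars <- function(t_c, t_f) {
  check_step_timing(t_c, t_f)
  ts <- 2 * t_f + t_c
  data.frame(
    sf = 1 / (t_c + t_f),
    ts = ts,
    duty_factor = t_c / (t_c + ts)
  )
}

#' Spring-mass variables from step timing (sine-wave model)
#'
#' Models the stance-phase vertical ground reaction force as a half sine
#' wave, from which peak force, centre-of-mass displacement, leg compression
#' and leg stiffness follow in closed form:
#' \deqn{F_{max} = m g \frac{\pi}{2}\left(\frac{t_f}{t_c} + 1\right)}
#' \deqn{\Delta z = \frac{F_{max} t_c^2}{m \pi^2} - \frac{g t_c^2}{8}}
#' \deqn{\Delta L = L - \sqrt{L^2 - (s t_c / 2)^2} + \Delta z}
#' \deqn{k_{leg} = F_{max} / \Delta L}
#' where `L` is leg length and `s` the running speed. The geometric term
#' requires `s * t_c / 2 < L` (the hip cannot sweep farther than the leg is
#' long); violations raise a model-domain error.
#'
#' @param t_c,t_f Contact and flight times in seconds (vectorised).
#' @param mass Body mass in kg.
#' @param speed Running speed in m/s.
#' @param height Body height in metres; used to estimate leg length when
#'   `leg_len` is not given.
#' @param leg_len Leg length in metres; overrides the height-based estimate.
#' @param cfg A [model_config()].
#' @return A data frame with the temporal variables (`sf`, `ts`,
#'   `duty_factor`) plus `fmax` (N), `delta_z` (m), `delta_l` (m), and
#'   `kleg` (N/m). `kleg * delta_l` equals `fmax` to machine precision by
#'   construction.
#' @export
#' @examples
#' spring_mass(0.25, 0.12, mass = 70, speed = 3.3, height = 1.78)
spring_mass <- function(t_c, t_f, mass, speed, height = NULL, leg_len = NULL,
                        cfg = model_config()) {
  check_step_timing(t_c, t_f)
  if (is.null(leg_len)) {
    if (is.null(height))
      stop("supply either `height` or `leg_len`", call. = FALSE)
    leg_len <- leg_length(height)
  }
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("`mass` must be positive", call. = FALSE)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("`speed` must be positive", call. = FALSE)
  stopifnot(inherits(cfg, "model_config"))
  g <- cfg$g

  n <- max(length(t_c), length(t_f), length(mass), length(speed),
           length(leg_len))
  t_c <- rep_len(t_c, n); t_f <- rep_len(t_f, n)
  mass <- rep_len(mass, n); speed <- rep_len(speed, n)
  leg_len <- rep_len(leg_len, n)

  half_sweep <- speed * t_c / 2
  if (any(half_sweep >= leg_len))
    stop("model-domain error: leg compression undefined for this ",
         "timing/speed/leg-length combination (s*t_c/2 >= L)", call. = FALSE)

  tv <- temporal_vars(t_c, t_f)
  fmax <- mass * g * (pi / 2) * (t_f / t_c + 1)
  delta_z <- fmax * t_c^2 / (mass * pi^2) - g * t_c^2 / 8
  delta_l <- leg_len - sqrt(leg_len^2 - half_sweep^2) + delta_z
  if (any(delta_l <= 0))
    stop("model-domain error: non-positive leg compression", call. = FALSE)

  cbind(tv, data.frame(fmax = fmax, delta_z = delta_z, delta_l = delta_l,
                       kleg = fmax / delta_l))
}

#' Invert the spring-mass model for step timings
#'
#' Finds the `(t_c, t_f)` pair whose forward [spring_mass()] evaluation
#' reproduces target values of peak force and leg compression, used to
#' calibrate the synthetic-cohort generator against published group means.
#' The flight-to-contact ratio follows in closed form from the peak-force
#' equation, `t_f / t_c = Fmax / (m g pi / 2) - 1`; `t_c` is then obtained
#' by bisection on the leg-compression equation, which is strictly
#' increasing in `t_c` on the admissible interval `(0, 2 L / s)`.
#'
#' @param fmax_target Target peak vertical ground reaction force, N. Must be
#'   at least `m * g * pi / 2` (the `t_f = 0` floor).
#' @param dl_target Target maximal leg compression, m. Must be positive.
#' @param mass Body mass, kg.
#' @param speed Running speed, m/s.
#' @param leg_len Leg length, m.
#' @param cfg A [model_config()].
#' @param tol Absolute tolerance on the leg-compression residual, m.
#' @return A list with elements `t_c` and `t_f` (seconds).
#' @export
#' @examples
#' invert_timings(1454, 0.18, mass = 70, speed = 3.3, leg_len = 0.9434)
invert_timings <- function(fmax_target, dl_target, mass, speed, leg_len,
                           cfg = model_config(), tol = 1e-10) {
  stopifnot(inherits(cfg, "model_config"))
  if (!all(is.finite(c(fmax_target, dl_target, mass, speed, leg_len))) ||
      mass <= 0 || speed <= 0 || leg_len <= 0)
    stop("all inputs must be finite; mass, speed, leg_len positive",
         call. = FALSE)
  if (dl_target <= 0)
    stop("`dl_target` must be positive", call. = FALSE)
  g <- cfg$g
  floor_fmax <- mass * g * pi / 2
  if (fmax_target < floor_fmax)
    stop("`fmax_target` below the t_f = 0 floor (m*g*pi/2 = ",
         format(floor_fmax), " N)", call. = FALSE)
  ratio <- fmax_target / floor_fmax - 1  # t_f / t_c

  dl_of_tc <- function(tc) {
    dz <- fmax_target * tc^2 / (mass * pi^2) - g * tc^2 / 8
    leg_len - sqrt(leg_len^2 - (speed * tc / 2)^2) + dz
  }

  eps <- 1e-9
  lo <- eps
  hi <- 2 * leg_len / speed - eps
  if (dl_of_tc(hi) < dl_target || dl_of_tc(lo) > dl_target)
    stop("calibration-infeasible: no contact time in (0, 2L/s) reaches ",
         "the requested leg compression", call. = FALSE)
  # bisection: guaranteed convergence on the monotone branch
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (dl_of_tc(mid) < dl_target) lo <- mid else hi <- mid
    if (abs(dl_of_tc(mid) - dl_target) <= tol) break
  }
  t_c <- (lo + hi) / 2
  list(t_c = t_c, t_f = ratio * t_c)
}
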