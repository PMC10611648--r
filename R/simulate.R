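# Synthetic detection trials with the statistical structure the two-stage
# analysis assumes: a true distance detection function times stage-2
# covariate effects on the logit scale, Bernoulli outcomes.

#' Default stage-2 coefficients for simulated experiments
#'
#' Moderate fixture effects on the log-odds scale (not estimates from any
#' field study): body-size and camera penalties relative to the
#' large-ungulate/HP2X baseline, a positive loading on the stage-1
#' detection probability, and a speed penalty.
#'
#' @return Named numeric vector keyed by design-matrix column names.
#' @export
default_sim_coefficients <- function() {
  c("(Intercept)" = -0.5,
    "body_sizelarge" = -0.4,
    "body_sizemedium" = -1.6,
    "camera_modelPC900" = -0.8,
    "dist_model" = 4,
    "speed_mps" = -1)
}

#' Simulation configuration
#'
#' Bundles everything needed to generate a reproducible synthetic trial
#' dataset: a factorial design, the true stage-1 detection function, true
#' stage-2 log-odds coefficients, the trial-speed distribution (normal
#' truncated at zero), and a sun-covariate model.
#'
#' @param design A `trial_design` from [generate_design()].
#' @param detfun True stage-1 `detfun_spec`; the default is a half-normal
#'   logistic mixture (scale 6 m, midpoint 1.5 m, steepness 3 per m) — the
#'   family such experiments typically select.
#' @param coefficients Named true log-odds effects; names must match
#'   design-matrix columns implied by `terms`. `NULL` drops the covariate
#'   layer entirely: outcomes are drawn as Bernoulli(p(y)) from the
#'   detection function alone (a pure stage-1 calibration experiment).
#' @param terms Stage-2 model terms used to build covariate effects.
#' @param speed_mean,speed_sd Trial speed distribution (m/s), truncated at 0.
#' @param sun Either `"uniform"` (altitude uniform on 0.05-1.2 rad, azimuth
#'   uniform on 0-2pi) or a list with fixed `altitude` and `azimuth`.
#' @param seed Integer RNG seed; fixed seed gives byte-identical trials.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(design = generate_design(),
                              detfun = detfun_spec("half_normal", alpha = 6,
                                                   mixture = TRUE,
                                                   mix_location = 1.5,
                                                   mix_steepness = 3),
                              coefficients = default_sim_coefficients(),
                              terms = c("body_size", "camera_model",
                                        "dist_model", "speed_mps"),
                              speed_mean = 1.0, speed_sd = 0.3,
                              sun = "uniform", seed = 1L) {
  stopifnot(inherits(design, "trial_design"), inherits(detfun, "detfun_spec"))
  if (!is.null(coefficients) &&
      (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))) {
    stop("'coefficients' must be a fully named vector", call. = FALSE)
  }
  structure(list(design = design, detfun = detfun,
                 coefficients = coefficients, terms = terms,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 sun = sun, seed = as.integer(seed)),
            class = "sim_config")
}

# exact truncated-normal (at zero) sampler via inverse CDF
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate detection trials
#'
#' Expands the design to one row per trial (design row order is
#' deterministic, so a fixed seed reproduces the dataset exactly), draws
#' continuous covariates (speed, sun position, vertical angle derived from
#' lens height and aiming distance so the two are realistically
#' correlated), computes each trial's success probability as
#' `plogis(X %*% coefficients)` — where `X` is the stage-2 design matrix
#' built with the *true* detection function — and draws Bernoulli
#' outcomes. Mapped first-detection positions are filled in for successes.
#'
#' @param config A `sim_config`.
#' @return A `detection_trials` data frame with `nrow(design)` rows.
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- as.data.frame(config$design)
  n <- nrow(design)
  trials <- data.frame(
    outcome = 0,
    distance_m = as.numeric(design$distance_m),
    body_size = as.character(design$body_size),
    camera_model = as.character(design$camera_model),
    lens_height_cm = as.numeric(design$lens_height_cm),
    aiming_distance_m = as.numeric(design$aiming_distance_m),
    stringsAsFactors = FALSE
  )
  # downward camera pitch implied by mounting geometry, plus set-up noise;
  # this induces the angle/height and angle/aiming-distance correlations
  # seen in real deployments
  geom_angle <- atan2(trials$lens_height_cm / 100,
                      trials$aiming_distance_m) * 180 / pi
  trials$vertical_angle_deg <- geom_angle + stats::rnorm(n, 0, 0.5)
  trials$speed_mps <- rtruncnorm0(n, config$speed_mean, config$speed_sd)
  if (identical(config$sun, "uniform")) {
    trials$sun_altitude_rad <- stats::runif(n, 0.05, 1.2)
    trials$sun_azimuth_rad <- stats::runif(n, 0, 2 * pi)
  } else {
    trials$sun_altitude_rad <- rep_len(config$sun$altitude, n)
    trials$sun_azimuth_rad <- rep_len(config$sun$azimuth, n)
  }
  trials$first_x_m <- NA_real_
  trials$first_y_m <- NA_real_
  trials <- detection_trials(trials)

  if (is.null(config$coefficients)) {
    p <- detection_probability(config$detfun, trials$distance_m)
  } else {
    dm <- build_design_matrix(trials, config$terms, config$detfun)
    beta <- config$coefficients
    unknown <- setdiff(names(beta), colnames(dm$matrix))
    if (length(unknown) > 0L) {
      stop("coefficient(s) reference unknown design column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    X <- dm$matrix[, names(beta), drop = FALSE]
    p <- plogis(drop(X %*% beta))
  }
  trials$outcome <- stats::rbinom(n, 1L, p)
  det <- trials$outcome == 1L
  trials$first_x_m[det] <- stats::rnorm(sum(det), 0, 1.2)
  trials$first_y_m[det] <- pmax(0.1, trials$distance_m[det] +
                                  stats::rnorm(sum(det), 0, 0.5))
  attr(trials, "true_probability") <- p
  trials
}

#' Solar altitude and azimuth
#'
#' Low-accuracy solar ephemeris (NOAA-style closed forms: mean solar
#' anomaly/longitude, equation of centre, obliquity, declination and the
#' equation of time), accurate to well under a degree for years 1900-2100.
#' Atmospheric refraction is not applied.
#'
#' @param time `POSIXct` time(s), UTC.
#' @param latitude_deg,longitude_deg Site coordinates in degrees
#'   (longitude positive east).
#' @return Data frame with `altitude_rad` in `[-pi/2, pi/2]` and
#'   `azimuth_rad` in `[0, 2*pi)` (clockwise from north).
#' @export
solar_position <- function(time, latitude_deg, longitude_deg) {
  if (any(abs(latitude_deg) > 90)) {
    stop("latitude must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (any(abs(longitude_deg) > 180)) {
    stop("longitude must lie in [-180, 180] degrees", call. = FALSE)
  }
  time <- as.POSIXct(time, tz = "UTC")
  yr <- as.integer(format(time, "%Y"))
  if (any(yr < 1900 | yr > 2100)) {
    stop("time must fall within years 1900-2100", call. = FALSE)
  }
  deg2rad <- pi / 180
  # Julian day from Unix epoch; JD of 1970-01-01 00:00 UTC is 2440587.5
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525  # Julian centuries since J2000

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(gma * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gma * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gma * deg2rad) * 0.000289
  true_long <- gml + ctr
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(omega * deg2rad)
  decl <- asin(sin(obliq * deg2rad) * sin(app_long * deg2rad))

  vary <- tan(obliq / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (vary * sin(2 * gml * deg2rad) -
    2 * ecc * sin(gma * deg2rad) +
    4 * ecc * vary * sin(gma * deg2rad) * cos(2 * gml * deg2rad) -
    0.5 * vary^2 * sin(4 * gml * deg2rad) -
    1.25 * ecc^2 * sin(2 * gma * deg2rad))  # minutes

  minutes_utc <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  tst <- (minutes_utc + eqtime + 4 * longitude_deg) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180) * deg2rad

  lat <- latitude_deg * deg2rad
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cos_zen <- pmin(pmax(cos_zen, -1), 1)
  zen <- acos(cos_zen)
  altitude <- pi / 2 - zen

  az <- atan2(sin(ha), cos(ha) * sin(lat) - tan(decl) * cos(lat))
  azimuth <- (az + pi) %% (2 * pi)  # clockwise from north

  data.frame(altitude_rad = altitude, azimuth_rad = azimuth)
}
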