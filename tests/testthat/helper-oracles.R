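# Independent oracles and small fixture builders used across the suite.

# random but valid detection trials (both outcome classes present)
make_trials <- function(n, seed = 1) {
  set.seed(seed)
  lv <- trial_levels()
  repeat {
    df <- data.frame(
      outcome = rbinom(n, 1, 0.5),
      distance_m = runif(n, 0.5, 15),
      body_size = sample(lv$body_size, n, replace = TRUE),
      camera_model = sample(lv$camera_model, n, replace = TRUE),
      lens_height_cm = sample(c(86, 116, 146), n, replace = TRUE),
      aiming_distance_m = sample(c(5, 10, 15), n, replace = TRUE),
      vertical_angle_deg = runif(n, 0, 20),
      speed_mps = runif(n, 0.3, 2),
      sun_altitude_rad = runif(n, -0.2, 1.3),
      sun_azimuth_rad = runif(n, 0, 2 * pi),
      stringsAsFactors = FALSE
    )
    if (n < 2L || length(unique(df$outcome)) == 2L) break
  }
  detection_trials(df)
}

# per-row Bernoulli log-likelihood summation, no vectorized shortcuts
nll_brute_force <- function(trials, spec) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    p <- detection_probability(spec, trials$distance_m[i])
    p <- min(max(p, 1e-12), 1 - 1e-12)
    total <- total - (trials$outcome[i] * log(p) +
                        (1 - trials$outcome[i]) * log(1 - p))
  }
  total
}

# direct Bernoulli likelihood maximization with analytic gradient,
# independent of glm's IRLS
logit_mle_oracle <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(-(2 * y - 1) * eta)))
  }
  grad <- function(beta) {
    p <- plogis(drop(X %*% beta))
    drop(crossprod(X, p - y))
  }
  fit <- optim(rep(0, ncol(X)), nll, gr = grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit <- optim(fit$par, nll, gr = grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  setNames(fit$par, colnames(X))
}

# exhaustive Mann-Whitney pair count, ties counted one half
auc_pair_count <- function(outcomes, scores) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Michalsky (1988) approximate solar position: an independent formulation
# of the ephemeris (mean longitude/anomaly -> ecliptic longitude -> RA/dec,
# sidereal-time hour angle) used to cross-check the package's version.
michalsky_solar <- function(time, lat_deg, lon_deg) {
  d2r <- pi / 180
  jd <- as.numeric(as.POSIXct(time, tz = "UTC")) / 86400 + 2440587.5
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lambda <- (L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)) %% 360
  eps <- 23.439 - 0.0000004 * n
  ra <- atan2(cos(eps * d2r) * sin(lambda * d2r), cos(lambda * d2r))
  dec <- asin(sin(eps * d2r) * sin(lambda * d2r))
  hours_ut <- ((jd + 0.5) %% 1) * 24
  gmst <- (6.697375 + 0.0657098242 * n + hours_ut) %% 24
  lmst <- (gmst + lon_deg / 15) %% 24
  ha <- lmst * 15 * d2r - ra
  ha <- ((ha + pi) %% (2 * pi)) - pi
  lat <- lat_deg * d2r
  alt <- asin(sin(dec) * sin(lat) + cos(dec) * cos(lat) * cos(ha))
  az <- atan2(sin(ha), cos(ha) * sin(lat) - tan(dec) * cos(lat))
  c(altitude = alt, azimuth = (az + pi) %% (2 * pi))
}
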