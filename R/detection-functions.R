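#' Detection-function specification
#'
#' Describes a monotone-decreasing distance detection function for the
#' trigger process: the probability that a camera's sensor fires when an
#' animal passes at distance `y` metres. Three families are supported,
#'
#' * exponential: `p(y) = exp(-y / alpha)`
#' * half-normal: `p(y) = exp(-y^2 / (2 * alpha^2))`
#' * hazard-rate: `p(y) = 1 - exp(-(y / alpha)^(-gamma))`
#'
#' each optionally multiplied by a logistic-in-distance mixture term
#' `1 / (1 + exp(-(y - mix_location) * mix_steepness))` that allows low
#' detection immediately in front of the camera, where animals pass beneath
#' the sensor cone. The mixture adds exactly two parameters.
#'
#' @param family One of `"exponential"`, `"half_normal"`, `"hazard"`.
#' @param alpha Scale parameter, metres; must be positive.
#' @param gamma Shape parameter (> 0), hazard family only.
#' @param mixture Logical; include the logistic near-camera mixture?
#' @param mix_location Mixture midpoint distance (m, >= 0); the distance at
#'   which the logistic term halves the base curve.
#' @param mix_steepness Mixture slope (per metre, > 0).
#' @return A `detfun_spec` object.
#' @examples
#' detfun_spec("half_normal", alpha = 6, mixture = TRUE,
#'             mix_location = 1.5, mix_steepness = 3)
#' @export
detfun_spec <- function(family = c("exponential", "half_normal", "hazard"),
                        alpha, gamma = NULL, mixture = FALSE,
                        mix_location = NULL, mix_steepness = NULL) {
  family <- match.arg(family)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("'alpha' must be a positive scalar", call. = FALSE)
  }
  if (family == "hazard") {
    if (is.null(gamma) || !is.finite(gamma) || gamma <= 0) {
      stop("hazard family requires a positive 'gamma'", call. = FALSE)
    }
  } else if (!is.null(gamma)) {
    stop("'gamma' is only meaningful for the hazard family", call. = FALSE)
  }
  if (isTRUE(mixture)) {
    if (is.null(mix_location) || !is.finite(mix_location) ||
        mix_location < 0) {
      stop("mixture requires 'mix_location' >= 0", call. = FALSE)
    }
    if (is.null(mix_steepness) || !is.finite(mix_steepness) ||
        mix_steepness <= 0) {
      stop("mixture requires positive 'mix_steepness'", call. = FALSE)
    }
  } else if (!is.null(mix_location) || !is.null(mix_steepness)) {
    stop("mixture parameters supplied but 'mixture' is FALSE", call. = FALSE)
  }
  structure(list(family = family, alpha = alpha, gamma = gamma,
                 mixture = isTRUE(mixture), mix_location = mix_location,
                 mix_steepness = mix_steepness),
            class = "detfun_spec")
}

#' Number of free parameters of a detection-function specification
#'
#' One for the exponential and half-normal scale, two for the hazard
#' (scale + shape), plus two when the logistic mixture is included.
#'
#' @param spec A `detfun_spec`.
#' @return Integer parameter count K.
#' @export
n_detfun_params <- function(spec) {
  k <- if (spec$family == "hazard") 2L else 1L
  if (spec$mixture) k <- k + 2L
  k
}

# Base family curves; the hazard exponent blows up as y -> 0, where the
# detection probability tends to 1 (evaluated exactly at y = 0 as 1).
detfun_base <- function(family, y, alpha, gamma = NULL) {
  p <- switch(family,
    exponential = exp(-y / alpha),
    half_normal = exp(-y^2 / (2 * alpha^2)),
    hazard = {
      out <- 1 - exp(-(y / alpha)^(-gamma))
      out[y == 0] <- 1
      out
    },
    stop("unknown family: ", family, call. = FALSE)
  )
  pmin(pmax(p, 0), 1)
}

#' Evaluate a detection function at given distances
#'
#' @param spec A `detfun_spec`.
#' @param y Vector of distances in metres (>= 0).
#' @return Detection probabilities in `[0, 1]`.
#' @examples
#' detection_probability(detfun_spec("exponential", alpha = 5), 5)  # exp(-1)
#' @export
detection_probability <- function(spec, y) {
  stopifnot(inherits(spec, "detfun_spec"))
  if (any(y < 0)) stop("distances must be non-negative", call. = FALSE)
  p <- detfun_base(spec$family, y, spec$alpha, spec$gamma)
  if (spec$mixture) {
    p <- p * plogis((y - spec$mix_location) * spec$mix_steepness)
  }
  p
}

#' Bernoulli negative log-likelihood of trial outcomes
#'
#' `-sum(w * log p(y) + (1 - w) * log(1 - p(y)))` over trials with outcome
#' `w` and distance `y`; probabilities are clamped to `[1e-12, 1 - 1e-12]`
#' to keep the sum finite (the hazard family reaches p = 1 at y = 0).
#'
#' @param trials `detection_trials` data frame (uses `outcome`,
#'   `distance_m`).
#' @param spec A `detfun_spec`.
#' @return Non-negative scalar.
#' @export
detection_nll <- function(trials, spec) {
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  eps <- 1e-12
  p <- detection_probability(spec, trials$distance_m)
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(trials$outcome * log(p) + (1 - trials$outcome) * log1p(-p))
}

#' Akaike Information Criterion
#'
#' @param k Number of estimated parameters.
#' @param log_likelihood Maximized log-likelihood.
#' @return `2 * k - 2 * log_likelihood`.
#' @export
aic <- function(k, log_likelihood) {
  if (any(k < 0)) stop("'k' must be non-negative", call. = FALSE)
  2 * k - 2 * log_likelihood
}

# Pack/unpack free parameters on an unconstrained (log) scale.
detfun_pack <- function(family, mixture) {
  nm <- "log_alpha"
  if (family == "hazard") nm <- c(nm, "log_gamma")
  if (mixture) nm <- c(nm, "log_mix_location", "log_mix_steepness")
  nm
}

detfun_unpack <- function(theta, family, mixture) {
  alpha <- exp(theta[[1L]])
  gamma <- NULL
  i <- 2L
  if (family == "hazard") {
    gamma <- exp(theta[[i]])
    i <- i + 1L
  }
  if (mixture) {
    detfun_spec(family, alpha = alpha, gamma = gamma, mixture = TRUE,
                mix_location = exp(theta[[i]]),
                mix_steepness = exp(theta[[i + 1L]]))
  } else {
    detfun_spec(family, alpha = alpha, gamma = gamma)
  }
}

#' Fit a detection function to detection trials by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood of trial outcomes over the free
#' parameters of the chosen family (optionally with the logistic mixture),
#' optimizing on the log scale for positivity. The likelihood surface can
#' carry several local maxima, so fitting uses a deterministic multi-start
#' grid (scale starts at 2, 5, 10, 15 and 25 m, crossed with two mixture
#' midpoints when the mixture is on): Nelder-Mead from each start followed
#' by a BFGS polish, keeping the best optimum. One-parameter families use
#' Brent's method on a wide bracket instead.
#'
#' @param trials `detection_trials` data frame.
#' @param family Detection-function family.
#' @param mixture Logical; include the logistic near-camera mixture?
#' @return A `detfun_fit` with elements `spec` (fitted parameters),
#'   `log_likelihood`, `k`, `aic`, `converged`, `n_trials` and a
#'   `diagnostic` message when fitting is degenerate.
#' @export
fit_detection_function <- function(trials,
                                   family = c("exponential", "half_normal",
                                              "hazard"),
                                   mixture = FALSE) {
  family <- match.arg(family)
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  outcomes <- trials$outcome
  if (all(outcomes == 1) || all(outcomes == 0)) {
    return(structure(list(spec = NULL, log_likelihood = NA_real_,
                          k = NA_integer_, aic = NA_real_, converged = FALSE,
                          n_trials = nrow(trials),
                          diagnostic = paste0(
                            "boundary: all trials ",
                            if (all(outcomes == 1)) "detected" else "missed",
                            "; the MLE lies on the parameter boundary")),
                     class = "detfun_fit"))
  }
  # closure over the raw vectors: called thousands of times per fit
  y <- trials$distance_m
  w <- trials$outcome
  eps <- 1e-12
  is_hazard <- family == "hazard"
  nll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    alpha <- exp(theta[[1L]])
    p <- switch(family,
      exponential = exp(-y / alpha),
      half_normal = exp(-y^2 / (2 * alpha^2)),
      hazard = 1 - exp(-(y / alpha)^(-exp(theta[[2L]])))
    )
    if (mixture) {
      i <- if (is_hazard) 3L else 2L
      p <- p * plogis((y - exp(theta[[i]])) * exp(theta[[i + 1L]]))
    }
    p <- pmin(pmax(p, eps), 1 - eps)
    val <- -sum(w * log(p) + (1 - w) * log1p(-p))
    if (!is.finite(val)) 1e10 else val
  }
  par_names <- detfun_pack(family, mixture)
  n_par <- length(par_names)

  alpha_starts <- c(2, 5, 10, 15, 25)
  if (n_par == 1L) {
    opt <- optim(log(5), nll, method = "Brent",
                 lower = log(1e-3), upper = log(1e3))
    best <- list(par = opt$par, value = opt$value, converged = TRUE)
  } else {
    starts <- lapply(alpha_starts, function(a) {
      th <- log(a)
      if (is_hazard) th <- c(th, log(2))
      if (mixture) th <- c(th, log(1), log(2))
      th
    })
    best <- NULL
    for (th0 in starts) {
      nm <- try(optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8)),
                silent = TRUE)
      if (inherits(nm, "try-error")) next
      pol <- try(optim(nm$par, nll, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12)),
                 silent = TRUE)
      cand <- if (inherits(pol, "try-error") || pol$value > nm$value) {
        list(par = nm$par, value = nm$value, converged = nm$convergence == 0)
      } else {
        list(par = pol$par, value = pol$value, converged = pol$convergence == 0)
      }
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    if (is.null(best)) stop("detection-function fit failed at all starts",
                            call. = FALSE)
  }
  spec <- detfun_unpack(best$par, family, mixture)
  ll <- -best$value
  k <- n_detfun_params(spec)
  structure(list(spec = spec, log_likelihood = ll, k = k,
                 aic = aic(k, ll), converged = isTRUE(best$converged),
                 n_trials = nrow(trials), diagnostic = NULL),
            class = "detfun_fit")
}

#' @export
print.detfun_fit <- function(x, ...) {
  label <- detfun_label(if (is.null(x$spec)) list(family = "?",
                                                  mixture = FALSE) else x$spec)
  cat("Detection-function fit:", label, "\n")
  if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n")
  if (!is.null(x$spec)) {
    pars <- unlist(x$spec[c("alpha", "gamma", "mix_location",
                            "mix_steepness")])
    cat("  parameters:",
        paste(sprintf("%s = %.4g", names(pars), pars), collapse = ", "), "\n")
    cat(sprintf("  LL = %.2f, K = %d, AIC = %.2f, n = %d, converged = %s\n",
                x$log_likelihood, x$k, x$aic, x$n_trials, x$converged))
  }
  invisible(x)
}

detfun_label <- function(spec) {
  base <- c(exponential = "Exponential", half_normal = "Half-normal",
            hazard = "Hazard")[[spec$family]]
  if (isTRUE(spec$mixture)) paste0(base, " (logistic mixture)") else base
}

#' The six candidate detection-function models
#'
#' @return Data frame of family/mixture combinations: each of the three
#'   families with and without the logistic mixture.
#' @export
candidate_detfun_set <- function() {
  data.frame(
    family = rep(c("exponential", "half_normal", "hazard"), each = 2L),
    mixture = rep(c(FALSE, TRUE), times = 3L),
    stringsAsFactors = FALSE
  )
}

#' Fit all candidate detection functions
#'
#' @param trials `detection_trials` data frame.
#' @return Named list of `detfun_fit` objects, one per candidate.
#' @export
fit_all_detection_functions <- function(trials) {
  cand <- candidate_detfun_set()
  fits <- vector("list", nrow(cand))
  labels <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fits[[i]] <- fit_detection_function(trials, cand$family[i],
                                        cand$mixture[i])
    labels[i] <- detfun_label(list(family = cand$family[i],
                                   mixture = cand$mixture[i]))
  }
  names(fits) <- labels
  fits
}

#' Rank fitted detection functions by AIC
#'
#' Builds a model-selection table (label, K, LL, AIC, delta-AIC) sorted by
#' ascending AIC; the first row, with delta-AIC 0, is the selected model.
#' Ties keep input order.
#'
#' @param fits List of `detfun_fit` objects, or a list/data frame with
#'   elements `k` and `log_likelihood` per model.
#' @param labels Optional model labels; defaults to list names or fitted
#'   family labels.
#' @return A `model_selection` data frame with columns `model`, `k`,
#'   `log_likelihood`, `aic`, `delta_aic`.
#' @export
select_model <- function(fits, labels = NULL) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  k <- vapply(fits, function(f) as.numeric(f$k), numeric(1))
  ll <- vapply(fits, function(f) as.numeric(f$log_likelihood), numeric(1))
  if (is.null(labels)) {
    labels <- names(fits)
    if (is.null(labels)) {
      labels <- vapply(fits, function(f) {
        if (!is.null(f$spec)) detfun_label(f$spec) else "model"
      }, character(1))
    }
  }
  tab <- data.frame(model = labels, k = k, log_likelihood = ll,
                    aic = aic(k, ll), stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), , drop = FALSE]  # stable: ties keep input order
  tab$delta_aic <- tab$aic - tab$aic[1L]
  rownames(tab) <- NULL
  class(tab) <- c("model_selection", "data.frame")
  tab
}
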