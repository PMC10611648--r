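# End-to-end workflow: load or simulate trials, fit and select the stage-1
# detection function, fit the two stage-2 suites, evaluate by ROC, and
# export marginal-effect profiles, with a run manifest for reproducibility.

#' Stage-2 term suites
#'
#' Vertical camera angle is strongly rank-correlated with lens height and
#' aiming distance in typical deployments, so the covariates are split into
#' two suites fitted separately: an angle suite and a height+aiming suite.
#' Both include body size, camera model, speed, sun position, the stage-1
#' `dist_model` covariate and its interactions with body size and camera
#' model.
#'
#' @param suite `"angle"` or `"height"`.
#' @return Character vector of term labels.
#' @export
suite_terms <- function(suite = c("angle", "height")) {
  suite <- match.arg(suite)
  common <- c("body_size", "camera_model", "dist_model", "speed_mps",
              "sun_azimuth_rad", "body_size:dist_model",
              "camera_model:dist_model")
  if (suite == "angle") {
    c("vertical_angle_deg", common)
  } else {
    c("lens_height_cm", "aiming_distance_m", common, "sun_altitude_rad")
  }
}

# ---- JSON serialization -------------------------------------------------

detfun_spec_to_list <- function(spec) {
  spec[!vapply(spec, is.null, logical(1))]
}

list_to_detfun_spec <- function(x) {
  detfun_spec(family = x$family, alpha = x$alpha, gamma = x$gamma,
              mixture = isTRUE(x$mixture), mix_location = x$mix_location,
              mix_steepness = x$mix_steepness)
}

#' Write a fitted detection function to JSON
#' @param fit A `detfun_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detfun_json <- function(fit, path) {
  obj <- list(spec = detfun_spec_to_list(fit$spec),
              log_likelihood = fit$log_likelihood, k = fit$k, aic = fit$aic,
              converged = fit$converged, n_trials = fit$n_trials)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted detection function from JSON
#' @param path Path written by [write_detfun_json()].
#' @return A `detfun_fit`.
#' @export
read_detfun_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(spec = list_to_detfun_spec(as.list(obj$spec)),
                 log_likelihood = obj$log_likelihood, k = obj$k,
                 aic = obj$aic, converged = obj$converged,
                 n_trials = obj$n_trials, diagnostic = NULL),
            class = "detfun_fit")
}

#' Write a stage-2 model to JSON
#' @param fit A `covariate_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  obj <- list(terms = fit$terms,
              coefficients = fit$coefficients,
              vcov = unclass(fit$vcov),
              reference_levels = as.list(fit$reference_levels),
              detfun = detfun_spec_to_list(fit$detfun),
              log_likelihood = fit$log_likelihood,
              converged = fit$converged, n = fit$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stage-2 model from JSON
#'
#' The returned fit can predict and compute marginal effects but does not
#' carry the training trials; pass `trials` explicitly to those functions.
#'
#' @param path Path written by [write_model_json()].
#' @return A `covariate_fit`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- as.matrix(obj$vcov)
  dimnames(V) <- list(obj$coefficients$term, obj$coefficients$term)
  structure(list(terms = obj$terms, coefficients = obj$coefficients,
                 vcov = V, assign = NULL,
                 term_labels = obj$terms,
                 log_likelihood = obj$log_likelihood,
                 converged = obj$converged, diagnostic = NULL,
                 reference_levels = unlist(obj$reference_levels),
                 detfun = list_to_detfun_spec(as.list(obj$detfun)),
                 trials = NULL, n = obj$n),
            class = "covariate_fit")
}

write_selection_tsv <- function(tab, path) {
  out <- data.frame(Model = tab$model, K = tab$k, LL = tab$log_likelihood,
                    AIC = tab$aic, dAIC = tab$delta_aic)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_coef_tsv <- function(fit, path) {
  tab <- fit$coefficients
  names(tab) <- c("Covariate", "Estimate", "SE", "z", "p")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# mean predicted probability (+ delta-method SE) with several covariates
# set counterfactually at once; used for the two-way marginal profiles
marginal_point <- function(fit, trials, values) {
  base <- as.data.frame(trials)
  for (nm in names(values)) {
    if (is.factor(base[[nm]])) {
      base[[nm]] <- factor(as.character(values[[nm]]),
                           levels = levels(base[[nm]]))
    } else {
      base[[nm]] <- values[[nm]]
    }
  }
  dm <- build_design_matrix(base, fit$terms, fit$detfun)
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  X <- dm$matrix[, names(beta), drop = FALSE]
  p <- plogis(drop(X %*% beta))
  grad <- colMeans(X * (p * (1 - p)))
  c(estimate = mean(p), se = sqrt(drop(t(grad) %*% fit$vcov %*% grad)))
}

marginal_profile <- function(fit, trials, grids) {
  combos <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)[rev(seq_along(grids))]
  names(combos) <- names(grids)
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    marginal_point(fit, trials, as.list(combos[i, , drop = FALSE]))
  }))
  cbind(combos, as.data.frame(res))
}

#' Run the full analysis pipeline
#'
#' Executes the workflow in order: load trials from CSV (or simulate them
#' from a `sim_config`), fit all six candidate detection functions and
#' rank them by AIC, fit the angle and height+aiming stage-2 suites
#' conditioned on the selected detection function, evaluate both by ROC,
#' and write marginal-effect profiles (distance x body size x vertical
#' angle; distance x body size x camera x lens height). Any stage failure
#' aborts with the stage name and removes partial outputs.
#'
#' @param trials_path Path to a trial CSV (exclusive with `config`).
#' @param config A `sim_config` for synthetic trials.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer; overrides the config seed.
#' @param stepwise Apply backwards stepwise selection to both suites?
#' @param alpha Stepwise significance threshold.
#' @param verbose Log stage progress to stderr?
#' @return Invisibly, a list with the selection table, suite fits, AUCs
#'   and the manifest.
#' @export
run_pipeline <- function(trials_path = NULL, config = NULL,
                         out_dir = "camtrigger-run", seed = NULL,
                         stepwise = FALSE, alpha = 0.05, verbose = FALSE) {
  if (is.null(trials_path) == is.null(config)) {
    stop("supply exactly one of 'trials_path' or 'config'", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  say <- function(...) if (verbose) message(format(Sys.time(),
                                                   "%H:%M:%S "), ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(created)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outfile <- function(name) {
    p <- file.path(out_dir, name)
    created <<- c(created, p)
    p
  }

  say("stage load")
  trials <- stage("load", {
    if (!is.null(trials_path)) {
      read_trials(trials_path)
    } else {
      if (!is.null(seed)) config$seed <- as.integer(seed)
      simulate_trials(config)
    }
  })

  say("stage stage1 (", nrow(trials), " trials)")
  sel <- stage("stage1", {
    fits <- fit_all_detection_functions(trials)
    tab <- select_model(fits)
    write_selection_tsv(tab, outfile("model_selection.tsv"))
    best <- fits[[match(tab$model[1L], names(fits))]]
    write_detfun_json(best, outfile("selected_detfun.json"))
    list(fits = fits, table = tab, best = best)
  })

  say("stage stage2")
  suites <- stage("stage2", {
    out <- list()
    for (s in c("angle", "height")) {
      fit <- fit_logit(trials, suite_terms(s), sel$best)
      if (stepwise) fit <- backward_stepwise(fit, alpha = alpha)
      write_coef_tsv(fit, outfile(sprintf("glm_%s.tsv", s)))
      write_model_json(fit, outfile(sprintf("glm_%s.json", s)))
      out[[s]] <- fit
    }
    out
  })

  say("stage evaluate")
  aucs <- stage("evaluate", {
    out <- list()
    for (s in names(suites)) {
      roc <- roc_auc(trials$outcome, predict_probability(suites[[s]], trials))
      utils::write.csv(
        data.frame(threshold = roc$thresholds,
                   sensitivity = roc$sensitivities,
                   specificity = roc$specificities),
        outfile(sprintf("roc_%s.csv", s)), row.names = FALSE)
      out[[s]] <- roc$auc
    }
    out
  })

  say("stage marginal")
  stage("marginal", {
    dist_grid <- sort(unique(trials$distance_m))
    angle_grid <- round(unname(stats::quantile(trials$vertical_angle_deg,
                                               c(0.1, 0.5, 0.9))), 1)
    prof1 <- marginal_profile(suites$angle, trials, list(
      vertical_angle_deg = unique(angle_grid),
      body_size = trial_levels()$body_size,
      distance_m = dist_grid))
    utils::write.csv(prof1, outfile("marginal_distance_body.csv"),
                     row.names = FALSE)
    prof2 <- marginal_profile(suites$height, trials, list(
      camera_model = trial_levels()$camera_model,
      lens_height_cm = sort(unique(trials$lens_height_cm)),
      body_size = trial_levels()$body_size,
      distance_m = dist_grid))
    utils::write.csv(prof2, outfile("marginal_distance_body_camera_height.csv"),
                     row.names = FALSE)
  })

  manifest <- list(
    command = "run_pipeline",
    inputs = if (!is.null(trials_path)) trials_path else "simulated",
    config_hash = hash_object(if (!is.null(config)) config else trials_path),
    seed = if (!is.null(seed)) seed else
      if (!is.null(config)) config$seed else NA,
    n_trials = nrow(trials),
    selected_model = sel$table$model[1L],
    auc = aucs,
    outputs = basename(created),
    package_version = as.character(utils::packageVersion("camtrigger")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; selected: ", sel$table$model[1L])
  invisible(list(trials = trials, selection = sel$table, suites = suites,
                 auc = aucs, manifest = manifest))
}

# stable content hash via serialization to a temp file
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
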