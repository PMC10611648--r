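# Stage-2 inference: logit-link binomial regression of trial outcomes on
# experimental covariates plus the stage-1 detection-function prediction
# ("distance model" covariate), with backwards stepwise selection under a
# marginality rule, marginal effects and ROC evaluation.

as_detfun_spec <- function(detfun) {
  if (inherits(detfun, "detfun_fit")) {
    if (is.null(detfun$spec)) {
      stop("detection-function fit carries no parameters (boundary fit)",
           call. = FALSE)
    }
    detfun$spec
  } else if (inherits(detfun, "detfun_spec")) {
    detfun
  } else {
    stop("'detfun' must be a detfun_spec or detfun_fit", call. = FALSE)
  }
}

# Adds the stage-1 covariate: the fitted detection probability at each
# trial's distance, on the raw [0, 1] probability scale.
augment_trials <- function(trials, detfun) {
  spec <- as_detfun_spec(detfun)
  trials <- as.data.frame(trials)
  trials$dist_model <- detection_probability(spec, trials$distance_m)
  trials
}

term_variables <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

#' Build the stage-2 design matrix
#'
#' Expands model terms against trial covariates plus the stage-1 covariate
#' `dist_model` (the fitted detection probability at each trial's
#' distance). Categorical covariates use treatment contrasts against the
#' declared reference levels (`large_ungulate`, `HP2X`); interaction terms,
#' written `"A:B"`, are elementwise products of their parent columns.
#'
#' @param trials `detection_trials` data frame.
#' @param terms Character vector of term labels, e.g.
#'   `c("body_size", "dist_model", "body_size:dist_model")`.
#' @param detfun Fitted stage-1 model (`detfun_fit` or `detfun_spec`).
#' @return List with `matrix` (numeric design matrix incl. intercept),
#'   `assign` (column-to-term map), `term_labels` and the augmented `data`.
#' @export
build_design_matrix <- function(trials, terms, detfun) {
  aug <- augment_trials(trials, detfun)
  vars <- unique(unlist(lapply(terms, term_variables)))
  missing_vars <- setdiff(vars, names(aug))
  if (length(missing_vars) > 0L) {
    stop("unknown covariate(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) {
    if (is.factor(aug[[v]]) && anyNA(aug[[v]])) {
      stop("covariate '", v, "' contains an undeclared level", call. = FALSE)
    }
  }
  f <- if (length(terms) == 0L) stats::as.formula("~ 1") else
    stats::reformulate(terms)
  tt <- stats::terms(f)
  mm <- stats::model.matrix(f, data = aug)
  list(matrix = mm, assign = attr(mm, "assign"),
       term_labels = attr(tt, "term.labels"), data = aug)
}

#' Fit the stage-2 binomial regression
#'
#' Logit-link GLM of the trial outcome on the given terms, conditioned on a
#' fixed stage-1 detection function (its fitted probability enters as the
#' `dist_model` covariate; stage-1 parameters are held at their MLEs and
#' their uncertainty is not propagated). Wald `z` statistics and two-sided
#' normal `p`-values are reported per coefficient.
#'
#' @param trials `detection_trials` data frame.
#' @param terms Character vector of term labels (see
#'   [build_design_matrix()]); `character(0)` fits intercept-only.
#' @param detfun Fitted stage-1 model.
#' @return A `covariate_fit`: coefficient table, covariance, log-likelihood,
#'   convergence/separation diagnostics, reference levels, and the inputs
#'   needed to refit (terms, trials, stage-1 spec).
#' @export
fit_logit <- function(trials, terms, detfun) {
  dm <- build_design_matrix(trials, terms, detfun)
  X <- dm$matrix
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  y <- dm$data$outcome
  sep_warning <- FALSE
  g <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warning <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- g$coefficients
  # observed information from the IRLS weights at the optimum
  W <- g$weights
  info <- crossprod(X * sqrt(W))
  V <- solve(info)
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  mu <- g$fitted.values
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  separation <- sep_warning && max(abs(beta)) > 10
  lv <- trial_levels()
  structure(list(
    terms = terms,
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = unname(se), z = unname(z), p = unname(p),
                              stringsAsFactors = FALSE),
    vcov = V,
    assign = dm$assign,
    term_labels = dm$term_labels,
    log_likelihood = ll,
    converged = isTRUE(g$converged) && !separation,
    diagnostic = if (separation) "possible complete separation" else NULL,
    reference_levels = vapply(lv, `[`, character(1), 1L),
    detfun = as_detfun_spec(detfun),
    trials = trials,
    n = length(y)
  ), class = "covariate_fit")
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat(sprintf("Stage-2 binomial regression (logit link), n = %d\n", x$n))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$z <- round(tab$z, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("  log-likelihood: %.3f\n", x$log_likelihood))
  invisible(x)
}

#' Joint Wald tests per model term
#'
#' A categorical factor (or an interaction involving one) contributes a
#' block of contrast columns; the block is tested jointly with a Wald
#' chi-square so stepwise decisions are made per factor, not per contrast.
#'
#' @param fit A `covariate_fit`.
#' @return Data frame with one row per term: `term`, `df`, `chisq`, `p`.
#' @export
term_wald_tests <- function(fit) {
  labels <- fit$term_labels
  out <- data.frame(term = labels, df = NA_integer_, chisq = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  beta <- fit$coefficients$estimate
  for (i in seq_along(labels)) {
    idx <- which(fit$assign == i)
    b <- beta[idx]
    Vb <- fit$vcov[idx, idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(Vb) %*% b)
    out$df[i] <- length(idx)
    out$chisq[i] <- stat
    out$p[i] <- stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
  }
  out
}

# Terms that may not be dropped: any term whose variables are a strict
# subset of another remaining term's variables (marginality).
protected_terms <- function(terms) {
  var_sets <- lapply(terms, term_variables)
  prot <- vapply(seq_along(terms), function(i) {
    any(vapply(seq_along(terms), function(j) {
      i != j && all(var_sets[[i]] %in% var_sets[[j]]) &&
        length(var_sets[[j]]) > length(var_sets[[i]])
    }, logical(1)))
  }, logical(1))
  terms[prot]
}

#' Backwards stepwise selection on the stage-2 model
#'
#' Repeatedly refits after dropping the single least-significant eligible
#' term whose joint Wald `p` exceeds `alpha`. A main effect is ineligible
#' while any interaction containing it remains (marginality), and factor
#' contrast blocks are removed as a block. Stops when every eligible term
#' is significant; removing everything returns the intercept-only model.
#'
#' @param fit Initial `covariate_fit` (the global model).
#' @param alpha Significance threshold, default 0.05.
#' @return The reduced `covariate_fit`, with the removal history in
#'   attribute `"steps"`.
#' @export
backward_stepwise <- function(fit, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  steps <- character(0)
  repeat {
    if (length(fit$terms) == 0L) break
    tests <- term_wald_tests(fit)
    prot <- protected_terms(fit$terms)
    elig <- tests[!(tests$term %in% prot), , drop = FALSE]
    elig <- elig[elig$p > alpha, , drop = FALSE]
    if (nrow(elig) == 0L) break
    worst <- elig$term[which.max(elig$p)]
    steps <- c(steps, worst)
    fit <- fit_logit(fit$trials, setdiff(fit$terms, worst), fit$detfun)
  }
  attr(fit, "steps") <- steps
  fit
}

#' Predicted detection probabilities from a stage-2 fit
#'
#' Inverse-logit of the linear predictor on the same design-matrix
#' construction used for fitting (the stage-1 covariate is recomputed from
#' each trial's distance with the fit's detection function).
#'
#' @param fit A `covariate_fit`.
#' @param trials Trials to predict for; defaults to the fitting data.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, trials = fit$trials) {
  dm <- build_design_matrix(trials, fit$terms, fit$detfun)
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  X <- dm$matrix[, names(beta), drop = FALSE]
  unname(plogis(drop(X %*% beta)))
}

#' Marginal effects of a focal covariate
#'
#' For each grid value, sets the focal covariate to that value in every
#' observed trial (all other covariates kept as observed), averages the
#' predicted probabilities, and attaches a delta-method standard error from
#' the coefficient covariance. Setting `distance_m` counterfactually also
#' moves the stage-1 `dist_model` covariate, so distance profiles reflect
#' the full two-stage model.
#'
#' @param fit A `covariate_fit`.
#' @param trials Trials to average over; defaults to the fitting data.
#' @param focal Name of the focal covariate (a trial column).
#' @param grid Values to set it to; for categorical covariates these must
#'   be declared levels.
#' @return Data frame with `value`, `estimate` (mean probability), `se`.
#' @export
marginal_effects <- function(fit, trials = fit$trials, focal, grid) {
  stopifnot(length(grid) >= 1L)
  base <- as.data.frame(trials)
  if (!focal %in% names(base)) {
    stop("focal covariate '", focal, "' not found", call. = FALSE)
  }
  is_cat <- is.factor(base[[focal]]) || is.character(base[[focal]])
  lv <- if (is.factor(base[[focal]])) levels(base[[focal]]) else
    trial_levels()[[focal]]
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  out <- data.frame(value = grid, estimate = NA_real_, se = NA_real_)
  for (i in seq_along(grid)) {
    g <- grid[i]
    if (is_cat) {
      if (!as.character(g) %in% lv) {
        stop("'", g, "' is not a declared level of ", focal, call. = FALSE)
      }
      base[[focal]] <- factor(as.character(g), levels = lv)
    } else {
      base[[focal]] <- as.numeric(g)
    }
    dm <- build_design_matrix(base, fit$terms, fit$detfun)
    X <- dm$matrix[, names(beta), drop = FALSE]
    p <- plogis(drop(X %*% beta))
    out$estimate[i] <- mean(p)
    grad <- colMeans(X * (p * (1 - p)))
    out$se[i] <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  }
  out
}

#' ROC curve and AUC of predicted probabilities
#'
#' Sensitivity/specificity across all distinct score thresholds, with AUC
#' by the trapezoidal rule — numerically identical to the Mann-Whitney
#' probability that a random detection outscores a random miss, ties
#' counted one half.
#'
#' @param outcomes Binary 0/1 outcomes (both classes must be present).
#' @param scores Predicted probabilities or any monotone score.
#' @return A `roc_result`: `auc` plus aligned `thresholds`,
#'   `sensitivities`, `specificities` vectors.
#' @export
roc_auc <- function(outcomes, scores) {
  stopifnot(length(outcomes) == length(scores))
  outcomes <- as.numeric(outcomes)
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both outcome classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- outcomes[ord]
  # cumulative counts at the end of each tie group of distinct scores
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  sens <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thresholds <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(auc = auc, thresholds = thresholds, sensitivities = sens,
                 specificities = 1 - fpr),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Spearman rank correlation between two trial covariates
#'
#' Collinearity diagnostic (midrank ties) used to decide whether strongly
#' correlated deployment covariates — e.g. vertical angle vs lens height —
#' should be split across separate model suites rather than entered
#' jointly.
#'
#' @param trials `detection_trials` data frame (or any data frame).
#' @param covariates Character vector of two column names.
#' @return Spearman's rho.
#' @export
collinearity_check <- function(trials, covariates) {
  stopifnot(length(covariates) == 2L)
  x <- as.numeric(trials[[covariates[1L]]])
  y <- as.numeric(trials[[covariates[2L]]])
  if (length(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant covariate",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Combined per-interval detection probability
#'
#' Probability of observing an animal at least once in a time interval with
#' `n_visits` independent visits, each detected with probability
#' `r_e * r_t * r_p` (encounter x trigger x usable image):
#' `1 - (1 - r_e * r_t * r_p)^n_visits`.
#'
#' @param r_e,r_t,r_p Component probabilities in `[0, 1]`.
#' @param n_visits Non-negative number of visits in the interval.
#' @return Probability of at least one detection.
#' @examples
#' combined_detection_probability(0.5, 0.5, 1, 2)  # 0.4375
#' @export
combined_detection_probability <- function(r_e, r_t, r_p, n_visits) {
  rates <- c(r_e, r_t, r_p)
  if (any(rates < 0 | rates > 1)) {
    stop("detection rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_visits < 0)) stop("'n_visits' must be non-negative",
                              call. = FALSE)
  1 - (1 - r_e * r_t * r_p)^n_visits
}
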