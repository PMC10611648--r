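detfun_fixture <- detfun_spec("half_normal", alpha = 6, mixture = TRUE,
                              mix_location = 1.5, mix_steepness = 3)

test_that("the design matrix encodes contrasts, the stage-1 covariate and
           interactions correctly", {
  tr <- make_trials(40, seed = 51)
  terms <- c("body_size", "camera_model", "dist_model",
             "body_size:dist_model")
  dm <- build_design_matrix(tr, terms, detfun_fixture)
  X <- dm$matrix

  # stage-1 covariate equals the fitted probability at each trial distance
  expect_equal(unname(X[, "dist_model"]),
               detection_probability(detfun_fixture, tr$distance_m))
  # baseline coding: reference levels map to zero contrast columns
  ref <- tr$camera_model == "HP2X"
  expect_true(all(X[ref, "camera_modelPC900"] == 0))
  expect_true(all(X[!ref, "camera_modelPC900"] == 1))
  expect_true(all(X[tr$body_size == "large_ungulate",
                    c("body_sizelarge", "body_sizemedium")] == 0))
  # interaction columns are elementwise products
  expect_equal(unname(X[, "body_sizemedium:dist_model"]),
               unname(X[, "body_sizemedium"] * X[, "dist_model"]))
  i <- which(tr$body_size == "medium")[1]
  expect_equal(X[i, "body_sizemedium:dist_model"],
               unname(X[i, "dist_model"]))

  expect_error(build_design_matrix(tr, "nonexistent", detfun_fixture),
               "unknown covariate")
})

test_that("the logit fit matches closed forms and independent maximization", {
  # intercept-only: MLE is the empirical logit
  tr <- make_trials(30, seed = 52)
  tr$outcome <- rep(c(1, 0), c(18, 12))
  fit0 <- fit_logit(tr, character(0), detfun_fixture)
  expect_equal(fit0$coefficients$estimate, qlogis(0.6), tolerance = 1e-6)

  # a single binary covariate: coefficient is the 2x2 log odds ratio
  tr2 <- make_trials(200, seed = 53)
  tr2$camera_model <- factor(rep(c("HP2X", "PC900"), each = 100),
                             levels = trial_levels()$camera_model)
  tr2$outcome <- c(rbinom(100, 1, 0.7), rbinom(100, 1, 0.4))
  expect_gt(min(table(tr2$outcome, tr2$camera_model)), 0)
  fit2 <- fit_logit(tr2, "camera_model", detfun_fixture)
  tab <- table(tr2$camera_model, tr2$outcome)
  lor <- log(tab["PC900", "1"] * tab["HP2X", "0"] /
               (tab["PC900", "0"] * tab["HP2X", "1"]))
  est <- fit2$coefficients$estimate[fit2$coefficients$term ==
                                      "camera_modelPC900"]
  expect_equal(est, lor, tolerance = 1e-6)

  # coefficients match a direct likelihood maximization
  for (s in 1:5) {
    tr3 <- make_trials(40, seed = 530 + s)
    terms <- c("body_size", "dist_model", "speed_mps")
    fit3 <- fit_logit(tr3, terms, detfun_fixture)
    X <- build_design_matrix(tr3, terms, detfun_fixture)$matrix
    oracle <- logit_mle_oracle(X, tr3$outcome)
    expect_equal(setNames(fit3$coefficients$estimate, fit3$coefficients$term),
                 oracle, tolerance = 1e-6)
  }
})

test_that("rank deficiency and separation are diagnosed", {
  tr <- make_trials(60, seed = 54)
  tr$extra <- tr$speed_mps  # exact duplicate column
  expect_error(fit_logit(tr, c("speed_mps", "extra"), detfun_fixture),
               "collinear")
  sep <- make_trials(40, seed = 55)
  sep$outcome <- as.integer(sep$speed_mps > stats::median(sep$speed_mps))
  fit <- fit_logit(sep, "speed_mps", detfun_fixture)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation")
})

test_that("backwards stepwise respects significance and marginality", {
  # all-significant model is a fixed point
  tr <- simulate_trials(simulation_config(
    design = generate_design(replicates = 3), seed = 61))
  terms <- c("body_size", "camera_model", "dist_model", "speed_mps")
  fit <- fit_logit(tr, terms, detfun_fixture)
  tests <- term_wald_tests(fit)
  if (all(tests$p <= 0.05)) {
    kept <- backward_stepwise(fit)
    expect_equal(kept$terms, terms)
  }

  # marginality: a parent main effect survives while its interaction stays
  fit_int <- fit_logit(tr, c(terms, "body_size:dist_model"), detfun_fixture)
  reduced <- backward_stepwise(fit_int)
  if ("body_size:dist_model" %in% reduced$terms) {
    expect_true(all(c("body_size", "dist_model") %in% reduced$terms))
  }
  # each step strictly decreases the term count
  expect_lte(length(reduced$terms), length(fit_int$terms))

  # a pure-noise covariate is removed in the vast majority of runs
  removed <- 0L
  runs <- 50L
  for (s in seq_len(runs)) {
    trs <- simulate_trials(simulation_config(
      design = generate_design(replicates = 2), seed = 600 + s))
    base <- as.data.frame(trs)
    set.seed(6000 + s)
    base$noise <- rnorm(nrow(base))
    f <- fit_logit(base, c(terms, "noise"), detfun_fixture)
    r <- backward_stepwise(f)
    if (!"noise" %in% r$terms) removed <- removed + 1L
  }
  expect_gte(removed / runs, 0.9)
})

test_that("predictions are the inverse-logit of the linear predictor", {
  tr <- make_trials(5, seed = 71)
  fit <- fit_logit(make_trials(300, seed = 72),
                   c("body_size", "dist_model"), detfun_fixture)
  # hand-computed inverse logit on 5 rows
  X <- build_design_matrix(tr, fit$terms, detfun_fixture)$matrix
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(predict_probability(fit, tr),
               unname(1 / (1 + exp(-drop(X[, names(beta)] %*% beta)))))
  # all-zero coefficients predict one half everywhere
  fit$coefficients$estimate[] <- 0
  expect_equal(predict_probability(fit, tr), rep(0.5, 5))
  # arithmetic check of the inverse-logit map itself
  expect_equal(plogis(6.803), 1 / (1 + exp(-6.803)))
  expect_equal(plogis(6.803), 0.9989, tolerance = 1e-4)
})

test_that("marginal effects average predictions and their SEs are credible", {
  tr <- make_trials(400, seed = 81)
  set.seed(81)
  p_true <- plogis(1 - 2 * (tr$body_size == "medium") + 2 *
                     detection_probability(detfun_fixture, tr$distance_m))
  tr$outcome <- rbinom(400, 1, p_true)
  if (length(unique(tr$outcome)) < 2) tr$outcome[1:2] <- 0:1
  fit <- fit_logit(tr, c("body_size", "dist_model"), detfun_fixture)

  # intercept-only fit: marginal effect is flat across the grid
  fit0 <- fit_logit(tr, character(0), detfun_fixture)
  me0 <- marginal_effects(fit0, tr, "speed_mps", grid = c(0.5, 1, 2))
  expect_equal(diff(me0$estimate), c(0, 0))

  # closed-form averaged inverse logit for a known-coefficient model
  me <- marginal_effects(fit, tr, "body_size",
                         grid = trial_levels()$body_size)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  dm <- detection_probability(detfun_fixture, tr$distance_m)
  manual <- mean(plogis(beta["(Intercept)"] + beta["body_sizemedium"] +
                          beta["dist_model"] * dm))
  expect_equal(me$estimate[me$value == "medium"], manual)

  # frequency-weighted categorical marginal effects recover the mean
  # exactly on balanced data (the factor is crossed with everything else)
  trb <- simulate_trials(simulation_config(
    design = generate_design(replicates = 2), seed = 82))
  fitb <- fit_logit(trb, c("body_size", "dist_model"), detfun_fixture)
  meb <- marginal_effects(fitb, trb, "body_size",
                          grid = trial_levels()$body_size)
  wb <- table(trb$body_size) / nrow(trb)
  expect_equal(sum(meb$estimate * as.numeric(wb)),
               mean(predict_probability(fitb, trb)), tolerance = 1e-10)

  expect_error(marginal_effects(fit, tr, "body_size", grid = "huge"),
               "not a declared level")

  # delta-method SE against a nonparametric bootstrap
  boot <- replicate(400, {
    idx <- sample(400, replace = TRUE)
    b <- tr[idx, ]
    f <- try(fit_logit(b, c("body_size", "dist_model"), detfun_fixture),
             silent = TRUE)
    if (inherits(f, "try-error")) return(NA_real_)
    marginal_effects(f, b, "body_size", grid = "medium")$estimate
  })
  expect_equal(me$se[me$value == "medium"], sd(boot, na.rm = TRUE),
               tolerance = 0.15)
})

test_that("ROC analysis equals the Mann-Whitney pair count", {
  out <- c(1, 1, 0, 0)
  sc <- c(0.9, 0.4, 0.6, 0.2)
  r <- roc_auc(out, sc)
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_pair_count(out, sc))

  # perfect separation and pure ties
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both outcome classes")

  # random datasets, including heavy ties; endpoints anchored at (0,0),(1,1)
  set.seed(91)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    out <- rbinom(n, 1, 0.4)
    if (length(unique(out)) < 2) next
    sc <- round(runif(n), sample(1:3, 1))
    r <- roc_auc(out, sc)
    expect_equal(r$auc, auc_pair_count(out, sc), tolerance = 1e-12)
    expect_equal(r$sensitivities[1], 0)
    expect_equal(1 - r$specificities[1], 0)
    expect_equal(r$sensitivities[length(r$sensitivities)], 1)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(out, sc, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank correlations use midranks and flag degenerate input", {
  d <- data.frame(a = 1:6, b = (1:6)^2)
  expect_equal(collinearity_check(d, c("a", "b")), 1)
  d$b <- rev(d$b)
  expect_equal(collinearity_check(d, c("a", "b")), -1)
  # midrank hand computation with ties
  d2 <- data.frame(a = c(1, 2, 2, 3, 4, 5), b = c(2, 1, 3, 3, 5, 6))
  ra <- rank(d2$a); rb <- rank(d2$b)
  hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(collinearity_check(d2, c("a", "b")), hand)
  d3 <- data.frame(a = rep(1, 5), b = 1:5)
  expect_error(collinearity_check(d3, c("a", "b")), "constant")
})

test_that("the combined per-interval detection probability is exact", {
  expect_equal(combined_detection_probability(1, 1, 1, 1), 1)
  expect_equal(combined_detection_probability(0.9, 0.8, 0.7, 0), 0)
  expect_equal(combined_detection_probability(0.5, 0.5, 1, 2), 0.4375)
  expect_error(combined_detection_probability(1.2, 0.5, 0.5, 1), "\\[0, 1\\]")
  expect_error(combined_detection_probability(0.5, 0.5, 0.5, -1),
               "non-negative")
})
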