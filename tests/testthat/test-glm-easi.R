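# Stepwise per-ion linear models and EASI prediction.

test_that("exact linear dependence is recovered perfectly", {
  set.seed(10)
  x <- runif(40, 10, 60)
  vals <- cbind(`82` = rep(100, 40), `94` = x, `182` = x,
                `105` = runif(40, 5, 20))
  m <- make_matrix(vals)
  mod <- fit_stepwise(m, 182)
  expect_identical(names(mod$coefficients), "94")
  expect_equal(unname(mod$coefficients), 1, tolerance = 1e-8)
  expect_equal(mod$intercept, 0, tolerance = 1e-6)
  expect_equal(mod$r_squared, 1, tolerance = 1e-10)
})

test_that("stepwise selects the true support and matches OLS on it", {
  set.seed(128)
  n <- 128
  x1 <- runif(n, 20, 80); x2 <- runif(n, 10, 50)
  noise <- rnorm(n, 0, 0.5)
  y <- 50 + 0.8 * x1 - 0.3 * x2 + noise
  vals <- cbind(`82` = rep(100, n), `182` = y, `94` = x1, `96` = x2,
                `105` = runif(n, 5, 25), `152` = runif(n, 2, 12))
  m <- make_matrix(vals)
  mod <- fit_stepwise(m, 182)
  expect_setequal(names(mod$coefficients), c("94", "96"))

  # oracle: ordinary least squares on the true support
  oracle <- lm(y ~ x1 + x2)
  se <- coef(summary(oracle))[, "Std. Error"]
  expect_lt(abs(mod$coefficients[["94"]] - 0.8), 3 * se[["x1"]])
  expect_lt(abs(mod$coefficients[["96"]] - (-0.3)), 3 * se[["x2"]])
  expect_equal(mod$coefficients[["94"]], coef(oracle)[["x1"]], tolerance = 1e-8)
  expect_gt(mod$r_squared, 0.9)
})

test_that("null covariates enter at about the nominal false-entry rate", {
  # single candidate independent of the target: with p_enter = 0.05 the
  # partial-F null should admit it in ~5% of seeded runs
  runs <- 400
  entered <- vapply(seq_len(runs), function(i) {
    set.seed(3000 + i)
    vals <- cbind(`182` = rnorm(30, 50, 5), `94` = rnorm(30, 30, 5))
    length(fit_stepwise(make_matrix(vals), 182)$coefficients) > 0
  }, logical(1))
  rate <- mean(entered)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})

test_that("zero-variance targets and covariates are handled", {
  set.seed(4)
  vals <- cbind(`82` = rep(100, 20), `182` = runif(20, 40, 60),
                `94` = runif(20, 20, 40))
  m <- make_matrix(vals)
  # zero-variance target -> constant model
  mod82 <- fit_stepwise(m, 82)
  expect_length(mod82$coefficients, 0)
  expect_equal(mod82$intercept, 100)
  expect_equal(mod82$r_squared, 0)
  # zero-variance covariate never enters
  mod182 <- fit_stepwise(m, 182)
  expect_false("82" %in% names(mod182$coefficients))
  expect_error(fit_stepwise(m, 57), "not in the panel")
  expect_error(fit_stepwise(make_matrix(vals[1:2, , drop = FALSE]), 182),
               "at least 3")
})

test_that("fit_easi fits one model per panel ion with high R2 on generator data", {
  m <- training_matrix(n = 128, seed = 21, k = 20)
  model <- fit_easi(m)
  expect_length(model$ion_models, 20)
  expect_identical(model$panel, as.integer(colnames(m)))
  r2 <- vapply(model$ion_models, `[[`, numeric(1), "r_squared")
  # base peak is a constant model (R2 defined 0); the rest explain > 90%
  varying <- names(r2) != "82"
  expect_gt(mean(r2[varying] > 0.9), 0.9)
  expect_equal(r2[["82"]], 0)
  ncov <- vapply(model$ion_models, function(x) length(x$coefficients), integer(1))
  expect_true(all(ncov[varying] >= 1))
})

test_that("a two-channel panel models each ion on the single other channel", {
  set.seed(9)
  x <- runif(30, 20, 60)
  vals <- cbind(`94` = 2 * x + rnorm(30, 0, 0.1), `182` = x)
  model <- fit_easi(make_matrix(vals))
  expect_identical(names(model$ion_models[["94"]]$coefficients), "182")
  expect_identical(names(model$ion_models[["182"]]$coefficients), "94")
})

test_that("identical training spectra yield all-constant models", {
  vals <- matrix(rep(c(100, 55, 30), each = 5), nrow = 5,
                 dimnames = list(NULL, c("82", "182", "94")))
  model <- fit_easi(make_matrix(vals))
  expect_true(all(vapply(model$ion_models,
                         function(x) length(x$coefficients) == 0, logical(1))))
})

test_that("in-sample EASI residuals have mean zero per ion", {
  m <- training_matrix(n = 60, seed = 31, k = 12)
  model <- fit_easi(m)
  records <- predict(model, m, approach = "easi")
  res <- t(vapply(records, `[[`, records[[1]]$residuals, "residuals"))
  expect_true(all(abs(colMeans(res)) < 1e-8))
})

test_that("a query at the training mean gets the consensus prediction from EASI", {
  m <- training_matrix(n = 50, seed = 41, k = 10)
  model <- fit_easi(m)
  mean_query <- colMeans(m)
  rec <- predict(model, mean_query, approach = "easi")[[1]]
  expect_equal(unname(rec$predicted), model$consensus$mean, tolerance = 1e-8)
})

test_that("consensus predictions are identical for every query", {
  m <- training_matrix(n = 30, seed = 51, k = 8)
  model <- fit_easi(m)
  q <- assemble_matrix(as_nominal(simulate_replicates(cocaine_like_spec(), 3,
                                                      seed = 52)), model$panel)
  recs <- predict(model, q, approach = "consensus")
  for (r in recs) {
    expect_equal(unname(r$predicted), model$consensus$mean)
    expect_equal(r$residuals, r$predicted - r$measured)
  }
})

test_that("constant-model channels predict the training constant regardless of query", {
  m <- training_matrix(n = 30, seed = 61, k = 10)
  model <- fit_easi(m)
  q <- unclass(m)[1, ]
  q[["82"]] <- 87  # perturb the normally constant base-peak channel
  rec <- predict(model, q, approach = "easi")[[1]]
  expect_equal(unname(rec$predicted[["82"]]), model$ion_models[["82"]]$intercept)
})

test_that("panel mismatch is an error", {
  m <- training_matrix(n = 30, seed = 71, k = 10)
  model <- fit_easi(m)
  q <- training_matrix(n = 2, seed = 72, k = 9)
  expect_error(predict(model, q), "panel")
})

test_that("EASI predictions are not clipped to [0, 100]", {
  m <- training_matrix(n = 60, seed = 81, k = 20)
  model <- fit_easi(m)
  # a grossly off-pattern query drives some linear predictions out of range
  q <- unclass(m)[1, , drop = FALSE]
  q[1, colnames(q) != "82"] <- rev(q[1, colnames(q) != "82"]) * 3
  rec <- predict(model, q[1, ], approach = "easi")[[1]]
  expect_true(any(rec$predicted < 0 | rec$predicted > 100))
})

test_that("EASI models persist to JSON and back without changing predictions", {
  m <- training_matrix(n = 40, seed = 91, k = 12)
  model <- fit_easi(m)
  model$covariance_model <- fit_covariance(m)
  path <- withr::local_tempfile(fileext = ".json")
  write_easi_model(model, path)
  back <- read_easi_model(path)
  expect_identical(back$panel, model$panel)
  expect_equal(back$consensus$mean, model$consensus$mean)
  for (ch in as.character(model$panel)) {
    expect_equal(back$ion_models[[ch]]$coefficients,
                 model$ion_models[[ch]]$coefficients)
  }
  q <- assemble_matrix(as_nominal(simulate_replicates(cocaine_like_spec(), 5,
                                                      seed = 92)), model$panel)
  r1 <- predict(model, q, approach = "easi")
  r2 <- predict(back, q, approach = "easi")
  for (i in seq_along(r1)) expect_equal(r1[[i]]$predicted, r2[[i]]$predicted)
  # covariance model survives too
  expect_equal(back$covariance_model$covariance, model$covariance_model$covariance)
  expect_equal(mahalanobis_distance(back$covariance_model, q),
               mahalanobis_distance(model$covariance_model, q))
})
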