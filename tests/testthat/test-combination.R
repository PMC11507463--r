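test_that("the 13-variable feature set follows its definitions", {
  f <- build_features(c(KING = 0.25, IBIS = 0.25, TRUFFLE = 0.25,
                        GERMLINE = 0.25))
  expect_length(f, 13L)
  expect_true(all(f[grep("^d_", names(f))] == 0))
  expect_true(all(f[grep("^r_", names(f))] == 1))

  f2 <- build_features(c(KING = 0.2, IBIS = 0.25, TRUFFLE = 0.24,
                         GERMLINE = 0.22))
  expect_equal(f2[["d_KING_IBIS"]], -0.05)
  expect_equal(f2[["r_KING_IBIS"]], 0.8)
  expect_equal(f2[["r_TRUFFLE_IBIS"]], 0.96)
  expect_equal(f2[["r_GERMLINE_IBIS"]], 0.88)

  df <- build_features(data.frame(theta_KING = c(0.2, 0.1),
                                  theta_IBIS = c(0.25, 0.1),
                                  theta_TRUFFLE = c(0.24, 0.1),
                                  theta_GERMLINE = c(0.22, 0.1)))
  expect_equal(dim(df), c(2L, 13L))
  expect_error(build_features(c(KING = NA, IBIS = 1, TRUFFLE = 1,
                                GERMLINE = 1)), "defined")
})

test_that("bundled fusion models evaluate to their printed arithmetic", {
  models <- combination_models()
  expect_named(models, paste0("M", 1:7))

  # M7 at all-equal estimates of 0.25: direct evaluation of the constants
  f <- build_features(c(KING = 0.25, IBIS = 0.25, TRUFFLE = 0.25,
                        GERMLINE = 0.25))
  m7_direct <- 0.00279 + 0.98496 * 0.25 - 0.00034 + 0.00021 - 0.00114
  expect_equal(predict_theta(models$M7, f), m7_direct, tolerance = 1e-12)
  expect_equal(m7_direct, 0.24776, tolerance = 1e-12)

  # M2 with agreeing MoM and probability-thresholded estimates: the
  # difference term vanishes
  for (th in c(0.05, 0.2, 0.4)) {
    f2 <- build_features(c(KING = th, IBIS = 0.1, TRUFFLE = th,
                           GERMLINE = 0.1))
    expect_equal(predict_theta(models$M2, f2), 0.00209 + 0.99867 * th,
                 tolerance = 1e-12)
  }

  # evaluable at the degenerate floor where only the IBS-run estimate is
  # positive
  f3 <- build_features(c(KING = 0, IBIS = 0.00138, TRUFFLE = 0,
                         GERMLINE = 0))
  expect_true(is.finite(predict_theta(models$M7, f3)))
  expect_error(predict_theta(models$M7, f3[1:3]), "missing")

  # near-identity: when all methods agree, the fusion output tracks theta
  for (th in seq(0, 0.5, by = 0.01)) {
    f4 <- build_features(c(KING = th, IBIS = max(th, 0.00138), TRUFFLE = th,
                           GERMLINE = th))
    expect_lt(abs(predict_theta(models$M7, f4) - th), 0.01)
  }
})

test_that("stepwise fitting recovers a planted linear model", {
  n <- 5000L
  feats <- kinfuse:::with_seed(2024, {
    th <- data.frame(
      theta_KING = stats::runif(n, -0.01, 0.4),
      theta_IBIS = stats::runif(n, 0.00138, 0.4),
      theta_TRUFFLE = stats::runif(n, 0, 0.4),
      theta_GERMLINE = stats::runif(n, 0, 0.4)
    )
    build_features(th)
  })
  target <- kinfuse:::with_seed(2025, {
    0.002 + 0.95 * feats$theta_TRUFFLE + 0.004 * feats$r_KING_IBIS +
      stats::rnorm(n, sd = 2e-5)
  })
  fit <- fit_stepwise(feats, target, seed = 9)
  expect_setequal(setdiff(names(fit$coefficients), "(Intercept)"),
                  c("theta_TRUFFLE", "r_KING_IBIS"))
  expect_lt(abs(fit$coefficients[["theta_TRUFFLE"]] / 0.95 - 1), 0.01)
  expect_lt(abs(fit$coefficients[["r_KING_IBIS"]] / 0.004 - 1), 0.01)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] / 0.002 - 1), 0.02)
  expect_gt(fit$r2, 0.999)
  expect_gt(fit$cv_r2, 0.999)

  # determinism: same seed, same folds, same model
  fit2 <- fit_stepwise(feats, target, seed = 9)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$cv_r2, fit2$cv_r2)

  # pure-noise features never beat the true model on the criterion
  noisy <- cbind(feats, noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  fit3 <- fit_stepwise(noisy, target, seed = 9)
  expect_true(all(c("theta_TRUFFLE", "r_KING_IBIS") %in%
                    names(fit3$coefficients)))

  expect_error(fit_stepwise(feats[1:50, ], target[1:50]), "observations")
})

test_that("stepwise selection agrees with an established implementation", {
  # independent oracle: MASS::stepAIC on the same data and feature pool
  n <- 2000L
  feats <- kinfuse:::with_seed(31, {
    build_features(data.frame(
      theta_KING = stats::runif(n, 0, 0.4),
      theta_IBIS = stats::runif(n, 0.01, 0.4),
      theta_TRUFFLE = stats::runif(n, 0, 0.4),
      theta_GERMLINE = stats::runif(n, 0, 0.4)
    ))
  })
  target <- kinfuse:::with_seed(32, {
    0.01 + 0.8 * feats$theta_KING + 0.15 * feats$theta_IBIS +
      stats::rnorm(n, sd = 1e-4)
  })
  # search the same non-collinear pool with both implementations; selected
  # models may differ in marginal noise terms, but both must find the true
  # signal terms with matching coefficients
  pool <- feats[, c("theta_KING", "theta_IBIS", "theta_TRUFFLE",
                    "theta_GERMLINE", "r_KING_IBIS", "r_TRUFFLE_IBIS",
                    "r_GERMLINE_IBIS")]
  mine <- fit_stepwise(pool, target, seed = 4)
  dat <- cbind(pool, .y = target)
  ref <- MASS::stepAIC(
    stats::lm(.y ~ 1, data = dat), direction = "both", trace = 0,
    scope = list(upper = stats::reformulate(names(pool), ".y"))
  )
  for (term in c("theta_KING", "theta_IBIS")) {
    expect_true(term %in% names(mine$coefficients))
    expect_true(term %in% names(stats::coef(ref)))
    expect_equal(mine$coefficients[[term]], stats::coef(ref)[[term]],
                 tolerance = 1e-3)
  }
  expect_lt(abs(mine$coefficients[["theta_KING"]] - 0.8), 0.01)
  expect_lt(abs(mine$coefficients[["theta_IBIS"]] - 0.15), 0.01)
})

test_that("expected kinship is the error-free four-method mean", {
  est <- data.frame(
    theta_KING = c(0.2, 0.1), theta_IBIS = c(0.3, 0.1),
    theta_TRUFFLE = c(0.2, 0.1), theta_GERMLINE = c(0.3, 0.1)
  )
  expect_equal(expected_theta(est), c(0.25, 0.1))
  expect_error(expected_theta(est[, 1:3]), "four")
})

test_that("cohort-level fusion fitting tracks the expected coefficient", {
  est0 <- small_cohort_estimates()
  noisy1 <- estimate_cohort(inject_cohort_errors(small_cohort(), 0.02,
                                                 seed = 12))
  noisy2 <- estimate_cohort(inject_cohort_errors(small_cohort(), 0.05,
                                                 seed = 13))
  model <- fit_combination_model(
    list("0" = est0, "0.02" = noisy1, "0.05" = noisy2), seed = 3
  )
  expect_s3_class(model, "combination_model")
  expect_gt(model$r2, 0.95)
  pred <- predict_theta(model, build_features(est0))
  expect_gt(stats::cor(pred, expected_theta(est0))^2, 0.95)
  expect_error(fit_combination_model(list("0.01" = est0)), "error-free")
})

test_that("fusion models round-trip through JSON", {
  m7 <- combination_models()$M7
  js <- withr::local_tempfile(fileext = ".json")
  write_model_json(m7, js)
  back <- read_model_json(js)
  expect_identical(back$coefficients, m7$coefficients)
  expect_identical(back$subset, m7$subset)
  f <- build_features(c(KING = 0.2, IBIS = 0.21, TRUFFLE = 0.19,
                        GERMLINE = 0.2))
  expect_equal(predict_theta(back, f), predict_theta(m7, f),
               tolerance = 1e-15)
})
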