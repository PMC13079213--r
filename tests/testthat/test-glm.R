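test_that("an unadjusted fit matches the closed-form 2x2 solution", {
  set.seed(41)
  n <- 4000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + log(2) * x))
  fit <- fit_logistic(tibble::tibble(y = y, x = x), model_spec("y", "x"))
  oracle <- logit_2x2_oracle(y, x)
  i <- match("x", fit$term)
  expect_equal(fit$beta[i], oracle$beta, tolerance = 1e-6)
  expect_equal(fit$se[i], oracle$se, tolerance = 1e-6)
  expect_equal(fit$n_used, n)
})

test_that("null regressors stay within 3 SE of zero", {
  set.seed(42)
  n <- 20000
  dat <- tibble::tibble(y = rbinom(n, 1, 0.3), x = rbinom(n, 1, 0.25),
                        z = rnorm(n))
  fit <- fit_logistic(dat, model_spec("y", c("x"), covariates = "z"))
  for (tm in c("x", "z")) {
    i <- match(tm, fit$term)
    expect_lt(abs(fit$beta[i]), 3 * fit$se[i])
  }
})

test_that("the coefficient table is internally consistent", {
  set.seed(43)
  n <- 3000
  dat <- tibble::tibble(y = rbinom(n, 1, 0.3), x = rbinom(n, 1, 0.25))
  fit <- fit_logistic(dat, model_spec("y", "x"))
  expect_true(isSymmetric(fit$vcov, tol = 1e-10))
  expect_true(all(diag(fit$vcov) >= 0))
  expect_equal(fit$p, 2 * pnorm(-abs(fit$beta / fit$se)))
  td <- tidy_fit(fit)
  expect_equal(td$or, exp(td$beta))
  expect_equal(td$ci_high, exp(td$beta + qnorm(0.975) * td$se))
})

test_that("quasi-complete separation is flagged and yields no estimates", {
  toy <- tibble::tibble(y = c(0, 0, 0, 0, 1, 1, 1, 1),
                        x = c(0, 0, 0, 0, 1, 1, 1, 1))
  fit <- fit_logistic(toy, model_spec("y", "x"))
  expect_true(fit$separation_flag)
  expect_equal(nrow(tidy_fit(fit)), 0L)
  expect_error(reri_from_fit(fit, "x", "x", "x"), "flagged")
})

test_that("degenerate outcomes and missing columns error clearly", {
  dat <- tibble::tibble(y = rep(1, 20), x = rbinom(20, 1, 0.5))
  expect_error(fit_logistic(dat, model_spec("y", "x")), "single level")
  dat$y[1] <- 2
  expect_error(fit_logistic(dat, model_spec("y", "x")), "binary")
  expect_error(fit_logistic(dat, model_spec("y", "nope")), "nope")
  expect_error(model_spec("y", "x", interaction_terms = list(c("x", "z"))),
               "exposures")
})

test_that("listwise deletion happens per model", {
  set.seed(44)
  n <- 500
  dat <- tibble::tibble(y = rbinom(n, 1, 0.4), x = rbinom(n, 1, 0.5),
                        z = rnorm(n))
  dat$z[1:50] <- NA
  fit_xz <- fit_logistic(dat, model_spec("y", "x", covariates = "z"))
  fit_x <- fit_logistic(dat, model_spec("y", "x"))
  expect_equal(fit_xz$n_used, n - 50L)
  expect_equal(fit_x$n_used, n)
})

test_that("adding an orthogonal covariate barely moves a null exposure", {
  set.seed(45)
  n <- 30000
  dat <- tibble::tibble(y = rbinom(n, 1, 0.3), x = rbinom(n, 1, 0.25),
                        w = rnorm(n))
  base <- fit_logistic(dat, model_spec("y", "x"))
  adj <- fit_logistic(dat, model_spec("y", "x", covariates = "w"))
  i <- match("x", base$term); j <- match("x", adj$term)
  expect_lt(abs(base$beta[i] - adj$beta[j]), 3 * adj$se[j])
})
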