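# A synthetic fit object with chosen coefficients and covariance, for exact
# checks of the RERI algebra without a model behind it.
fake_fit <- function(b1, b2, b3, sigma = diag(3) * 1e-4) {
  terms <- c("(Intercept)", "g", "e", "g:e")
  beta <- c(-1, b1, b2, b3)
  vc <- diag(4) * 1e-4
  vc[2:4, 2:4] <- sigma
  se <- sqrt(diag(vc))
  structure(list(term = terms, beta = beta, se = se,
                 p = 2 * pnorm(-abs(beta / se)), vcov = vc, n_used = 1000L,
                 converged = TRUE, separation_flag = FALSE,
                 spec = model_spec("y", c("g", "e"),
                                   interaction_terms = list(c("g", "e")))),
            class = "psygxe_fit")
}

test_that("RERI reproduces the defining formula and its decomposition", {
  # multiplicative null is not additive null: OR 2 x OR 1.5 leaves RERI 0.5
  r <- reri_from_fit(fake_fit(log(2), log(1.5), 0), "g", "e", "g:e")
  expect_equal(r$reri, 0.5, tolerance = 1e-10)
  # full null: RERI 0 whatever the covariance
  r0 <- reri_from_fit(fake_fit(0, 0, 0, sigma = matrix(0.3, 3, 3) + diag(3)),
                      "g", "e", "g:e")
  expect_equal(r0$reri, 0, tolerance = 1e-12)
  set.seed(51)
  for (rep in 1:50) {
    b <- runif(3, -0.7, 0.7)
    r <- reri_from_fit(fake_fit(b[1], b[2], b[3]), "g", "e", "g:e")
    expect_equal(r$reri, reri_oracle(b[1], b[2], b[3]), tolerance = 1e-10)
    expect_equal(r$reri, r$or_11 - r$or_01 - r$or_10 + 1, tolerance = 1e-10)
    # decomposition: excess risks + RERI rebuild the combined excess risk
    expect_equal(r$excess_prs + r$excess_ace + r$reri, r$or_11 - 1,
                 tolerance = 1e-10)
    expect_equal(r$ci95, c(r$reri - qnorm(0.975) * r$se,
                           r$reri + qnorm(0.975) * r$se))
  }
})

test_that("the delta-method SE matches a direct quadratic form", {
  set.seed(52)
  a <- matrix(rnorm(9), 3, 3); sigma <- crossprod(a) / 10
  b <- c(0.3, 0.5, -0.2)
  r <- reri_from_fit(fake_fit(b[1], b[2], b[3], sigma), "g", "e", "g:e")
  or11 <- exp(sum(b))
  h <- c(or11 - exp(b[1]), or11 - exp(b[2]), or11)
  expect_equal(r$se, sqrt(drop(t(h) %*% sigma %*% h)), tolerance = 1e-12)
})

test_that("multiplicative results pass through the product term", {
  f <- fake_fit(0.2, 0.1, -0.25)
  m <- multiplicative_from_fit(f, "g:e")
  i <- match("g:e", f$term)
  expect_equal(m$coefficient, f$beta[i])
  expect_equal(m$se, f$se[i])
  expect_equal(m$p, f$p[i])
  expect_equal(m$direction, "antagonistic")
  expect_equal(multiplicative_from_fit(fake_fit(0, 0, 0.3), "g:e")$direction,
               "synergistic")
  expect_error(multiplicative_from_fit(f, "g:z"), "not in fit")
})

test_that("additive classification follows the sign-consistency rule", {
  classify <- function(reri, lo, hi, or11) {
    r <- structure(list(reri = reri, se = 1, ci95 = c(lo, hi), p = 0.01,
                        or_11 = or11, or_10 = 1.2, or_01 = 1.3,
                        excess_prs = 0.2, excess_ace = 0.3),
                   class = "psygxe_reri")
    classify_additive(r)
  }
  expect_equal(classify(0.24, 0.07, 0.40, or11 = 2.0), "synergistic")
  expect_equal(classify(-0.23, -0.37, -0.08, or11 = 1.5), "antagonistic")
  expect_equal(classify(0.10, -0.05, 0.25, or11 = 2.0), "none")
})

test_that("planted multiplicative interactions are recovered from one cohort", {
  sc <- interaction_scenario(30000, seed = 53, beta_prs = log(1.6),
                             beta_ace = log(1.9), scale = "multiplicative",
                             value = -0.3)
  cohort <- add_exposures(generate_cohort(sc))
  fit <- fit_gxe(cohort)
  tm <- gxe_terms()
  m <- multiplicative_from_fit(fit, tm[["interaction"]])
  expect_lt(abs(m$coefficient - (-0.3)), 3 * m$se)
  # multiplicative-null data: or_11 = or_10 * or_01 exactly
  sc0 <- interaction_scenario(30000, seed = 54, beta_prs = log(1.6),
                              beta_ace = log(1.9), value = 0)
  m0 <- multiplicative_from_fit(fit_gxe(add_exposures(generate_cohort(sc0))),
                                tm[["interaction"]])
  expect_lt(abs(m0$coefficient), 3 * m0$se)
})

test_that("the parametric bootstrap corroborates the delta-method SE", {
  sc <- interaction_scenario(20000, seed = 55, beta_prs = log(1.5),
                             beta_ace = log(1.8), scale = "additive",
                             value = 0.25)
  cohort <- add_exposures(generate_cohort(sc))
  fit <- fit_gxe(cohort)
  tm <- gxe_terms()
  r <- reri_from_fit(fit, tm[["prs"]], tm[["ace"]], tm[["interaction"]])
  set.seed(56)
  boot <- reri_bootstrap_se(fit, tm[["prs"]], tm[["ace"]], tm[["interaction"]],
                            n_draws = 2000)
  expect_lt(abs(r$se - boot) / boot, 0.10)
})
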