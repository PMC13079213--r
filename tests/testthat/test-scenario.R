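test_that("plant_additive_interaction inverts the RERI definition", {
  # multiplicative null already carries RERI 0.5 for these mains
  expect_equal(plant_additive_interaction(log(2), log(1.5), 0.5), 0)
  expect_equal(plant_additive_interaction(0, 0, 0), 0)
  # additive null for OR 2 x OR 1.5 forces a negative product term
  b3 <- plant_additive_interaction(log(2), log(1.5), 0)
  expect_equal(b3, log(2.5 / 3))
  expect_equal(reri_oracle(log(2), log(1.5), b3), 0, tolerance = 1e-12)
})

test_that("planted coefficients round-trip through the RERI formula", {
  set.seed(11)
  for (i in 1:1000) {
    b1 <- runif(1, -1, 1.5); b2 <- runif(1, -1, 1.5)
    target <- runif(1, 1 - exp(b1) - exp(b2), 3) + 1e-6
    b3 <- plant_additive_interaction(b1, b2, target)
    expect_lt(abs(reri_oracle(b1, b2, b3) - target), 1e-12)
  }
})

test_that("infeasible additive targets are rejected explicitly", {
  expect_error(plant_additive_interaction(0, 0, -1.5), "infeasible")
  expect_error(plant_additive_interaction(log(0.5), log(0.5), -0.1),
               "infeasible")
})

test_that("scenario validation rejects bad fields by name", {
  expect_error(simulation_scenario(0), "n_participants")
  expect_error(prs_component_spec(inter_threshold_correlation = 1.2),
               "inter_threshold_correlation")
  expect_error(prs_component_spec(inter_threshold_correlation = 0),
               "inter_threshold_correlation")
  expect_error(ace_spec(endorsement = c(physical_abuse = 1.2,
                                        emotional_abuse = 0.1,
                                        sexual_abuse = 0.1,
                                        emotional_neglect = 0.1,
                                        physical_neglect = 0.1)),
               "endorsement")
  expect_error(outcome_spec(prevalence = 0), "prevalence")
  expect_error(outcome_spec(interaction = list(scale = "weird", value = 0)),
               "interaction")
  expect_error(covariate_spec(p_male = -0.1), "p_male")
})

test_that("pc1 variance target maps to the exchangeable correlation", {
  ps <- prs_component_spec(n_thresholds = 10, pc1_variance_target = 0.9)
  # compound symmetry: leading share (1 + 9 rho) / 10
  expect_equal((1 + 9 * ps$inter_threshold_correlation) / 10, 0.9)
})
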