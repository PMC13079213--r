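test_that("null scenario reproduces the baseline prevalence", {
  n <- 10000
  sc <- interaction_scenario(n, seed = 101, prevalence = 0.3,
                             beta_prs = 0, beta_ace = 0, value = 0)
  cohort <- generate_cohort(sc)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(cohort$sym) - 0.3), 3 * se)
})

test_that("degenerate inter-threshold correlation collapses the score matrix", {
  sc <- simulation_scenario(
    200, seed = 5,
    prs_spec = list(scz = prs_component_spec(inter_threshold_correlation = 1),
                    bip = prs_component_spec()))
  cohort <- generate_cohort(sc)
  m <- as.matrix(cohort[grep("^scz_score_t", names(cohort))])
  # identical up to scale: all columns collapse to one standardized column
  z <- scale(m)
  expect_lt(max(abs(z - z[, 1])), 1e-6)
  expect_true(all(abs(cor(m) - 1) < 1e-10))
})

test_that("identical scenario and seed reproduce the identical cohort", {
  sc <- interaction_scenario(500, seed = 77, value = 0.2)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(interaction_scenario(500, seed = 78, value = 0.2))
  expect_false(identical(serialize(a, NULL), serialize(c2, NULL)))
})

test_that("adversity endorsement rates track the scenario", {
  eps <- c(physical_abuse = 0.10, emotional_abuse = 0.20, sexual_abuse = 0.05,
           emotional_neglect = 0.15, physical_neglect = 0.08)
  sc <- simulation_scenario(20000, seed = 9,
                            ace_spec = ace_spec(endorsement = eps,
                                                item_correlation = 0.25))
  cohort <- generate_cohort(sc)
  flags <- derive_ace(cohort)
  for (it in names(eps)) {
    se <- sqrt(eps[[it]] * (1 - eps[[it]]) / 20000)
    expect_lt(abs(mean(flags[[it]]) - eps[[it]]), 4 * se)
  }
})

test_that("MCAR missingness never removes all five items of a participant", {
  sc <- simulation_scenario(
    3000, seed = 3,
    ace_spec = ace_spec(missing_rate = 0.45))
  cohort <- generate_cohort(sc)
  items <- as.matrix(cohort[paste0("cts5_item_", 1:5)])
  expect_equal(nrow(cohort), 3000)
  expect_gt(sum(is.na(items)), 0)
  expect_true(all(rowSums(!is.na(items)) >= 1))
})

test_that("cohort TSV and data dictionary round-trip", {
  sc <- interaction_scenario(120, seed = 2)
  cohort <- generate_cohort(sc)
  tmp <- file.path(tempdir(), "cohort.tsv")
  write_cohort(cohort, tmp)
  back <- read_cohort(tmp)
  expect_equal(nrow(back), 120)
  expect_identical(levels(back$sex), levels(cohort$sex))
  expect_equal(back$scz_score_t10, cohort$scz_score_t10, tolerance = 1e-9)
  dict <- attr(back, "dictionary")
  expect_equal(dict$cts5_item_1$role, "adversity_item")
  unlink(c(tmp, paste0(sub(".tsv", "", tmp), ".dictionary.json")))
})
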