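cts_row <- function(i1, i2, i3, i4, i5) {
  data.frame(cts5_item_1 = i1, cts5_item_2 = i2, cts5_item_3 = i3,
             cts5_item_4 = i4, cts5_item_5 = i5)
}
# fully non-endorsed profile: abuse items "Never true", neglect items
# ("felt loved", "taken to doctor") "Very often true"
none <- cts_row(0, 0, 0, 4, 4)

test_that("abuse items endorse at 'Sometimes true' and above", {
  r <- derive_ace(cts_row(2, 0, 0, 4, 4))  # physical abuse "Sometimes true"
  expect_equal(r$any_ace, 1L)
  expect_equal(r$ace_count, 1L)
  expect_equal(r$physical_abuse, 1L)
  expect_equal(derive_ace(none)$any_ace, 0L)
  expect_equal(derive_ace(none)$ace_count, 0L)
})

test_that("neglect items are reverse scored", {
  r <- derive_ace(cts_row(0, 0, 0, 0, 4))  # felt loved "Never true"
  expect_equal(r$any_ace, 1L)
  expect_equal(r$emotional_neglect, 1L)
  # neglect items at "Very often true" are non-endorsed even though the code
  # is maximal
  r2 <- derive_ace(cts_row(0, 0, 0, 4, 4))
  expect_equal(r2$any_ace, 0L)
})

test_that("partial missingness classifies from observed items only", {
  r <- derive_ace(cts_row(NA, NA, NA, NA, 3))
  expect_equal(r$any_ace, 0L)
  expect_equal(r$ace_count, 0L)
  r2 <- derive_ace(cts_row(3, NA, NA, NA, NA))
  expect_equal(r2$any_ace, 1L)
  expect_equal(r2$ace_count, 1L)
})

test_that("all-missing rows are excluded with a record", {
  x <- rbind(cts_row(NA, NA, NA, NA, NA), none)
  x$participant_id <- c("A", "B")
  r <- derive_ace(x)
  expect_true(is.na(r$any_ace[1]))
  excl <- attr(r, "exclusions")
  expect_equal(excl$row, 1L)
  expect_equal(excl$participant_id, "A")
  expect_match(excl$reason, "missing")
})

test_that("out-of-range sentinel codes are treated as missing", {
  r <- derive_ace(cts_row(-818, 0, 0, 4, 4))  # prefer-not-to-answer style
  expect_equal(r$any_ace, 0L)
  expect_true(is.na(r$physical_abuse))
})

test_that("endorsing one more item never decreases the count or flips any_ace", {
  set.seed(21)
  for (rep in 1:200) {
    resp <- sample(c(0:4, NA), 5, replace = TRUE)
    if (all(is.na(resp))) resp[1] <- 0L
    base <- derive_ace(cts_row(resp[1], resp[2], resp[3], resp[4], resp[5]))
    j <- sample(5, 1)
    resp2 <- resp
    resp2[j] <- if (j <= 3) 4L else 0L  # force endorsement of item j
    more <- derive_ace(cts_row(resp2[1], resp2[2], resp2[3], resp2[4], resp2[5]))
    expect_gte(more$ace_count, base$ace_count)
    expect_gte(more$any_ace, base$any_ace)
  }
})

test_that("symptom construction rules behave and unknown rules error", {
  expect_equal(derive_symptom(c("yes", "no", NA), "direct"), c(1L, 0L, NA))
  expect_equal(derive_symptom(c(1, 0, NA), "direct"), c(1L, 0L, NA))
  expect_equal(derive_symptom(c(0, 1, 2, 3), "ordinal_ge", 2), c(0L, 0L, 1L, 1L))
  x <- c(1:100)
  expect_equal(sum(derive_symptom(x, "quantile", 0.25)), 25L)  # scores below Q1
  expect_error(derive_symptom(c(0, 2), "direct"), "non-binary")
  expect_error(derive_symptom(1:3, "made_up"), "unregistered")
})

test_that("domain endorsement is any-endorsement with missing propagation", {
  expect_equal(derive_domain(cbind(0, 0, 1)), 1L)
  expect_equal(derive_domain(cbind(0, 0, 0)), 0L)
  expect_equal(derive_domain(cbind(NA, 1)), 1L)
  expect_equal(derive_domain(cbind(NA, 0)), 0L)
  expect_true(is.na(derive_domain(cbind(NA_integer_, NA_integer_))))
  # invariant to member ordering
  set.seed(4)
  m <- matrix(sample(c(0L, 1L, NA), 300, replace = TRUE), ncol = 3)
  expect_equal(derive_domain(m), derive_domain(m[, 3:1]))
})

test_that("derive_phenotypes appends symptom and domain columns", {
  cat <- build_catalog(c(a = 2, b = 1))
  cohort <- tibble::tibble(
    cts5_item_1 = c(2, 0), cts5_item_2 = c(0, 0), cts5_item_3 = c(0, 0),
    cts5_item_4 = c(4, 4), cts5_item_5 = c(4, 4),
    a_s1 = c(1, 0), a_s2 = c(0, 0), b_s1 = c(0, 1))
  out <- derive_phenotypes(cohort, cat)
  expect_equal(out$phen_dom_a, c(1L, 0L))
  expect_equal(out$phen_b_s1, c(0L, 1L))
  expect_equal(out$any_ace, c(1L, 0L))
  expect_error(derive_phenotypes(cohort[setdiff(names(cohort), "a_s2")], cat),
               "configuration error")
})

test_that("the default catalog counts 55 symptoms, 7 domains, 61 phenotypes", {
  counts <- catalog_counts(default_phenotype_catalog())
  expect_identical(counts$n_symptoms, 55L)
  expect_identical(counts$n_domains, 7L)
  expect_identical(counts$n_phenotypes, 61L)
})

test_that("catalogs survive a JSON round-trip", {
  cat <- default_phenotype_catalog()
  tmp <- tempfile(fileext = ".json")
  write_catalog(cat, tmp)
  back <- read_catalog(tmp)
  expect_equal(back$phenotype_id, cat$phenotype_id)
  expect_equal(back$members, cat$members)
  expect_equal(back$rule_param, cat$rule_param)
  unlink(tmp)
})

test_that("catalog validation rejects malformed entries", {
  cat <- default_phenotype_catalog()
  bad <- cat; bad$rule[1] <- "mystery"
  expect_error(phenotype_catalog(bad), "unregistered")
  bad2 <- cat; bad2$phenotype_id[2] <- bad2$phenotype_id[1]
  expect_error(phenotype_catalog(bad2), "unique")
  bad3 <- cat; bad3$members[[which(bad3$level == "domain")[1]]] <- "ghost_s9"
  expect_error(phenotype_catalog(bad3), "unknown symptoms")
})
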