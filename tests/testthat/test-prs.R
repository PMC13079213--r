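test_that("rank-1 score matrices collapse to the standardized column", {
  set.seed(31)
  base <- rnorm(60)
  x <- outer(base, 10^seq(-4, 1, length.out = 10))  # identical up to scale
  p <- prs_pca(x)
  expect_equal(p$pc1_variance_fraction, 1)
  expect_equal(p$score, as.numeric(scale(base)), tolerance = 1e-8)
})

test_that("PC1 variance share matches a brute-force eigendecomposition", {
  set.seed(32)
  for (rep in 1:5) {
    x <- matrix(rnorm(200 * 10), 200, 10) + rnorm(200)
    p <- prs_pca(x)
    o <- pc1_oracle(x)
    expect_equal(p$pc1_variance_fraction, o$variance_fraction,
                 tolerance = 1e-10)
    # loadings span the same direction as the brute-force eigenvector
    expect_equal(abs(sum(p$loadings * o$vector)), 1, tolerance = 1e-8)
  }
})

test_that("the score is standardized and sign-aligned to the score average", {
  set.seed(33)
  x <- matrix(rnorm(500 * 10), 500, 10) + 2 * rnorm(500)
  p <- prs_pca(x)
  expect_lt(abs(mean(p$score)), 1e-8)
  expect_lt(abs(sd(p$score) - 1), 1e-8)
  expect_gt(cor(p$score, rowMeans(scale(x))), 0)
  # negating the inputs reverses the risk direction, so the score flips
  expect_equal(prs_pca(-x)$score, -p$score, tolerance = 1e-8)
})

test_that("a common positive affine transform leaves the score unchanged", {
  set.seed(34)
  x <- matrix(rnorm(300 * 10), 300, 10) + rnorm(300)
  p0 <- prs_pca(x)$score
  p1 <- prs_pca(3.7 * x + 11)$score
  expect_equal(p1, p0, tolerance = 1e-8)
})

test_that("zero-variance threshold columns are reported by name", {
  x <- matrix(rnorm(300), 30, 10)
  colnames(x) <- paste0("t", 1:10)
  x[, 4] <- 2.5
  expect_error(prs_pca(x), "t4")
  x[, 4] <- rnorm(30); x[5, 4] <- NA
  expect_error(prs_pca(x), "missing")
})

test_that("dichotomization flags scores strictly above the 75th percentile", {
  expect_equal(sum(dichotomize_prs(1:100)), 25L)
  expect_equal(sum(dichotomize_prs(rep(1, 50))), 0L)  # strict inequality
  set.seed(35)
  high <- dichotomize_prs(rnorm(10000))
  expect_lt(abs(mean(high) - 0.25), 0.02)
})

test_that("PRSice-style all-score tables are read with labels intact", {
  tab <- data.frame(FID = paste0("F", 1:6), IID = paste0("I", 1:6),
                    check.names = FALSE)
  labs <- c("5e-08", "1e-06", "0.001", "0.05", "0.5", "1")
  for (l in labs) tab[[l]] <- rnorm(6)
  tmp <- tempfile(fileext = ".txt")
  write.table(tab, tmp, row.names = FALSE, quote = FALSE)
  got <- read_prs_scores(tmp)
  expect_equal(got$ids, tab$FID)
  expect_equal(colnames(got$scores), labs)
  unlink(tmp)
})
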