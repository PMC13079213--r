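# Independent oracles used to check package computations.

# Closed-form 2x2 contingency-table log-OR and its SE, sqrt(sum of 1/cell).
logit_2x2_oracle <- function(y, x) {
  n11 <- sum(y == 1 & x == 1); n10 <- sum(y == 1 & x == 0)
  n01 <- sum(y == 0 & x == 1); n00 <- sum(y == 0 & x == 0)
  list(beta = log((n11 * n00) / (n10 * n01)),
       se = sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00))
}

# RERI from the defining formula over the three log-ORs.
reri_oracle <- function(b1, b2, b3) exp(b1 + b2 + b3) - exp(b1) - exp(b2) + 1

# Brute-force leading eigenpair of the correlation matrix of x.
pc1_oracle <- function(x) {
  e <- eigen(stats::cor(x), symmetric = TRUE)
  list(variance_fraction = e$values[1] / sum(e$values),
       vector = e$vectors[, 1])
}
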