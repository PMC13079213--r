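#' Additive interaction: relative excess risk due to interaction (RERI)
#'
#' From a logistic fit with binary exposures \eqn{G} (high PRS), \eqn{E}
#' (any ACE) and their product term, with coefficients \eqn{\beta_1, \beta_2,
#' \beta_3}, the cell odds ratios against the doubly unexposed are
#' \eqn{OR_{10} = e^{\beta_1}}, \eqn{OR_{01} = e^{\beta_2}},
#' \eqn{OR_{11} = e^{\beta_1 + \beta_2 + \beta_3}}, and
#' \deqn{RERI = OR_{11} - OR_{01} - OR_{10} + 1.}
#' RERI decomposes the combined excess risk: \eqn{OR_{11} - 1 =
#' (OR_{10} - 1) + (OR_{01} - 1) + RERI}, i.e. excess risk from the PRS
#' alone, from ACEs alone, and the departure from additivity.
#'
#' The standard error comes from the delta method: with gradient
#' \eqn{h = (OR_{11} - OR_{10},\; OR_{11} - OR_{01},\; OR_{11})} over
#' \eqn{(\beta_1, \beta_2, \beta_3)} and \eqn{\Sigma} the corresponding 3x3
#' block of the coefficient covariance matrix, \eqn{se^2 = h^\top \Sigma h}.
#' (Covariate coefficients do not enter RERI, so their gradient entries are
#' zero and the 3x3 block is exact, not an approximation to the full
#' covariance propagation.) The 95% CI is \eqn{RERI \mp 1.96\,se} and the
#' p-value is two-sided Wald on \eqn{RERI/se}.
#'
#' @param fit A converged, unflagged `psygxe_fit` containing the three terms.
#' @param prs_term,ace_term Names of the two main-effect terms.
#' @param interaction_term Name of the product term (e.g.
#'   `"prs_scz_high:any_ace"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `psygxe_reri`: `reri`, `se`, `ci95` (length-2),
#'   `p`, `or_11`, `or_10`, `or_01`, `excess_prs` (`or_10 - 1`),
#'   `excess_ace` (`or_01 - 1`).
#' @export
reri_from_fit <- function(fit, prs_term, ace_term, interaction_term,
                          conf_level = 0.95) {
  stopifnot(inherits(fit, "psygxe_fit"))
  if (fit$separation_flag)
    stop("refusing flagged fit (separation or non-convergence): estimates ",
         "are unavailable", call. = FALSE)
  idx <- match(c(prs_term, ace_term, interaction_term), fit$term)
  if (anyNA(idx))
    stop("term(s) not in fit: ",
         paste(c(prs_term, ace_term, interaction_term)[is.na(idx)],
               collapse = ", "), call. = FALSE)
  b <- fit$beta[idx]
  or_10 <- exp(b[1]); or_01 <- exp(b[2]); or_11 <- exp(sum(b))
  reri <- or_11 - or_01 - or_10 + 1
  h <- c(or_11 - or_10, or_11 - or_01, or_11)
  sigma <- fit$vcov[idx, idx]
  se <- sqrt(max(drop(t(h) %*% sigma %*% h), 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(reri = reri, se = se,
                 ci95 = c(reri - z * se, reri + z * se),
                 p = 2 * pnorm(-abs(reri / se)),
                 or_11 = or_11, or_10 = or_10, or_01 = or_01,
                 excess_prs = or_10 - 1, excess_ace = or_01 - 1),
            class = "psygxe_reri")
}

#' Multiplicative interaction: the product-term log-odds coefficient
#'
#' The multiplicative interaction equals the product-term coefficient
#' \eqn{\beta_3 = \log OR_{11} - \log OR_{10} - \log OR_{01} =
#' \log[OR_{11} / (OR_{10} \cdot OR_{01})]}. A coefficient above zero is a
#' multiplicative synergistic interaction (ACE effects amplified at high
#' genetic risk); below zero, antagonistic (ACE effects dampened at high
#' genetic risk, e.g. a ceiling effect).
#'
#' @param fit A converged, unflagged `psygxe_fit`.
#' @param interaction_term Name of the product term.
#' @return A list of class `psygxe_multiplicative`: `coefficient`, `se`, `p`,
#'   `direction` (`"synergistic"`, `"antagonistic"`, or `"null"` at exactly
#'   zero).
#' @export
multiplicative_from_fit <- function(fit, interaction_term) {
  stopifnot(inherits(fit, "psygxe_fit"))
  if (fit$separation_flag)
    stop("refusing flagged fit (separation or non-convergence): estimates ",
         "are unavailable", call. = FALSE)
  i <- match(interaction_term, fit$term)
  if (is.na(i))
    stop("term not in fit: ", interaction_term, call. = FALSE)
  b3 <- fit$beta[i]
  structure(list(coefficient = b3, se = fit$se[i], p = fit$p[i],
                 direction = if (b3 > 0) "synergistic"
                             else if (b3 < 0) "antagonistic" else "null"),
            class = "psygxe_multiplicative")
}

#' Classify an additive interaction estimate
#'
#' `"none"` when the 95% CI spans zero. Otherwise the RERI sign is compared
#' with the sign of the combined excess risk `or_11 - 1`: a concordant sign
#' is an additive synergistic effect (joint effect beyond the sum of the two
#' alone), a discordant sign is antagonistic. (Odds ratios themselves are
#' always positive, so the sign rule lives on the excess-risk scale.)
#'
#' @param result A `psygxe_reri` from [reri_from_fit()].
#' @return `"synergistic"`, `"antagonistic"`, or `"none"`.
#' @export
classify_additive <- function(result) {
  stopifnot(inherits(result, "psygxe_reri"))
  if (result$ci95[1] <= 0 && result$ci95[2] >= 0) return("none")
  if (sign(result$reri) == sign(result$or_11 - 1)) "synergistic" else "antagonistic"
}

#' Parametric-bootstrap standard error of RERI
#'
#' Draws coefficient vectors from the multivariate normal implied by the
#' fitted coefficients and covariance matrix, recomputes RERI for each draw,
#' and returns the empirical standard deviation. Used as an independent
#' check on the delta-method standard error.
#'
#' @param fit A converged `psygxe_fit`.
#' @param prs_term,ace_term,interaction_term Term names as in
#'   [reri_from_fit()].
#' @param n_draws Number of bootstrap replicates.
#' @return Bootstrap SE (a single number).
#' @export
reri_bootstrap_se <- function(fit, prs_term, ace_term, interaction_term,
                              n_draws = 2000L) {
  stopifnot(inherits(fit, "psygxe_fit"), !fit$separation_flag)
  idx <- match(c(prs_term, ace_term, interaction_term), fit$term)
  if (anyNA(idx)) stop("term(s) not in fit", call. = FALSE)
  draws <- MASS::mvrnorm(n_draws, mu = fit$beta[idx], Sigma = fit$vcov[idx, idx])
  reri <- exp(rowSums(draws)) - exp(draws[, 1]) - exp(draws[, 2]) + 1
  sd(reri)
}

#' @export
print.psygxe_reri <- function(x, ...) {
  cat(sprintf("RERI %.3f (95%% CI %.3f to %.3f; p = %.3g) [%s]\n",
              x$reri, x$ci95[1], x$ci95[2], x$p, classify_additive(x)))
  cat(sprintf("  OR11 %.3f = 1 + excess_prs %.3f + excess_ace %.3f + RERI %.3f\n",
              x$or_11, x$excess_prs, x$excess_ace, x$reri))
  invisible(x)
}

#' @export
print.psygxe_multiplicative <- function(x, ...) {
  cat(sprintf("multiplicative interaction %.3f (SE %.3f; p = %.3g) [%s]\n",
              x$coefficient, x$se, x$p, x$direction))
  invisible(x)
}
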