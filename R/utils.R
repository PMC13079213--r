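`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric and non-missing")
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (bad) stop_field(field, sprintf("probabilities must lie in %s", if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stop_field(field, "must be TRUE or FALSE")
  invisible(x)
}

#' @importFrom stats qlogis plogis pnorm qnorm quantile rbinom rnorm runif
#'   binomial coef vcov glm glm.control model.matrix complete.cases
#'   prcomp sd cor setNames as.formula p.adjust rmultinom
NULL
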