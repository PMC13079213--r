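#' Aggregate per-threshold polygenic scores by their first principal component
#'
#' Raw polygenic scores computed at several GWAS p-value thresholds are
#' highly correlated but differ in scale by orders of magnitude, so each
#' column is centered and scaled to unit variance before the
#' eigendecomposition (correlation-matrix PCA). The first principal
#' component is extracted, sign-aligned so that it correlates positively
#' with the row-wise mean of the standardized columns (the sign of a
#' principal component is otherwise arbitrary, and alignment must not peek
#' at any outcome), and standardized to mean 0, SD 1 over the sample.
#'
#' @param scores An `n x m` numeric matrix (or data frame) of per-threshold
#'   scores, no missing entries, `n > m`.
#' @param threshold_labels Optional labels for the columns (e.g. the p-value
#'   thresholds `5e-8 ... 1`), carried as names of `loadings`.
#' @return A list of class `psygxe_prs` with `score` (standardized PC1),
#'   `high` (binary, top quartile, from [dichotomize_prs()]), `loadings`
#'   (column loadings of PC1), and `pc1_variance_fraction`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(500), 50, 10) + rnorm(50)
#' p <- prs_pca(x)
#' c(mean(p$score), sd(p$score), p$pc1_variance_fraction)
#' @export
prs_pca <- function(scores, threshold_labels = NULL) {
  x <- as.matrix(scores)
  if (!is.numeric(x)) stop_field("scores", "must be numeric")
  if (anyNA(x))
    stop("missing entries in the score matrix; drop incomplete rows upstream",
         call. = FALSE)
  if (nrow(x) <= ncol(x))
    stop_field("scores", "needs more rows than threshold columns")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% paste0("column ", which(sds == 0))
    stop("zero-variance threshold column: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  z <- scale(x)
  if (cor(score, rowMeans(z)) < 0) {
    score <- -score
    loadings <- -loadings
  }
  score <- as.numeric(scale(score))
  names(loadings) <- threshold_labels %||% colnames(x) %||%
    paste0("t", seq_len(ncol(x)))
  structure(list(score = score,
                 high = dichotomize_prs(score),
                 loadings = loadings,
                 pc1_variance_fraction = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "psygxe_prs")
}

#' Dichotomize a polygenic score at its 75th percentile
#'
#' High genetic risk is defined as a score strictly above the empirical 75th
#' percentile (linear-interpolation quantile, `type = 7`). The rule is
#' deterministic and seedless; with heavy ties at the threshold fewer than a
#' quarter of the sample can be flagged high.
#'
#' @param score Numeric vector (non-empty).
#' @param probs Quantile cut point; default 0.75.
#' @return Integer vector: 1 above the cut, 0 otherwise.
#' @examples
#' table(dichotomize_prs(1:100))  # exactly 25 high
#' @export
dichotomize_prs <- function(score, probs = 0.75) {
  if (length(score) == 0L) stop_field("score", "must be non-empty")
  as.integer(score > quantile(score, probs, names = FALSE, type = 7))
}

#' Read a PRSice-style "all score" table
#'
#' Accepts the layout PRSice writes: one ID column (`FID`/`IID` or a single
#' id column) followed by one numeric column per p-value threshold; or any
#' generic delimited table with an id column plus threshold columns.
#'
#' @param path Path to a whitespace- or tab-delimited score file.
#' @param id_cols Candidate id column names; the ones present are used (first
#'   as the id carried forward).
#' @return A list with `ids` (character) and `scores` (numeric matrix, one
#'   column per threshold, threshold labels preserved from the header).
#' @export
read_prs_scores <- function(path, id_cols = c("FID", "IID", "ID", "participant_id")) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  present <- intersect(id_cols, names(tab))
  if (length(present) == 0L)
    stop_field("path", paste("no id column found; expected one of:",
                             paste(id_cols, collapse = ", ")))
  score_cols <- setdiff(names(tab), present)
  scores <- as.matrix(tab[score_cols])
  if (!is.numeric(scores)) stop_field("path", "threshold columns must be numeric")
  list(ids = as.character(tab[[present[1]]]), scores = scores)
}
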