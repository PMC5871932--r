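#' Fit a selection index by principal component regression
#'
#' Regresses a target trait (yield per unit area, not measurable on single
#' plants) on secondary traits that are, using the leading principal
#' components of the predictors. The number of components is the one
#' minimizing the leave-one-out cross-validation root-mean-square error,
#' computed by literal refitting; ties (within 1e-12) go to the smallest k.
#' Coefficients are back-transformed to the original trait scale and an
#' intercept is carried so predictions are in yield units. Predictors are
#' mean-centered; set `scale = TRUE` to also unit-scale them.
#'
#' @param trait_means numeric matrix or data frame, observations (cultivars)
#'   x traits, no missing values.
#' @param yield numeric response vector.
#' @param max_components largest number of components to consider; capped at
#'   the predictor rank.
#' @param scale unit-scale predictors before PCA (default `FALSE`).
#' @return An object of class `gs_index_model` with elements `coefficients`
#'   (named, original trait scale), `intercept`, `n_components`,
#'   `rmse_profile`, `trait_names`, `scale`.
#' @export
fit_pcr <- function(trait_means, yield, max_components = ncol(trait_means),
                    scale = FALSE) {
  x <- as.matrix(trait_means)
  y <- as.numeric(yield)
  if (nrow(x) != length(y)) stop("trait table and yield length differ")
  if (nrow(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rk <- qr(sweep(x, 2L, colMeans(x)))$rank
  if (max_components > min(rk, nrow(x) - 2L))
    max_components <- min(rk, nrow(x) - 2L)
  if (max_components < 1L) stop("predictor matrix has rank 0")

  rmse <- vapply(seq_len(max_components), function(k) {
    press <- vapply(seq_len(nrow(x)), function(i) {
      fit <- pcr_solve(x[-i, , drop = FALSE], y[-i], k, scale)
      (y[i] - (fit$intercept + sum(fit$coefficients * x[i, ])))^2
    }, numeric(1))
    sqrt(mean(press))
  }, numeric(1))
  k <- which(rmse <= min(rmse) + 1e-12)[1L]

  fit <- pcr_solve(x, y, k, scale)
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(x)),
                 intercept = fit$intercept, n_components = k,
                 rmse_profile = rmse, trait_names = colnames(x),
                 scale = scale),
            class = "gs_index_model")
}

# PCR at fixed component count; coefficients on the original predictor scale
pcr_solve <- function(x, y, k, scale = FALSE) {
  m <- colMeans(x)
  s <- if (scale) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  if (any(s == 0)) stop("constant predictor cannot be unit-scaled")
  xc <- sweep(sweep(x, 2L, m), 2L, s, `/`)
  sv <- svd(xc)
  keep <- seq_len(k)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], k)
  gamma <- solve(crossprod(scores), crossprod(scores, y - mean(y)))
  b <- (sv$v[, keep, drop = FALSE] %*% gamma)[, 1L] / s
  list(coefficients = b, intercept = mean(y) - sum(b * m))
}

#' @export
print.gs_index_model <- function(x, ...) {
  cat(sprintf("<gs_index_model> %d component(s), LOOCV RMSE %.4g\n",
              x$n_components, x$rmse_profile[x$n_components]))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Construct an index model from fixed coefficients
#'
#' Wraps published regression weights (e.g. the bundled
#' `index_coefficients.csv`) into the model object used by the rest of the
#' pipeline.
#'
#' @param coefficients named numeric vector of per-trait weights.
#' @param intercept scalar, default 0 (the index as printed carries none).
#' @return A `gs_index_model` (with an empty RMSE profile).
#' @export
index_model <- function(coefficients, intercept = 0) {
  structure(list(coefficients = coefficients, intercept = intercept,
                 n_components = NA_integer_, rmse_profile = numeric(0),
                 trait_names = names(coefficients), scale = FALSE),
            class = "gs_index_model")
}

#' Compute selection index values
#'
#' The index of individual i is `s_i = intercept + sum_j b_j u_ij`, where
#' `u_ij` is the observed, expected or predicted value of trait j. The map
#' is linear, so the index of a mean trait vector equals the mean index.
#' Because selection uses only rankings, the intercept never changes who is
#' selected; set `intercept = FALSE` for the pure weighted sum.
#'
#' @param traits numeric matrix or data frame, individuals x traits, with
#'   column names covering the model's `trait_names` (extra columns and
#'   arbitrary order allowed).
#' @param model a `gs_index_model`.
#' @param source label recorded with the values: `"observed"`, `"expected"`
#'   or `"predicted"`.
#' @param intercept include the model intercept (default `TRUE`).
#' @return data.frame with columns `individual_id`, `value`, `source`.
#' @export
compute_index <- function(traits, model, source = "observed",
                          intercept = TRUE) {
  x <- as.matrix(traits)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$trait_names)) stop("trait-name mismatch")
    colnames(x) <- model$trait_names
  }
  if (!all(model$trait_names %in% colnames(x))) stop("trait-name mismatch")
  x <- x[, model$trait_names, drop = FALSE]
  s <- drop(x %*% model$coefficients) +
    if (intercept) model$intercept else 0
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  data.frame(individual_id = ids, value = unname(s), source = source,
             stringsAsFactors = FALSE)
}

#' Mantel test for similarity of two trait correlation matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries;
#' the p-value is the permutation tail probability over simultaneous
#' row/column permutations of the second matrix, with the identity
#' permutation included in the null set, i.e.
#' `p = (1 + #more extreme) / (n_perm + 1)`. Two-sided by default.
#'
#' @param corr_a,corr_b square symmetric matrices of equal dimension with
#'   traits in the same order.
#' @param n_perm number of random permutations (>= 99).
#' @param two_sided compare `|r|` (default) rather than `r`.
#' @param seed optional integer seed.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(corr_a, corr_b, n_perm = 9999, two_sided = TRUE,
                        seed = NULL) {
  if (!all(dim(corr_a) == dim(corr_b))) stop("dimension mismatch")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(corr_a)
  obs <- stats::cor(corr_a[ut], corr_b[ut])
  f <- if (two_sided) abs else identity
  n <- nrow(corr_b)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    if (f(stats::cor(corr_a[ut], corr_b[p, p][ut])) >= f(obs) - 1e-12)
      hits <- hits + 1L
  }
  list(statistic = obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}
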