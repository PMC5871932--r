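#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal. Printed
#' correlation tables assembled from two sources are often slightly
#' indefinite; this repair is applied before any Cholesky-type construction.
#'
#' @param x symmetric matrix with unit diagonal.
#' @param eps smallest admitted eigenvalue.
#' @return A symmetric PSD matrix with unit diagonal.
#' @export
near_psd <- function(x, eps = 1e-8) {
  if (!isSymmetric(unname(x), tol = 1e-8)) stop("matrix must be symmetric")
  e <- eigen((x + t(x)) / 2, symmetric = TRUE)
  v <- pmax(e$values, eps)
  y <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(y))
  y <- y / tcrossprod(d)
  diag(y) <- 1
  dimnames(y) <- dimnames(x)
  (y + t(y)) / 2
}

#' Build a pleiotropic QTL architecture matching a target genetic correlation
#'
#' All traits share one set of QTL; per-locus effect vectors are drawn from a
#' multivariate normal with covariance equal to the (PSD-repaired) target
#' correlation matrix, which makes the expected genetic correlation matrix
#' equal the target. When a reference population is supplied the effect
#' matrix is re-whitened against the realized QTL genotypes so that the
#' genetic covariance in that population equals the target exactly, and
#' per-trait environmental standard deviations are set from the requested
#' heritabilities: `error_sd = trait_sd * sqrt(1 - h2)` with genetic standard
#' deviation `trait_sd * sqrt(h2)`.
#'
#' @param map a `gs_map`. QTL are taken from loci with `mode == "qtl"` when
#'   present, otherwise sampled from all loci.
#' @param target_corr trait x trait correlation matrix (dimnames give trait
#'   names; must be symmetric with unit diagonal).
#' @param h2 per-trait narrow-sense heritability in (0, 1], recycled.
#' @param n_qtl number of QTL shared by all traits.
#' @param trait_means,trait_sds phenotypic location and scale per trait,
#'   recycled.
#' @param ref_pop optional `gs_population` used to calibrate realized
#'   variances and correlations.
#' @param seed optional integer seed.
#' @return A list of class `gs_trait_architecture` with elements
#'   `trait_names`, `qtl_ids`, `effects` (n_qtl x traits), `error_sd`,
#'   `trait_means`, `center`, `h2`, `target_corr`.
#' @export
build_trait_architecture <- function(map, target_corr, h2 = 0.5, n_qtl = 100,
                                     trait_means = 0, trait_sds = 1,
                                     ref_pop = NULL, seed = NULL) {
  if (!is.matrix(target_corr) || nrow(target_corr) != ncol(target_corr))
    stop("target_corr must be a square matrix")
  if (n_qtl < 1) stop("n_qtl must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  traits <- rownames(target_corr)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(target_corr)))
  Tn <- length(traits)
  h2 <- rep_len(h2, Tn)
  if (any(h2 <= 0 | h2 > 1)) stop("heritabilities must lie in (0,1]")
  trait_means <- rep_len(trait_means, Tn)
  trait_sds <- rep_len(trait_sds, Tn)
  sigma <- near_psd(target_corr)

  cand <- map$marker_id[map$mode == "qtl"]
  if (length(cand) == 0L) cand <- map$marker_id
  if (length(cand) < n_qtl) stop("not enough candidate QTL loci on the map")
  qtl <- sample(cand, n_qtl)

  g_sd <- trait_sds * sqrt(h2)
  # right-multiplying by S gives effect covariance S'S = D chol(Sigma)' chol(Sigma) D
  scale_m <- chol(sigma) %*% diag(g_sd, Tn)
  raw <- matrix(stats::rnorm(n_qtl * Tn), n_qtl, Tn)
  if (!is.null(ref_pop)) {
    q <- dosage(ref_pop, qtl)
    center <- colMeans(q)
    g0 <- sweep(q, 2L, center) %*% raw
    cv <- stats::cov(g0)
    # exact whitening in the reference population; fall back to the HWE
    # approximation when the raw genetic covariance is rank-deficient
    ok <- tryCatch({ w <- solve(chol(cv)); TRUE }, error = function(e) FALSE)
    eff <- if (ok) raw %*% w %*% scale_m
           else raw %*% scale_m / sqrt(sum(2 * (center / 2) * (1 - center / 2)))
  } else {
    center <- rep(1, n_qtl)  # dosage mean at p = 0.5
    eff <- raw %*% scale_m / sqrt(n_qtl * 0.5)
  }
  colnames(eff) <- traits
  structure(list(trait_names = traits, qtl_ids = qtl, effects = eff,
                 error_sd = trait_sds * sqrt(1 - h2),
                 trait_means = stats::setNames(trait_means, traits),
                 center = center, h2 = stats::setNames(h2, traits),
                 target_corr = sigma),
            class = "gs_trait_architecture")
}

#' @export
print.gs_trait_architecture <- function(x, ...) {
  cat(sprintf("<gs_trait_architecture> %d traits, %d shared QTL\n",
              length(x$trait_names), length(x$qtl_ids)))
  invisible(x)
}

#' True genetic values of a population
#'
#' Sum of QTL effects over centered genotype dosages, plus the trait means.
#'
#' @param pop a `gs_population`.
#' @param arch a `gs_trait_architecture`.
#' @return numeric matrix individuals x traits.
#' @export
genetic_values <- function(pop, arch) {
  ids <- match(arch$qtl_ids, pop$map$marker_id)
  if (anyNA(ids)) stop("architecture QTL missing from the population's map")
  q <- sweep(dosage(pop)[, ids, drop = FALSE], 2L, arch$center)
  g <- q %*% arch$effects
  sweep(g, 2L, arch$trait_means, `+`)
}

#' Phenotype a population
#'
#' Phenotype = genetic value + independent normal error per trait
#' (`error_sd` from the architecture). With `error_sd = 0` the call is
#' deterministic.
#'
#' @param pop a `gs_population`.
#' @param arch a `gs_trait_architecture`.
#' @param seed optional integer seed.
#' @return numeric matrix individuals x traits with individual ids as
#'   rownames.
#' @export
phenotype <- function(pop, arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genetic_values(pop, arch)
  n <- nrow(g)
  e <- matrix(stats::rnorm(n * ncol(g), 0, rep(arch$error_sd, each = n)),
              n, ncol(g))
  y <- g + e
  dimnames(y) <- list(pop$id, arch$trait_names)
  y
}
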