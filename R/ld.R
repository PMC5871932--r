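# Two-locus haplotype bookkeeping. Haplotypes are indexed 1..4 as
# AB, Ab, aB, ab (allele "1" written as the capital).
HAP_A <- c(1L, 1L, 0L, 0L)
HAP_B <- c(1L, 0L, 1L, 0L)

# unordered haplotype-pair table: dosage at each locus and HWE multiplicity
hap_pairs <- local({
  idx <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  data.frame(i = idx[, 2L], j = idx[, 1L],
             gA = HAP_A[idx[, 2L]] + HAP_A[idx[, 1L]],
             gB = HAP_B[idx[, 2L]] + HAP_B[idx[, 1L]],
             mult = ifelse(idx[, 1L] == idx[, 2L], 1L, 2L))
})

observe_class <- function(g, mode) if (mode == "dominant") pmin(g, 1L) else g

r2_from_hapfreq <- function(p) {
  pa <- p[1L] + p[2L]
  pb <- p[1L] + p[3L]
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den <= 0) return(0)
  d <- p[1L] - pa * pb
  min(1, d * d / den)
}

#' Squared LD from phased haplotype counts
#'
#' `r2 = D^2 / (pA qA pB qB)` with `D = pAB - pA pB`, for fully phased data.
#' Used as the ground-truth estimator in simulations.
#'
#' @param counts length-4 vector of haplotype counts in order AB, Ab, aB, ab.
#' @return r-squared in [0, 1].
#' @export
r2_phased <- function(counts) {
  if (length(counts) != 4L) stop("need 4 haplotype counts (AB, Ab, aB, ab)")
  r2_from_hapfreq(counts / sum(counts))
}

#' Two-locus EM estimate of r-squared
#'
#' Estimates the four haplotype frequencies from unphased genotypes at two
#' loci, where each locus may be assayed codominantly (dosage 0/1/2) or
#' dominantly (presence 0/1, heterozygote indistinguishable from the
#' dominant homozygote). The E-step distributes each observed genotype class
#' over its compatible haplotype-pair configurations under Hardy-Weinberg
#' proportions; the M-step re-estimates the haplotype frequencies; iteration
#' stops when the largest absolute change in estimated frequencies drops
#' below `tol` (default 1e-4). Initialization is at linkage equilibrium of
#' the marginal allele-frequency estimates. For two codominant columns the
#' procedure is the standard double-heterozygote EM and matches
#' [r2_direct()].
#'
#' @param geno_i,geno_j integer genotype vectors (missing allowed; pairs with
#'   a missing value are dropped).
#' @param mode_i,mode_j `"codominant"` or `"dominant"`.
#' @param tol convergence tolerance on haplotype-frequency change.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param track_loglik record the observed-data log-likelihood at every
#'   iteration (asserted non-decreasing in the test suite).
#' @return list with `r2`, `hap_freq`, `method = "em"`, `em_iterations`,
#'   `converged`, `loglik`, and optionally `loglik_path`.
#' @export
r2_em <- function(geno_i, geno_j, mode_i = "codominant",
                  mode_j = "codominant", tol = 1e-4, max_iter = 1000,
                  track_loglik = FALSE) {
  ok <- !is.na(geno_i) & !is.na(geno_j)
  gi <- as.integer(geno_i[ok])
  gj <- as.integer(geno_j[ok])
  n <- length(gi)
  if (n < 2L) stop("too few complete observations")
  if (length(unique(gi)) < 2L || length(unique(gj)) < 2L)
    stop("monomorphic column")

  cls_a <- observe_class(hap_pairs$gA, mode_i)
  cls_b <- observe_class(hap_pairs$gB, mode_j)
  pair_class <- paste(cls_a, cls_b)
  obs_class <- paste(observe_class(gi, mode_i), observe_class(gj, mode_j))
  counts <- table(obs_class)
  classes <- names(counts)
  nc <- as.numeric(counts)
  # membership (pairs x classes) and haplotype-increment (pairs x 4) matrices
  memb <- outer(pair_class, classes, `==`) + 0
  hinc <- matrix(0, nrow(hap_pairs), 4L)
  for (t in seq_len(nrow(hap_pairs))) {
    hinc[t, hap_pairs$i[t]] <- hinc[t, hap_pairs$i[t]] + 1
    hinc[t, hap_pairs$j[t]] <- hinc[t, hap_pairs$j[t]] + 1
  }

  # allele-frequency moment estimates for the LE start
  pA <- if (mode_i == "dominant") 1 - sqrt(max(1e-9, mean(gi == 0))) else mean(gi) / 2
  pB <- if (mode_j == "dominant") 1 - sqrt(max(1e-9, mean(gj == 0))) else mean(gj) / 2
  pA <- min(max(pA, 1e-6), 1 - 1e-6)
  pB <- min(max(pB, 1e-6), 1 - 1e-6)
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))

  llp <- if (track_loglik) numeric(max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pw <- p[hap_pairs$i] * p[hap_pairs$j] * hap_pairs$mult
    prob <- pmax(drop(crossprod(memb, pw)), 1e-300)  # class probabilities
    if (track_loglik) llp[iter] <- sum(nc * log(prob))
    # posterior weight of each pair within its class, scaled by class counts
    wt <- pw * drop(memb %*% (nc / prob))
    p_new <- drop(crossprod(hinc, wt)) / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  out <- list(r2 = r2_from_hapfreq(p), hap_freq = p, method = "em",
              em_iterations = iter, converged = converged,
              loglik = ld_obs_loglik(gi, gj, mode_i, mode_j, p))
  if (track_loglik) out$loglik_path <- llp[seq_len(iter)]
  out
}

#' Observed-data log-likelihood of two-locus genotype data
#'
#' Multinomial log-likelihood of the observed genotype classes given
#' haplotype frequencies, under Hardy-Weinberg random union of gametes.
#' Shared by the EM estimator and the grid-search oracle in the tests.
#'
#' @param geno_i,geno_j genotype vectors (no missing).
#' @param mode_i,mode_j assay modes.
#' @param p length-4 haplotype frequency vector (AB, Ab, aB, ab).
#' @return scalar log-likelihood.
#' @export
ld_obs_loglik <- function(geno_i, geno_j, mode_i, mode_j, p) {
  pw <- p[hap_pairs$i] * p[hap_pairs$j] * hap_pairs$mult
  cls <- paste(observe_class(hap_pairs$gA, mode_i),
               observe_class(hap_pairs$gB, mode_j))
  prob <- tapply(pw, cls, sum)
  obs <- paste(observe_class(as.integer(geno_i), mode_i),
               observe_class(as.integer(geno_j), mode_j))
  sum(log(pmax(prob[obs], 1e-300)))
}

#' Direct r-squared between two codominant marker columns
#'
#' The standard two-locus estimator: haplotype frequencies via the
#' double-heterozygote EM (closed-form likelihood for codominant data), then
#' `r2 = D^2 / (pA qA pB qB)`. At complete phase certainty it equals the
#' squared correlation of allele counts.
#'
#' @param geno_i,geno_j codominant genotype vectors (0/1/2).
#' @return r-squared in [0, 1].
#' @export
r2_direct <- function(geno_i, geno_j) {
  if (any(geno_i > 2 | geno_j > 2, na.rm = TRUE)) stop("codominant input expected")
  r2_em(geno_i, geno_j, "codominant", "codominant", tol = 1e-8,
        max_iter = 5000)$r2
}

#' EM r-squared when at least one marker is dominant
#'
#' Thin wrapper of [r2_em()] matching the dominant-marker estimation route
#' (stopping tolerance 1e-4 on the haplotype-frequency change).
#'
#' @inheritParams r2_em
#' @export
r2_em_dominant <- function(geno_i, geno_j, mode_i = "dominant",
                           mode_j = "dominant", tol = 1e-4, max_iter = 1000) {
  if (mode_i != "dominant" && mode_j != "dominant")
    stop("at least one column must be dominant")
  r2_em(geno_i, geno_j, mode_i, mode_j, tol = tol, max_iter = max_iter)
}

#' Pairwise LD within linkage groups up to a maximum map distance
#'
#' Emits every same-linkage-group marker pair with map distance at most
#' `max_distance`. Pairs of codominant markers use the direct estimator;
#' pairs involving a dominant marker use the EM estimator. Monomorphic
#' markers are skipped.
#'
#' @param genotypes matrix from [observe_markers()] (or any genotype matrix
#'   with column names and a `"modes"` attribute).
#' @param map a `gs_map` covering the genotyped markers.
#' @param max_distance largest map distance in cM (default 50).
#' @param max_pairs optional cap: a random subsample of eligible pairs (for
#'   large panels); `NULL` keeps all.
#' @return data.frame with columns `marker_i`, `marker_j`, `distance`, `r2`,
#'   `method`, `em_iterations`, `maf_i`, `maf_j`.
#' @export
ld_decay <- function(genotypes, map, max_distance = 50, max_pairs = NULL) {
  ids <- colnames(genotypes)
  mi <- match(ids, map$marker_id)
  if (anyNA(mi)) stop("map does not cover all genotyped markers")
  modes <- marker_modes(genotypes)
  lg <- map$linkage_group[mi]
  pos <- map$position_cM[mi]
  poly <- vapply(seq_along(ids), function(j)
    length(unique(genotypes[!is.na(genotypes[, j]), j])) > 1L, logical(1))

  pairs <- do.call(rbind, lapply(unique(lg), function(g) {
    w <- which(lg == g & poly)
    if (length(w) < 2L) return(NULL)
    cmb <- utils::combn(w, 2L)
    d <- abs(pos[cmb[1L, ]] - pos[cmb[2L, ]])
    keep <- d <= max_distance
    if (!any(keep)) return(NULL)
    cbind(i = cmb[1L, keep], j = cmb[2L, keep], d = d[keep])
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no eligible marker pairs")
  if (!is.null(max_pairs) && nrow(pairs) > max_pairs)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]

  maf <- function(j) {
    x <- genotypes[!is.na(genotypes[, j]), j]
    p <- if (modes[j] == "dominant") 1 - sqrt(max(0, mean(x == 0))) else mean(x) / 2
    min(p, 1 - p)
  }
  mafs <- vapply(seq_along(ids), maf, numeric(1))

  np <- nrow(pairs)
  r2v <- numeric(np)
  itv <- rep(NA_integer_, np)
  em <- logical(np)
  for (r in seq_len(np)) {
    i <- pairs[r, "i"]; j <- pairs[r, "j"]
    em[r] <- modes[i] == "dominant" || modes[j] == "dominant"
    if (em[r]) {
      est <- r2_em(genotypes[, i], genotypes[, j], modes[i], modes[j])
      r2v[r] <- est$r2
      itv[r] <- est$em_iterations
    } else {
      r2v[r] <- r2_direct(genotypes[, i], genotypes[, j])
    }
  }
  data.frame(marker_i = ids[pairs[, "i"]], marker_j = ids[pairs[, "j"]],
             distance = pairs[, "d"], r2 = r2v,
             method = ifelse(em, "em", "direct"), em_iterations = itv,
             maf_i = mafs[pairs[, "i"]], maf_j = mafs[pairs[, "j"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hill-Weir drift expectation of r-squared
#'
#' `E[r2]` as a function of `C = 4 Ne c` for a sample of `n` diploid
#' individuals. Variant `"hill_weir"` (default) is the drift approximation
#' times the finite-sample bracket; variant `"drift_floor"` is the drift
#' approximation plus an additive `1/n` sampling floor.
#'
#' @param C scaled recombination parameter `4 Ne c` (vectorized).
#' @param n sample size (diploid individuals); `Inf` gives the pure drift
#'   term.
#' @param variant formula variant.
#' @return numeric vector, non-increasing in `C`.
#' @export
hill_weir_expected_r2 <- function(C, n = Inf,
                                  variant = c("hill_weir", "drift_floor")) {
  variant <- match.arg(variant)
  base <- (10 + C) / ((2 + C) * (11 + C))
  if (!is.finite(n)) return(base)
  if (variant == "hill_weir")
    base * (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
  else base + 1 / n
}

#' LD-based effective population size
#'
#' Fits `Ne` by least squares of observed pairwise r-squared against the
#' Hill-Weir expectation `E[r2](C)` with `C = 4 Ne c`, the recombination
#' fraction `c` obtained from map distance via the Haldane map function.
#' By default observations are averaged in 1-cM distance bins (fitted at bin
#' midpoints); pairs with a minor allele frequency below `min_maf` at either
#' marker are excluded. A fit at the search bounds is flagged.
#'
#' The drift expectation holds at drift-recombination equilibrium, which a
#' population reaches after roughly `1/(2c)` generations; when the number of
#' generations `t` since the population's founding is known, restricting the
#' fit to `c >= 1/(2t)` (via `min_distance`) avoids the upward bias from
#' tightly linked, not-yet-equilibrated pairs. Binned fits weight each bin
#' by its pair count.
#'
#' @param pairs data.frame from [ld_decay()].
#' @param sample_size number of genotyped individuals behind the r2 values.
#' @param min_maf MAF exclusion threshold (default 0.05).
#' @param min_distance smallest map distance (cM) admitted to the fit.
#' @param bin_width cM bin width; `NULL` fits unbinned pairs.
#' @param variant passed to [hill_weir_expected_r2()].
#' @param ne_bounds search interval for Ne.
#' @return list of class `gs_ne` with `ne`, `curve` (data.frame distance /
#'   observed / expected), `sample_size`, `n_pairs`, `variant`,
#'   `bound_hit`.
#' @export
fit_ne <- function(pairs, sample_size, min_maf = 0.05, min_distance = 0,
                   bin_width = 1, variant = c("hill_weir", "drift_floor"),
                   ne_bounds = c(1, 1e5)) {
  variant <- match.arg(variant)
  keep <- pairs$maf_i >= min_maf & pairs$maf_j >= min_maf &
    pairs$distance >= min_distance
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 20L || length(unique(round(pairs$distance, 6))) < 2L)
    stop("need >= 20 pairs spanning >= 2 distances after filtering")
  if (is.null(bin_width)) {
    ord <- order(pairs$distance)
    d <- pairs$distance[ord]
    r2 <- pairs$r2[ord]
    wts <- rep(1, length(d))
  } else {
    bin <- floor(pairs$distance / bin_width)
    bins <- sort(unique(bin))
    r2 <- vapply(bins, function(b) mean(pairs$r2[bin == b]), numeric(1))
    wts <- vapply(bins, function(b) sum(bin == b), numeric(1))
    d <- (bins + 0.5) * bin_width
  }
  cfrac <- pmax(haldane_c(d), 1e-6)
  sse <- function(log_ne) {
    e <- hill_weir_expected_r2(4 * exp(log_ne) * cfrac, sample_size, variant)
    sum(wts * (r2 - e)^2)
  }
  opt <- stats::optimize(sse, interval = log(ne_bounds), tol = 1e-10)
  ne <- exp(opt$minimum)
  bound_hit <- ne <= ne_bounds[1L] * 1.001 || ne >= ne_bounds[2L] * 0.999
  if (bound_hit) warning("Ne estimate at search bound; fit is degenerate")
  structure(list(ne = ne,
                 curve = data.frame(distance = d, observed = r2,
                                    expected = hill_weir_expected_r2(
                                      4 * ne * cfrac, sample_size, variant)),
                 sample_size = sample_size, n_pairs = nrow(pairs),
                 variant = variant, bound_hit = bound_hit),
            class = "gs_ne")
}

#' @export
print.gs_ne <- function(x, ...) {
  cat(sprintf("<gs_ne> Ne = %.2f from %d pairs (n = %d, %s)\n",
              x$ne, x$n_pairs, x$sample_size, x$variant))
  invisible(x)
}
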