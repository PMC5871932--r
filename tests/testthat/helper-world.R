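# Shared fixtures and independent oracles. Everything is generated in code;
# seeds are set per test.

tiny_map <- function(n_loci = 60, n_lg = 2, len = 100, dominant = 0) {
  lg <- sort(rep_len(seq_len(n_lg), n_loci))
  pos <- stats::ave(seq_len(n_loci), lg,
                    FUN = function(i) seq(0, len, length.out = length(i)))
  mode <- rep("codominant", n_loci)
  if (dominant > 0) mode[seq_len(round(dominant * n_loci))] <- "dominant"
  genetic_map(sprintf("m%03d", seq_len(n_loci)), lg, pos, mode)
}

rand_geno <- function(n, m, p = 0.4, prefix = "M") {
  matrix(rbinom(n * m, 2L, p), n, m,
         dimnames = list(sprintf("i%03d", seq_len(n)),
                         sprintf("%s%04d", prefix, seq_len(m))))
}

# draw unphased genotypes at two loci from known haplotype frequencies
draw_two_locus <- function(n, hapfreq) {
  A <- c(1L, 1L, 0L, 0L)
  B <- c(1L, 0L, 1L, 0L)
  h <- sample.int(4L, 2L * n, replace = TRUE, prob = hapfreq)
  h1 <- h[seq_len(n)]
  h2 <- h[n + seq_len(n)]
  list(gi = A[h1] + A[h2], gj = B[h1] + B[h2], h1 = h1, h2 = h2)
}

# Independent exhaustive-search oracle for the two-locus likelihood:
# coarse 0.01-step simplex grid, then a 0.0005-step refinement around the
# coarse optimum. Enumerates ordered haplotype pairs from scratch.
grid_oracle_loglik <- function(gi, gj, mode_i, mode_j, step = 0.01) {
  A <- c(1, 1, 0, 0)
  B <- c(1, 0, 1, 0)
  obs <- function(g, mode) if (mode == "dominant") pmin(g, 1) else g
  pr <- expand.grid(i = 1:4, j = 1:4)
  pr$cls <- paste(obs(A[pr$i] + A[pr$j], mode_i),
                  obs(B[pr$i] + B[pr$j], mode_j))
  cnt <- table(paste(obs(gi, mode_i), obs(gj, mode_j)))
  ll_at <- function(P) {
    ll <- rep(0, nrow(P))
    for (cl in names(cnt)) {
      prob <- rep(0, nrow(P))
      for (r in which(pr$cls == cl)) prob <- prob + P[, pr$i[r]] * P[, pr$j[r]]
      ll <- ll + cnt[[cl]] * log(pmax(prob, 1e-300))
    }
    ll
  }
  sq <- seq(0, 1, by = step)
  G <- as.matrix(expand.grid(sq, sq, sq))
  G <- G[rowSums(G) <= 1 + 1e-9, ]
  P <- cbind(G, pmax(0, 1 - rowSums(G)))
  ll <- ll_at(P)
  ctr <- P[which.max(ll), 1:3]
  sq2 <- seq(-step, step, by = step / 20)
  G2 <- as.matrix(expand.grid(ctr[1] + sq2, ctr[2] + sq2, ctr[3] + sq2))
  G2 <- G2[apply(G2 >= 0, 1, all) & rowSums(G2) <= 1, , drop = FALSE]
  P2 <- cbind(G2, pmax(0, 1 - rowSums(G2)))
  list(coarse = max(ll), refined = max(c(ll, ll_at(P2))))
}

# Independent ridge-regression-on-markers oracle at a given variance ratio:
# a = (Z'Z + delta * c * I)^-1 Z' (y - mu)
rrblup_oracle <- function(genotypes, y, delta, mu, trace_scale) {
  z <- scale(gsmass::impute_genotypes(genotypes), center = TRUE, scale = FALSE)
  keep <- apply(z, 2L, function(x) stats::sd(x) > 0)
  z <- z[, keep, drop = FALSE]
  drop(solve(crossprod(z) + delta * trace_scale * diag(ncol(z)),
             crossprod(z, y - mu)))
}

# Literal per-fold PCR LOOCV, written independently of fit_pcr
pcr_loocv_oracle <- function(x, y, k) {
  press <- vapply(seq_len(nrow(x)), function(i) {
    xt <- x[-i, , drop = FALSE]
    pc <- stats::prcomp(xt, center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(k), drop = FALSE]
    fit <- stats::lm(y[-i] ~ sc)
    newsc <- (x[i, ] - pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE]
    (y[i] - (coef(fit)[1L] + sum(coef(fit)[-1L] * newsc)))^2
  }, numeric(1))
  sqrt(mean(press))
}

# a small random correlation matrix from random data
rand_corr <- function(p, n = 20) stats::cor(matrix(stats::rnorm(n * p), n, p))
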