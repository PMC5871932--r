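test_that("founder simulation is reproducible, validated, and in linkage equilibrium", {
  map <- tiny_map(40, 2)
  a <- simulate_founders(30, map, seed = 11)
  b <- simulate_founders(30, map, seed = 11)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$hap2, b$hap2)
  expect_equal(ncol(a$hap1), nrow(map))

  expect_error(simulate_founders(1, map), "at least 2")
  expect_error(simulate_founders(10, map[0, ]), "empty map")
  expect_error(simulate_founders(10, map, allele_freq = rep(0, 40)), "in \\(0,1\\)")

  # two individuals, one marker: haplotype arrays of length 1 per copy
  one <- genetic_map("m1", 1, 0)
  p2 <- simulate_founders(2, one, allele_freq = 0.5, seed = 1)
  expect_equal(dim(p2$hap1), c(2L, 1L))

  # unlinked-pair r2 ~ 1/(2n): mean over cross-linkage-group pairs
  set.seed(42)
  big <- simulate_founders(200, tiny_map(60, 2), allele_freq = c(0.1, 0.9))
  d <- dosage(big)
  lg <- big$map$linkage_group
  pairs <- expand.grid(i = which(lg == 1), j = which(lg == 2))
  pairs <- pairs[sample.int(nrow(pairs), 250), ]
  r2 <- mapply(function(i, j) stats::cor(d[, i], d[, j])^2, pairs$i, pairs$j)
  expect_lt(mean(r2), 3 / (2 * 200))
})

test_that("random mating honours self-incompatibility and the pedigree", {
  set.seed(7)
  map <- tiny_map(30, 2)
  pop <- simulate_founders(40, map)
  off <- random_mate(pop, 192, self_incompatible = TRUE)
  expect_true(all(off$dam != off$sire))
  expect_true(all(off$dam %in% pop$id) && all(off$sire %in% pop$id))
  expect_equal(pop_size(off), 192L)
  expect_error(random_mate(pop, 5, dams = pop$id[1], sires = pop$id[1]),
               "2 distinct parents")

  # identical fully homozygous parents -> clonal offspring
  hom <- new_population(matrix(1L, 2, 30), matrix(1L, 2, 30), c("A", "B"),
                        map = map)
  off2 <- random_mate(hom, 10)
  expect_true(all(off2$hap1 == 1L) && all(off2$hap2 == 1L))
})

test_that("recombinant fraction matches the Haldane map function", {
  # dam heterozygous in coupling at two markers 50 cM apart; sire homozygous
  map2 <- genetic_map(c("a", "b"), c(1, 1), c(0, 50))
  pop <- new_population(matrix(c(1L, 0L, 1L, 0L), 2, 2),
                        matrix(0L, 2, 2), c("P1", "P2"), map = map2)
  set.seed(123)
  off <- random_mate(pop, 10000, dams = "P1", sires = "P2")
  gam <- off$hap1  # the maternal gamete
  rec_frac <- mean(gam[, 1] != gam[, 2])
  c_expect <- haldane_c(50)  # (1 - exp(-1))/2 ~ 0.316
  expect_lt(abs(rec_frac - c_expect), 3.5 * sqrt(c_expect * (1 - c_expect) / 10000))
  # same linkage group at 0 distance would never recombine; unlinked ~ 1/2
})

test_that("bottleneck inflates linked LD and reduces LD-based Ne", {
  set.seed(99)
  map <- tiny_map(120, 4, 100)
  fnd <- simulate_founders(200, map)
  expect_error(bottleneck_then_expand(fnd, 500, 10), "exceeds")

  linked_r2 <- function(pop) {
    d <- dosage(pop)
    lg <- pop$map$linkage_group
    pos <- pop$map$position_cM
    out <- c()
    for (g in unique(lg)) {
      w <- which(lg == g)
      for (t in seq_len(length(w) - 1L)) {
        i <- w[t]; j <- w[t + 1L]
        if (stats::sd(d[, i]) > 0 && stats::sd(d[, j]) > 0)
          out <- c(out, stats::cor(d[, i], d[, j])^2)
      }
    }
    mean(out)
  }
  base <- linked_r2(fnd)
  k2 <- bottleneck_then_expand(fnd, 2, 192)
  expect_gt(linked_r2(k2), base)

  k40 <- bottleneck_then_expand(fnd, 40, 192)
  g40 <- observe_markers(k40)
  gf <- observe_markers(fnd)
  ne40 <- fit_ne(ld_decay(g40, map, 50), sample_size = 192)
  nef <- suppressWarnings(fit_ne(ld_decay(gf, map, 50), sample_size = 200))
  expect_lt(ne40$ne, nef$ne)

  # k = population size: no bottleneck beyond one round of mating
  same <- bottleneck_then_expand(fnd, 200, 50)
  expect_equal(pop_size(same), 50L)
})

test_that("trait architecture hits target correlations and heritabilities", {
  set.seed(21)
  map <- tiny_map(300, 4)
  ref <- simulate_founders(2000, map)

  # independence case
  id8 <- diag(8)
  dimnames(id8) <- list(paste0("t", 1:8), paste0("t", 1:8))
  arch0 <- build_trait_architecture(map, id8, h2 = 0.5, n_qtl = 100,
                                    ref_pop = ref)
  g0 <- genetic_values(ref, arch0)
  expect_true(all(abs(stats::cor(g0)[upper.tri(id8)]) < 0.1))

  # published field structure, exact in the reference population
  tc <- near_psd(field_trait_correlations())
  arch <- buckwheat_architecture(map, ref_pop = ref, h2 = 0.5, n_qtl = 100)
  gr <- stats::cor(genetic_values(ref, arch))
  expect_lt(max(abs(gr - tc)), 1e-8)
  # approximate in an independent descendant population
  off <- random_mate(ref, 2000, seed = 22)
  go <- stats::cor(genetic_values(off, arch))
  expect_lt(max(abs(go - tc)), 0.15)

  # realized heritability: var(g) / var(y) near h2 in the reference pop
  y <- phenotype(ref, arch, seed = 3)
  g <- genetic_values(ref, arch)
  h2_real <- diag(stats::var(g)) / diag(stats::var(y))
  expect_true(all(abs(h2_real - 0.5) < 0.07))

  expect_error(build_trait_architecture(map, matrix(1, 2, 3)), "square")
  expect_error(build_trait_architecture(map, id8, h2 = 1.5), "\\(0,1\\]")
})

test_that("phenotyping is genetic value plus independent noise", {
  set.seed(5)
  map <- tiny_map(100, 2)
  pop <- simulate_founders(300, map)
  id3 <- diag(3); dimnames(id3) <- list(letters[1:3], letters[1:3])

  # h2 = 1: phenotype equals genetic value, replicate calls identical
  arch1 <- build_trait_architecture(map, id3, h2 = 1, n_qtl = 40, ref_pop = pop)
  expect_identical(phenotype(pop, arch1, seed = 1), phenotype(pop, arch1, seed = 2))
  expect_equal(unname(phenotype(pop, arch1)), unname(genetic_values(pop, arch1)))

  # clone pairs: phenotypic correlation ~ h2
  arch <- build_trait_architecture(map, id3, h2 = 0.5, n_qtl = 40, ref_pop = pop)
  clone <- new_population(rbind(pop$hap1, pop$hap1), rbind(pop$hap2, pop$hap2),
                          c(pop$id, paste0(pop$id, "_c")), map = map)
  y <- phenotype(clone, arch, seed = 8)
  r_clone <- stats::cor(y[seq_len(300), 1], y[300 + seq_len(300), 1])
  expect_lt(abs(r_clone - 0.5), 0.12)

  bad <- arch
  bad$qtl_ids[1] <- "nonexistent"
  expect_error(phenotype(pop, bad), "missing from")
})

test_that("marker observation codes dominant and codominant assays correctly", {
  map <- tiny_map(40, 2, dominant = 0.5)
  set.seed(31)
  pop <- simulate_founders(500, map, allele_freq = rep(0.4, 40))
  g <- observe_markers(pop)
  modes <- marker_modes(g)
  expect_true(all(g[, modes == "dominant"] %in% 0:1))
  expect_true(all(g[, modes == "codominant"] %in% 0:2))

  # dominant coding: aa -> 0, Aa/AA -> 1
  d <- dosage(pop)[, map$mode == "dominant", drop = FALSE]
  expect_equal(unname(g[, modes == "dominant"]), unname((d > 0) + 0L))

  # Hardy-Weinberg arithmetic: fraction of 1s ~ 1 - (1-p)^2 at p = 0.4
  frac1 <- mean(g[, modes == "dominant"])
  expect_lt(abs(frac1 - (1 - 0.6^2)), 0.02)

  # codominant-only panel
  g0 <- observe_markers(pop, markers = map$marker_id[map$mode == "codominant"])
  expect_true(all(g0 %in% 0:2))

  # missingness and imputation
  gm <- observe_markers(pop, missing_rate = 0.2, seed = 4)
  expect_gt(mean(is.na(gm)), 0.15)
  expect_false(anyNA(impute_genotypes(gm)))
  expect_error(observe_markers(pop, missing_rate = 2), "missing_rate")
})

test_that("heterozygosity decays at 1 - 1/(2Ne) per generation of drift", {
  set.seed(17)
  map <- tiny_map(40, 1)
  ratios <- replicate(200, {
    pop <- simulate_founders(20, map, allele_freq = c(0.3, 0.7))
    off <- random_mate(pop, 20)
    expected_heterozygosity(off) / expected_heterozygosity(pop)
  })
  # census 20, random pairing without selfing: Ne ~ N (+1/2)
  expect_lt(abs(mean(ratios) - (1 - 1 / (2 * 20))), 0.01)
})
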