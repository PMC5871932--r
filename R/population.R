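#' Diploid populations with phased haplotypes
#'
#' A `gs_population` stores two haplotype matrices (individuals x loci,
#' binary alleles), individual identifiers, pedigree links and a generation
#' label. All simulation operations ([simulate_founders()], [random_mate()],
#' [bottleneck_then_expand()]) return this class.
#'
#' @param hap1,hap2 integer matrices of 0/1 alleles, one row per individual,
#'   one column per map locus.
#' @param id character vector of individual identifiers.
#' @param dam,sire character vectors of parent identifiers (`NA` for
#'   founders).
#' @param generation single generation label.
#' @param map the `gs_map` the haplotypes are indexed by.
#' @return A list of class `gs_population`.
#' @export
new_population <- function(hap1, hap2, id, dam = NA_character_,
                           sire = NA_character_, generation = "founder",
                           map = NULL) {
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            all(dim(hap1) == dim(hap2)), nrow(hap1) == length(id))
  if (!is.null(map) && ncol(hap1) != nrow(map))
    stop("haplotype length must equal map locus count")
  if (anyDuplicated(id)) stop("individual ids must be unique")
  dam <- rep_len(as.character(dam), length(id))
  sire <- rep_len(as.character(sire), length(id))
  self <- !is.na(dam) & !is.na(sire) & dam == sire
  if (any(self)) stop("individual with dam_id == sire_id (selfing)")
  own <- (!is.na(dam) & dam == id) | (!is.na(sire) & sire == id)
  if (any(own)) stop("individual recorded as its own parent")
  structure(list(hap1 = hap1, hap2 = hap2, id = as.character(id),
                 dam = dam, sire = sire, generation = generation, map = map),
            class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  cat(sprintf("<gs_population> %d individuals x %d loci, generation '%s'\n",
              nrow(x$hap1), ncol(x$hap1), x$generation))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `gs_population`.
#' @export
pop_size <- function(pop) nrow(pop$hap1)

#' Allele dosage matrix (individuals x loci)
#'
#' Counts of the "1" allele per individual and locus, in map order.
#'
#' @param pop a `gs_population`.
#' @param loci optional locus index or marker_id subset.
#' @return integer matrix with individual ids as rownames and marker ids as
#'   colnames.
#' @export
dosage <- function(pop, loci = NULL) {
  d <- pop$hap1 + pop$hap2
  rownames(d) <- pop$id
  if (!is.null(pop$map)) colnames(d) <- pop$map$marker_id
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  d
}

#' Simulate unrelated founders in linkage equilibrium
#'
#' Each allele is drawn independently per locus and chromosome copy, so
#' founders carry no linkage disequilibrium; LD is introduced downstream by
#' drift (see [bottleneck_then_expand()]).
#'
#' @param n_individuals number of founders (>= 2).
#' @param map a `gs_map`.
#' @param allele_freq per-locus frequencies of the "1" allele in (0, 1);
#'   either a vector of length `nrow(map)` or a range `c(lo, hi)` sampled
#'   uniformly per locus.
#' @param seed integer seed; the operation is reproducible given the seed.
#' @return A `gs_population` labelled `"founder"`.
#' @export
simulate_founders <- function(n_individuals, map, allele_freq = c(0.1, 0.9),
                              seed = NULL) {
  if (n_individuals < 2) stop("need at least 2 founders")
  if (is.null(map) || nrow(map) == 0L) stop("empty map")
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(map)
  p <- if (length(allele_freq) == 2L && L != 2L)
    stats::runif(L, allele_freq[1], allele_freq[2]) else rep_len(allele_freq, L)
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must be in (0,1)")
  draw <- function() matrix(stats::rbinom(n_individuals * L, 1L, rep(p, each = n_individuals)),
                            n_individuals, L)
  new_population(draw(), draw(), sprintf("F%04d", seq_len(n_individuals)),
                 generation = "founder", map = map)
}

# One gamete per requested parent. Crossovers are a Poisson process on map
# length per linkage group (Haldane, no interference); the starting chromatid
# is uniform. Returns a matrix n_gametes x L.
make_gametes <- function(pop, parent_idx, blocks) {
  n <- length(parent_idx)
  L <- ncol(pop$hap1)
  out <- matrix(0L, n, L)
  for (b in blocks) {
    pos <- b$pos
    m <- length(pos)
    for (g in seq_len(n)) {
      k <- stats::rpois(1L, b$len / 100)
      phase <- if (k > 0L) {
        xo <- stats::runif(k, 0, b$len)
        (findInterval(pos, sort(xo)) + stats::rbinom(1L, 1L, 0.5)) %% 2L
      } else rep(stats::rbinom(1L, 1L, 0.5), m)
      i <- parent_idx[g]
      h1 <- pop$hap1[i, b$idx]
      out[g, b$idx] <- ifelse(phase == 0L, h1, pop$hap2[i, b$idx])
    }
  }
  out
}

#' Random mating with optional self-incompatibility
#'
#' Each offspring draws its dam uniformly from `dams` and its sire uniformly
#' from `sires`, excluding the dam when `self_incompatible` (the complete
#' outcrossing enforced by the S-locus in buckwheat). Gametes are formed by
#' Haldane-model recombination over the population's map and the pedigree is
#' recorded.
#'
#' @param pop a `gs_population`.
#' @param n_offspring number of offspring to produce.
#' @param self_incompatible if `TRUE` (default) no offspring may have
#'   `dam == sire`.
#' @param dams,sires identifiers of candidate seed and pollen parents;
#'   default all individuals.
#' @param generation label for the offspring generation.
#' @param seed optional integer seed.
#' @return A `gs_population` of the offspring.
#' @export
random_mate <- function(pop, n_offspring, self_incompatible = TRUE,
                        dams = pop$id, sires = pop$id,
                        generation = "offspring", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dam_idx <- match(dams, pop$id)
  sire_idx <- match(sires, pop$id)
  if (anyNA(dam_idx) || anyNA(sire_idx)) stop("unknown parent id")
  if (self_incompatible &&
      length(unique(c(dams, sires))) < 2L)
    stop("self-incompatible mating needs at least 2 distinct parents")
  d <- sample(dam_idx, n_offspring, replace = TRUE)
  s <- sample(sire_idx, n_offspring, replace = TRUE)
  if (self_incompatible) {
    for (i in which(d == s)) {
      repeat {
        s[i] <- sample(sire_idx, 1L)
        if (s[i] != d[i]) break
      }
    }
  }
  blocks <- map_blocks(pop$map)
  ids <- sprintf("%s_%04d", generation, seq_len(n_offspring))
  while (any(ids %in% pop$id)) ids <- paste0(ids, "x")  # avoid id collisions
  new_population(make_gametes(pop, d, blocks), make_gametes(pop, s, blocks),
                 ids,
                 dam = pop$id[d], sire = pop$id[s],
                 generation = generation, map = pop$map)
}

#' Bottleneck a population and expand by one round of random mating
#'
#' Samples `k` individuals without replacement and random-mates them (self-
#' incompatibly) to `n_out` offspring. A small `k` inflates linkage
#' disequilibrium between linked markers relative to the source population —
#' the route by which an outcrossing population with near-zero LD is given
#' enough LD for genomic prediction.
#'
#' @param pop a `gs_population`.
#' @param k bottleneck size (default 40, the number of plants random-mated
#'   to found the breeding population).
#' @param n_out offspring population size (default 192).
#' @param generation label for the output.
#' @param seed optional integer seed.
#' @return A `gs_population`.
#' @export
bottleneck_then_expand <- function(pop, k = 40, n_out = 192,
                                   generation = "initial", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k > pop_size(pop)) stop("bottleneck size exceeds population size")
  keep <- sample(pop$id, k)
  random_mate(pop, n_out, self_incompatible = TRUE, dams = keep, sires = keep,
              generation = generation)
}

#' Mean expected heterozygosity over loci
#'
#' 2p(1-p) averaged over loci, with p the sample allele frequency. Used to
#' check drift calibration (decay by 1 - 1/(2Ne) per generation).
#'
#' @param pop a `gs_population`.
#' @export
expected_heterozygosity <- function(pop) {
  p <- colMeans(pop$hap1 + pop$hap2) / 2
  mean(2 * p * (1 - p))
}
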