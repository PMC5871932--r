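extdata <- function(name) {
  system.file("extdata", name, package = "gsmass", mustWork = TRUE)
}

#' Bundled buckwheat reference inputs
#'
#' The package ships the published summary tables of a 3-year buckwheat
#' GS/PS field experiment as plain CSV: the selection-index weights
#' (principal-component-regression coefficients on the original trait
#' scale), among-trait correlation matrices from the index-building field
#' trial and from the initial breeding population, the 2014 common-garden
#' evaluation summary (population x trait means, SDs, sample sizes), and
#' genotyping panel counts per cycle. These are the inputs for the
#' arithmetic reproduced in the acceptance suite and the calibration targets
#' of the synthetic generator.
#'
#' @return `buckwheat_index_model()` a `gs_index_model`;
#'   `field_trait_correlations()` / `initial_trait_correlations()` named
#'   correlation matrices; `evaluation_summary_2014()` and
#'   `genotyping_summary()` data frames.
#' @name buckwheat_reference
NULL

#' @rdname buckwheat_reference
#' @export
buckwheat_index_model <- function() {
  df <- utils::read.csv(extdata("index_coefficients.csv"))
  index_model(stats::setNames(df$coefficient, df$trait))
}

read_corr <- function(file) {
  df <- utils::read.csv(extdata(file), check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$trait
  m
}

#' @rdname buckwheat_reference
#' @export
field_trait_correlations <- function() read_corr("trait_correlations_field.csv")

#' @rdname buckwheat_reference
#' @export
initial_trait_correlations <- function() read_corr("trait_correlations_initial.csv")

#' @rdname buckwheat_reference
#' @export
evaluation_summary_2014 <- function() {
  utils::read.csv(extdata("field_evaluation_2014.csv"))
}

#' @rdname buckwheat_reference
#' @export
genotyping_summary <- function() {
  utils::read.csv(extdata("genotyping_summary.csv"))
}

#' Trait architecture emulating the buckwheat experiment
#'
#' Eight traits (seed yield plus the seven index traits) with the published
#' field-trial genetic correlation structure as target, baseline means and
#' phenotypic SDs taken from the initial population of the bundled 2014
#' evaluation (seed yield, never measured on single plants, borrows the
#' selection-index scale as a synthetic stand-in), and a common default
#' heritability of 0.5 — the published work reports no per-trait
#' heritabilities, so a single mid-range value is assumed and documented.
#'
#' @param map `gs_map` (QTL taken from `mode == "qtl"` loci if present).
#' @param ref_pop reference `gs_population` for exact variance calibration.
#' @param h2 heritability (recycled over the 8 traits).
#' @param n_qtl shared QTL count.
#' @param seed optional integer seed.
#' @return `gs_trait_architecture`.
#' @export
buckwheat_architecture <- function(map, ref_pop = NULL, h2 = 0.5,
                                   n_qtl = 100, seed = NULL) {
  corr <- field_trait_correlations()
  ev <- evaluation_summary_2014()
  ini <- ev[ev$population == "initial", ]
  getv <- function(tr, col) ini[[col]][match(tr, ini$trait)]
  traits <- rownames(corr)
  src <- ifelse(traits == "seed_yield", "selection_index", traits)
  build_trait_architecture(map, corr, h2 = h2, n_qtl = n_qtl,
                           trait_means = getv(src, "mean"),
                           trait_sds = getv(src, "sd"),
                           ref_pop = ref_pop, seed = seed)
}

#' Build the full synthetic experiment world
#'
#' Convenience constructor used by the command-line tools, tests and the
#' acceptance script: a marker map plus dedicated QTL loci, a founder
#' population in linkage equilibrium, the buckwheat-like trait architecture
#' calibrated on those founders, and the published selection-index model.
#'
#' @param n_markers markers on the panel (default 2000, a desk-scale
#'   stand-in for the experiment's 14,598).
#' @param n_lg,lg_length_cM map geometry (default 8 x 100 cM; 2n = 16).
#' @param dominant_fraction proportion of dominant markers (default 0.5;
#'   the real panel mixes marker types in unstated proportions).
#' @param n_founders base-population size.
#' @param n_qtl shared QTL count.
#' @param h2 trait heritability.
#' @param allele_freq founder allele-frequency range.
#' @param seed integer seed.
#' @return list with `map`, `founders`, `arch`, `index_model`.
#' @export
setup_experiment <- function(n_markers = 2000, n_lg = 8, lg_length_cM = 100,
                             dominant_fraction = 0.5, n_founders = 200,
                             n_qtl = 100, h2 = 0.5,
                             allele_freq = c(0.1, 0.9), seed = 1) {
  set.seed(seed)
  mk <- random_map(n_markers, n_lg, lg_length_cM, dominant_fraction)
  qtl <- genetic_map(sprintf("Q%04d", seq_len(n_qtl)),
                     sort(rep_len(seq_len(n_lg), n_qtl)),
                     stats::runif(n_qtl, 0, lg_length_cM), "qtl")
  map <- genetic_map(c(mk$marker_id, qtl$marker_id),
                     c(mk$linkage_group, qtl$linkage_group),
                     c(mk$position_cM, qtl$position_cM),
                     c(mk$mode, qtl$mode))
  founders <- simulate_founders(n_founders, map, allele_freq)
  arch <- buckwheat_architecture(map, ref_pop = founders, h2 = h2,
                                 n_qtl = n_qtl)
  list(map = map, founders = founders, arch = arch,
       index_model = buckwheat_index_model())
}
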