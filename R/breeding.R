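#' Breeding-scheme configuration
#'
#' Captures the two-cycle-per-year genomic selection (GS) scheme and the
#' once-a-year phenotypic selection (PS) scheme. Defaults follow the
#' experimental design: 192 plants in the first GS cycle of each year
#' (trained and phenotyped), 48 genotype-only plants in the second, 192 in
#' each PS cycle, 12 selected everywhere, a 40-plant bottleneck founding the
#' initial population, and annual model updating.
#'
#' @param scheme `"gs"` or `"ps"`.
#' @param years number of breeding years (one PS cycle or two GS cycles
#'   each).
#' @param gs_cycle1_size,gs_cycle2_size,ps_size cycle population sizes.
#' @param n_selected number of seed parents selected per cycle.
#' @param update_policy `"annual"` (retrain at each year's first cycle) or
#'   `"never"` (keep the first model frozen).
#' @param bottleneck_k plants random-mated to found the initial population.
#' @param mortality_rate probability that a plant dies before selection.
#' @param seed_stock_n seeds retained per post-cycle population for the
#'   common-garden evaluation.
#' @param seed master seed; every stage seed is derived from it.
#' @return list of class `gs_scheme_config`.
#' @export
scheme_config <- function(scheme = c("gs", "ps"), years = 3,
                          gs_cycle1_size = 192, gs_cycle2_size = 48,
                          ps_size = 192, n_selected = 12,
                          update_policy = c("annual", "never"),
                          bottleneck_k = 40, mortality_rate = 0,
                          seed_stock_n = 36, seed = 1) {
  scheme <- match.arg(scheme)
  update_policy <- match.arg(update_policy)
  if (years < 1) stop("years must be >= 1")
  if (n_selected > min(gs_cycle1_size, gs_cycle2_size, ps_size))
    stop("n_selected exceeds a cycle population size")
  if (mortality_rate < 0 || mortality_rate >= 1)
    stop("mortality_rate must be in [0,1)")
  structure(list(scheme = scheme, years = years,
                 gs_cycle1_size = gs_cycle1_size,
                 gs_cycle2_size = gs_cycle2_size, ps_size = ps_size,
                 n_selected = n_selected, update_policy = update_policy,
                 bottleneck_k = bottleneck_k,
                 mortality_rate = mortality_rate,
                 seed_stock_n = seed_stock_n, seed = seed),
            class = "gs_scheme_config")
}

#' Rank individuals by index value
#'
#' Stable truncation-selection order: decreasing index value, ties broken by
#' individual id. With all-equal values the ranking falls back to id order.
#'
#' @param index_df data.frame from [compute_index()] (or any frame with
#'   `individual_id` and `value`).
#' @return character vector of ids, best first.
#' @export
rank_by_index <- function(index_df) {
  index_df$individual_id[order(-index_df$value, index_df$individual_id)]
}

#' Fill a selected set by rank, skipping dead plants
#'
#' Walks the ranking from the top, skipping identifiers in `deaths`, until
#' `n_selected` survivors are collected — the contingency used when selected
#' plants are lost to disease and the next-ranked plants take their place.
#'
#' @param ranked_ids ids ordered best-first (no duplicates).
#' @param n_selected set size to fill.
#' @param deaths ids of dead plants.
#' @return character vector of selected survivor ids (rank order).
#' @export
apply_mortality <- function(ranked_ids, n_selected, deaths = character(0)) {
  if (anyDuplicated(ranked_ids)) stop("duplicate ids in ranking")
  alive <- ranked_ids[!ranked_ids %in% deaths]
  if (length(alive) < n_selected) stop("fewer survivors than n_selected")
  alive[seq_len(n_selected)]
}

#' Drop markers monomorphic in the current population from a panel
#'
#' Reproduces marker-panel attrition across cycles: fixed markers carry no
#' information and are excluded when models are updated.
#'
#' @param panel character vector of marker ids.
#' @param genotypes genotype matrix of the current breeding population.
#' @return the retained marker ids.
#' @export
update_marker_panel <- function(panel, genotypes) {
  g <- genotypes[, intersect(panel, colnames(genotypes)), drop = FALSE]
  poly <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[!is.na(g[, j]), j]
    length(unique(x)) > 1L
  }, logical(1))
  out <- colnames(g)[poly]
  if (length(out) == 0L) stop("no polymorphic markers left in panel")
  out
}

#' Overlap of two top-k selections
#'
#' @param rank_a,rank_b ordered id vectors (best first, no duplicates).
#' @param k set size.
#' @return size of the intersection of the two top-k sets.
#' @export
selection_overlap <- function(rank_a, rank_b, k) {
  if (anyDuplicated(rank_a) || anyDuplicated(rank_b))
    stop("duplicate ids within a ranking")
  if (k > min(length(rank_a), length(rank_b))) stop("k exceeds list length")
  length(intersect(rank_a[seq_len(k)], rank_b[seq_len(k)]))
}

draw_deaths <- function(ids, rate) {
  if (rate <= 0) return(character(0))
  ids[stats::runif(length(ids)) < rate]
}

#' First-of-year GS cycle: genotype, phenotype, train, select after pollination
#'
#' Trains (or reuses, per the update policy) one G-BLUP model per index
#' trait, ranks plants by their expected selection index, and selects the
#' top `n_selected` as seed parents *after* pollination — so the pollen
#' parents of the next generation are the entire population. Returns the
#' next cycle's population of size `gs_cycle2_size`.
#'
#' @param pop breeding population (`gs_population`) of size
#'   `gs_cycle1_size`.
#' @param arch `gs_trait_architecture`.
#' @param index_model `gs_index_model`.
#' @param config `gs_scheme_config`.
#' @param prior_models named list of `gs_gblup` used when not retraining.
#' @param panel marker ids to genotype (attrition applied); default all
#'   non-QTL loci.
#' @param cycle_label e.g. `"GS1"`.
#' @param train retrain models this cycle.
#' @return list with `offspring`, `stock` (evaluation seed sample),
#'   `models`, `record`, `genotypes`, `phenotypes`, `index`.
#' @export
run_gs_cycle1 <- function(pop, arch, index_model, config,
                          prior_models = NULL, panel = NULL,
                          cycle_label = "GS1", train = TRUE) {
  if (pop_size(pop) != config$gs_cycle1_size)
    stop("population size != gs_cycle1_size")
  if (is.null(panel)) panel <- pop$map$marker_id[pop$map$mode != "qtl"]
  geno <- observe_markers(pop, markers = panel)
  panel <- update_marker_panel(panel, geno)
  geno <- geno[, panel, drop = FALSE]
  phen <- phenotype(pop, arch)
  traits <- index_model$trait_names
  models <- if (train) {
    stats::setNames(lapply(traits, function(tr)
      fit_gblup(geno, phen[, tr], trait_name = tr,
                panel_version = cycle_label)), traits)
  } else {
    if (is.null(prior_models)) stop("no prior models to reuse")
    prior_models
  }
  idx <- expected_index(models, geno, index_model)
  ranked <- rank_by_index(idx)
  deaths <- draw_deaths(pop$id, config$mortality_rate)
  selected <- apply_mortality(ranked, config$n_selected, deaths)
  offspring <- random_mate(pop, config$gs_cycle2_size, dams = selected,
                           generation = paste0("Post-", cycle_label))
  stock <- random_mate(pop, config$seed_stock_n, dams = selected,
                       generation = paste0("Stock-", cycle_label))
  record <- list(cycle_label = cycle_label, selected_ids = selected,
                 selection_source = "expected", seed_parent_ids = selected,
                 pollen_parent_ids = pop$id,
                 model_version = models[[1L]]$panel_version,
                 panel_size = length(panel), deaths = deaths)
  list(offspring = offspring, stock = stock, models = models,
       record = record, panel = panel, genotypes = geno, phenotypes = phen,
       index = idx)
}

#' Second-of-year GS cycle: genotype-only selection before pollination
#'
#' No phenotyping and no training: plants are ranked on the predicted
#' selection index and the top `n_selected` are selected *before*
#' pollination, so both seed and pollen parents are the selected set.
#' Returns the next year's population of size `gs_cycle1_size`.
#'
#' @inheritParams run_gs_cycle1
#' @param models per-trait `gs_gblup` list from the current model version.
#' @return list with `offspring`, `stock`, `record`, `genotypes`, `index`.
#' @export
run_gs_cycle2 <- function(pop, models, index_model, config, panel = NULL,
                          cycle_label = "GS2") {
  if (pop_size(pop) != config$gs_cycle2_size)
    stop("population size != gs_cycle2_size")
  if (is.null(panel)) panel <- pop$map$marker_id[pop$map$mode != "qtl"]
  geno <- observe_markers(pop, markers = panel)
  idx <- expected_index(models, geno, index_model, source = "predicted")
  ranked <- rank_by_index(idx)
  deaths <- draw_deaths(pop$id, config$mortality_rate)
  selected <- apply_mortality(ranked, config$n_selected, deaths)
  offspring <- random_mate(pop, config$gs_cycle1_size, dams = selected,
                           sires = selected,
                           generation = paste0("Post-", cycle_label))
  stock <- random_mate(pop, config$seed_stock_n, dams = selected,
                       sires = selected,
                       generation = paste0("Stock-", cycle_label))
  record <- list(cycle_label = cycle_label, selected_ids = selected,
                 selection_source = "predicted", seed_parent_ids = selected,
                 pollen_parent_ids = selected,
                 model_version = models[[1L]]$panel_version,
                 panel_size = length(panel), deaths = deaths)
  list(offspring = offspring, stock = stock, record = record,
       genotypes = geno, index = idx)
}

#' One PS cycle: observed-index selection after pollination
#'
#' The observed selection index is computed from phenotypes; the top
#' `n_selected` plants become seed parents, pollinated by the whole
#' population (selection acts on females only).
#'
#' @inheritParams run_gs_cycle1
#' @return list with `offspring`, `stock`, `record`, `phenotypes`, `index`.
#' @export
run_ps_cycle <- function(pop, arch, index_model, config,
                         cycle_label = "PS1") {
  if (pop_size(pop) != config$ps_size) stop("population size != ps_size")
  phen <- phenotype(pop, arch)
  idx <- compute_index(phen, index_model, source = "observed")
  ranked <- rank_by_index(idx)
  deaths <- draw_deaths(pop$id, config$mortality_rate)
  selected <- apply_mortality(ranked, config$n_selected, deaths)
  offspring <- random_mate(pop, config$ps_size, dams = selected,
                           generation = paste0("Post-", cycle_label))
  stock <- random_mate(pop, config$seed_stock_n, dams = selected,
                       generation = paste0("Stock-", cycle_label))
  record <- list(cycle_label = cycle_label, selected_ids = selected,
                 selection_source = "observed", seed_parent_ids = selected,
                 pollen_parent_ids = pop$id, model_version = NA_character_,
                 panel_size = NA_integer_, deaths = deaths)
  list(offspring = offspring, stock = stock, record = record,
       phenotypes = phen, index = idx)
}

#' Run a full GS or PS breeding program
#'
#' Imposes the bottleneck on the base population, then executes `years`
#' breeding years (two GS cycles or one PS cycle each), with annual model
#' updating and marker-panel attrition under GS. Seed-stock samples of every
#' post-cycle population are retained and phenotyped in one common
#' simulated environment at the end. Fully reproducible from the master
#' seed.
#'
#' @param config `gs_scheme_config`.
#' @param arch `gs_trait_architecture`.
#' @param index_model `gs_index_model`.
#' @param base_pop pre-bottleneck base population (`gs_population`).
#' @return list of class `gs_program`: `config`, `initial`, `populations`
#'   (post-cycle), `stocks`, `stock_phenotypes` (common environment),
#'   `records`, `models` (per model version), `cycle_data` (genotypes,
#'   phenotypes and index per training cycle), `panel_sizes`.
#' @export
run_program <- function(config, arch, index_model, base_pop) {
  set.seed(config$seed)
  # per-stage seeds derived once from the master seed
  stage_seed <- sample.int(.Machine$integer.max - 1L,
                           4L * config$years + 4L)
  st <- 0L
  next_seed <- function() { st <<- st + 1L; set.seed(stage_seed[st]) }

  n0 <- if (config$scheme == "gs") config$gs_cycle1_size else config$ps_size
  next_seed()
  initial <- bottleneck_then_expand(base_pop, config$bottleneck_k, n0,
                                    generation = "initial")
  pops <- list()
  stocks <- list(initial = initial)
  records <- list()
  models <- list()
  cycle_data <- list()
  panel_sizes <- integer(0)
  pop <- initial
  panel <- base_pop$map$marker_id[base_pop$map$mode != "qtl"]
  cur_models <- NULL

  if (config$scheme == "gs") {
    for (yr in seq_len(config$years)) {
      lab1 <- paste0("GS", 2L * yr - 1L)
      train <- config$update_policy == "annual" || yr == 1L
      next_seed()
      c1 <- run_gs_cycle1(pop, arch, index_model, config,
                          prior_models = cur_models, panel = panel,
                          cycle_label = lab1, train = train)
      if (train) models[[lab1]] <- c1$models
      cur_models <- c1$models
      panel <- c1$panel
      panel_sizes[lab1] <- length(panel)
      records[[lab1]] <- c1$record
      cycle_data[[lab1]] <- list(genotypes = c1$genotypes,
                                 phenotypes = c1$phenotypes,
                                 index = c1$index, population = pop)
      pops[[paste0("post_", tolower(lab1))]] <- c1$offspring
      stocks[[paste0("post_", tolower(lab1))]] <- c1$stock

      lab2 <- paste0("GS", 2L * yr)
      next_seed()
      c2 <- run_gs_cycle2(c1$offspring, cur_models, index_model, config,
                          panel = panel, cycle_label = lab2)
      records[[lab2]] <- c2$record
      panel_sizes[lab2] <- length(panel)
      pops[[paste0("post_", tolower(lab2))]] <- c2$offspring
      stocks[[paste0("post_", tolower(lab2))]] <- c2$stock
      pop <- c2$offspring
    }
  } else {
    for (yr in seq_len(config$years)) {
      lab <- paste0("PS", yr)
      next_seed()
      cy <- run_ps_cycle(pop, arch, index_model, config, cycle_label = lab)
      records[[lab]] <- cy$record
      cycle_data[[lab]] <- list(phenotypes = cy$phenotypes, index = cy$index,
                                population = pop)
      pops[[paste0("post_", tolower(lab))]] <- cy$offspring
      stocks[[paste0("post_", tolower(lab))]] <- cy$stock
      pop <- cy$offspring
    }
  }

  # common-garden evaluation of all seed stocks under one environment draw
  next_seed()
  stock_phen <- lapply(stocks, function(s) phenotype(s, arch))

  structure(list(config = config, initial = initial, populations = pops,
                 stocks = stocks, stock_phenotypes = stock_phen,
                 records = records, models = models,
                 cycle_data = cycle_data, panel_sizes = panel_sizes),
            class = "gs_program")
}

#' @export
print.gs_program <- function(x, ...) {
  cat(sprintf("<gs_program> %s, %d year(s), %d cycle record(s)\n",
              toupper(x$config$scheme), x$config$years, length(x$records)))
  invisible(x)
}

#' Mean true (genetic) selection index of a population
#'
#' The selection index applied to true genetic values — the simulation-only
#' ground truth used to measure realized response.
#'
#' @param pop a `gs_population`.
#' @param arch `gs_trait_architecture`.
#' @param index_model `gs_index_model`.
#' @return scalar mean index of genetic values.
#' @export
true_index_mean <- function(pop, arch, index_model) {
  g <- genetic_values(pop, arch)
  mean(compute_index(g, index_model, source = "expected")$value)
}
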