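#' Welch's t-test from summary statistics or raw vectors
#'
#' `t = (mean_b - mean_a) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The raw-
#' vector interface computes the sample summaries and calls the same path,
#' so the two routes agree exactly.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (sample SD, n-1
#'   denominator).
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("need n >= 2 per group")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) stop("zero pooled variance")
  t <- (mean_b - mean_a) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @rdname welch_test
#' @param a,b raw numeric vectors.
#' @export
welch_test_raw <- function(a, b) {
  welch_test(mean(a), stats::sd(a), length(a), mean(b), stats::sd(b), length(b))
}

#' Summarize populations per trait and selection index
#'
#' Per-population, per-trait means and sample SDs plus the same for the
#' selection index, and each mean as a percentage of the corresponding mean
#' in the initial population.
#'
#' @param phenotypes named list of phenotype matrices (individuals x traits),
#'   one per population, in cycle order.
#' @param index_model optional `gs_index_model`; adds a `selection_index`
#'   trait computed per individual.
#' @param initial label of the baseline population (default first element).
#' @return data.frame with columns `population`, `n`, `trait`, `mean`, `sd`,
#'   `percent_of_initial`.
#' @export
summarize_populations <- function(phenotypes, index_model = NULL,
                                  initial = names(phenotypes)[1L]) {
  if (!initial %in% names(phenotypes)) stop("initial population not found")
  rows <- lapply(names(phenotypes), function(popn) {
    y <- as.matrix(phenotypes[[popn]])
    if (nrow(y) < 2L) stop("population '", popn, "' has n < 2")
    if (!is.null(index_model)) {
      si <- compute_index(y, index_model)$value
      y <- cbind(y, selection_index = si)
    }
    data.frame(population = popn, n = nrow(y), trait = colnames(y),
               mean = apply(y, 2L, mean), sd = apply(y, 2L, stats::sd),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  add_percent_of_initial(out, initial)
}

#' Add percent-of-initial columns to a population summary table
#'
#' `percent_of_initial = 100 * mean / mean_initial`, computed per trait. The
#' baseline population gets 100 by construction. Works on any long summary
#' table with `population`, `trait`, `mean` columns — including bundled
#' published tables.
#'
#' @param summary_df long-format summary data frame.
#' @param initial baseline population label.
#' @return the input with a `percent_of_initial` column.
#' @export
add_percent_of_initial <- function(summary_df, initial = "initial") {
  base <- summary_df[summary_df$population == initial, ]
  if (nrow(base) == 0L) stop("initial population missing from summary")
  m0 <- stats::setNames(base$mean, base$trait)
  # (mean / m0) first so the baseline population is exactly 100
  summary_df$percent_of_initial <-
    100 * (summary_df$mean / m0[summary_df$trait])
  summary_df
}

#' All pairwise Welch comparisons with Bonferroni correction
#'
#' Every population pair, per trait; the Bonferroni family is the set of
#' pairwise comparisons within one trait (`m = choose(#populations, 2)`),
#' matching per-trait letter groupings in evaluation tables.
#'
#' @param summary_df long summary table with `population`, `trait`, `mean`,
#'   `sd`, `n` (e.g. from [summarize_populations()]); alternatively a named
#'   list of raw phenotype matrices, which is summarized first.
#' @param alpha familywise significance level.
#' @param index_model passed to [summarize_populations()] for raw input.
#' @return data.frame of class `gs_comparisons` with columns
#'   `population_a`, `population_b`, `trait`, `t_statistic`, `df`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
pairwise_comparisons <- function(summary_df, alpha = 0.05,
                                 index_model = NULL) {
  if (!is.data.frame(summary_df))
    summary_df <- summarize_populations(summary_df, index_model)
  pops <- unique(summary_df$population)
  if (length(pops) < 2L) stop("need at least 2 populations")
  m <- choose(length(pops), 2L)
  rows <- list()
  for (tr in unique(summary_df$trait)) {
    s <- summary_df[summary_df$trait == tr, ]
    s <- s[match(pops, s$population), ]
    for (i in seq_len(length(pops) - 1L)) for (j in seq(i + 1L, length(pops))) {
      w <- welch_test(s$mean[i], s$sd[i], s$n[i], s$mean[j], s$sd[j], s$n[j])
      rows[[length(rows) + 1L]] <-
        data.frame(population_a = pops[i], population_b = pops[j], trait = tr,
                   t_statistic = w$t, df = w$df, p_raw = w$p,
                   p_adjusted = min(1, m * w$p),
                   significant = min(1, m * w$p) < alpha,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gs_comparisons", "data.frame")
  out
}

#' Compact letter display from a pairwise comparison table
#'
#' Insert-and-absorb letter assignment on the adjusted significance matrix
#' of one trait: populations sharing a letter are not significantly
#' different. Letters are presentation only; the comparison table is the
#' canonical output.
#'
#' @param comparisons a `gs_comparisons` table.
#' @param trait trait to display.
#' @return named character vector of letter groups per population.
#' @export
letter_display <- function(comparisons, trait) {
  cc <- comparisons[comparisons$trait == trait, ]
  pops <- unique(c(cc$population_a, cc$population_b))
  np <- length(pops)
  sig <- matrix(FALSE, np, np, dimnames = list(pops, pops))
  for (r in seq_len(nrow(cc))) {
    sig[cc$population_a[r], cc$population_b[r]] <- cc$significant[r]
    sig[cc$population_b[r], cc$population_a[r]] <- cc$significant[r]
  }
  groups <- list(pops)  # start with one letter containing everyone
  for (i in seq_len(np - 1L)) for (j in seq(i + 1L, np)) {
    if (!sig[i, j]) next
    for (g in seq_along(groups)) {
      if (all(c(pops[i], pops[j]) %in% groups[[g]])) {
        # split the violated letter into two, then absorb duplicates
        groups[[length(groups) + 1L]] <- setdiff(groups[[g]], pops[i])
        groups[[g]] <- setdiff(groups[[g]], pops[j])
      }
    }
    keep <- !vapply(seq_along(groups), function(g)
      any(vapply(groups[-g], function(h) all(groups[[g]] %in% h), logical(1))),
      logical(1))
    groups <- groups[keep]
  }
  lab <- vapply(pops, function(p) paste(letters[which(vapply(
    groups, function(g) p %in% g, logical(1)))], collapse = ""),
    character(1))
  stats::setNames(lab, pops)
}

#' Per-cycle gain trajectory and final GS-vs-PS contrast
#'
#' Orders populations by scheme and cycle, tabulates per-cycle deltas and
#' cumulative percent gain of the selection-index mean, and contrasts the
#' final GS and PS populations with a Welch test.
#'
#' @param summary_df long summary with columns `population`, `scheme`
#'   (`"gs"`, `"ps"` or `"both"`), `cycle` (integer, 0 = initial), `trait`,
#'   `mean`, `sd`, `n`.
#' @param index_trait trait holding the index (default
#'   `"selection_index"`).
#' @return list with `trajectory` (per scheme/cycle: mean, delta,
#'   cumulative_percent_gain) and `final_contrast` (Welch test of final GS
#'   vs final PS population).
#' @export
gain_trajectory <- function(summary_df, index_trait = "selection_index") {
  s <- summary_df[summary_df$trait == index_trait, ]
  if (nrow(s) == 0L) stop("index trait not found")
  base <- s[s$cycle == 0, ]
  if (nrow(base) != 1L) stop("need exactly one cycle-0 population")
  traj <- lapply(c("gs", "ps"), function(sc) {
    ss <- s[s$scheme %in% c(sc, "both"), ]
    ss <- ss[order(ss$cycle), ]
    data.frame(scheme = sc, population = ss$population, cycle = ss$cycle,
               mean = ss$mean, delta = c(NA, diff(ss$mean)),
               cumulative_percent_gain = 100 * (ss$mean - base$mean) / base$mean,
               stringsAsFactors = FALSE)
  })
  traj <- do.call(rbind, traj)
  fin <- lapply(c("gs", "ps"), function(sc) {
    ss <- s[s$scheme == sc, ]
    ss[which.max(ss$cycle), ]
  })
  contrast <- welch_test(fin[[2L]]$mean, fin[[2L]]$sd, fin[[2L]]$n,
                         fin[[1L]]$mean, fin[[1L]]$sd, fin[[1L]]$n)
  list(trajectory = traj, final_contrast = c(contrast,
       list(gs = fin[[1L]]$population, ps = fin[[2L]]$population)))
}
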