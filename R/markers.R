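#' Observe marker genotypes
#'
#' Codominant markers report allele dosage {0,1,2}; dominant markers report
#' presence {0,1}, the heterozygote being indistinguishable from the
#' dominant homozygote (1 = at least one "1" allele). Missing calls are
#' introduced independently at `missing_rate`. QTL loci (`mode == "qtl"`) are
#' never reported.
#'
#' @param pop a `gs_population`.
#' @param markers optional subset of marker ids to assay; defaults to all
#'   non-QTL loci.
#' @param missing_rate proportion of calls set to `NA`.
#' @param seed optional integer seed.
#' @return integer matrix individuals x markers (class `gs_genotypes` via its
#'   `"modes"` attribute recording each column's assay mode).
#' @export
observe_markers <- function(pop, markers = NULL, missing_rate = 0,
                            seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  map <- pop$map
  if (is.null(markers)) markers <- map$marker_id[map$mode != "qtl"]
  idx <- match(markers, map$marker_id)
  if (anyNA(idx)) stop("unknown marker id")
  g <- dosage(pop)[, idx, drop = FALSE]
  modes <- map$mode[idx]
  dom <- modes == "dominant"
  if (any(dom)) g[, dom] <- (g[, dom, drop = FALSE] > 0L) + 0L
  if (missing_rate > 0) {
    miss <- stats::runif(length(g)) < missing_rate
    g[miss] <- NA_integer_
  }
  colnames(g) <- markers
  attr(g, "modes") <- stats::setNames(modes, markers)
  g
}

#' Marker assay modes of a genotype matrix
#' @param genotypes a matrix from [observe_markers()] or a plain matrix (all
#'   columns then assumed codominant unless their values never exceed 1).
#' @return character vector, one of `"codominant"`/`"dominant"` per column.
#' @export
marker_modes <- function(genotypes) {
  m <- attr(genotypes, "modes")
  if (!is.null(m)) return(unname(m[colnames(genotypes)]))
  apply(genotypes, 2L, function(x) {
    if (all(x %in% c(0L, 1L, NA))) "dominant" else "codominant"
  })
}

#' Mean-impute missing genotype calls
#'
#' Column-mean imputation, the minimal convention used before model
#' training. Columns that are entirely missing become their assay's
#' mid-value.
#'
#' @param genotypes numeric matrix with possible `NA`s.
#' @return numeric matrix without `NA`s.
#' @export
impute_genotypes <- function(genotypes) {
  if (!anyNA(genotypes)) return(genotypes)
  mu <- colMeans(genotypes, na.rm = TRUE)
  mu[is.nan(mu)] <- 0.5
  na <- which(is.na(genotypes), arr.ind = TRUE)
  genotypes[na] <- mu[na[, 2L]]
  genotypes
}
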