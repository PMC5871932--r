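# Delimited-text interchange: comma-separated, UTF-8, "NA" missing token,
# headers mandatory. Genotype matrices are individual-major.

#' Read and write package tables
#'
#' Writers/readers for the standard interchange files: genotype matrices
#' (rows = individuals, first column `individual_id`, remaining columns one
#' per marker), genetic maps (`marker_id`, `linkage_group`, `position_cM`,
#' `mode`), phenotype tables (first column `individual_id`) and pedigrees
#' (`individual_id`, `dam_id`, `sire_id`, `generation`). Round-trips are
#' lossless for ids and integers and to full double precision for reals.
#'
#' @param x object to write.
#' @param path file path.
#' @param map optional `gs_map` used to restore marker assay modes on read.
#' @return readers return the object; writers return `path` invisibly.
#' @name gsmass_io
NULL

#' @rdname gsmass_io
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(individual_id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname gsmass_io
#' @export
read_genotypes <- function(path, map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "individual_id")
    stop("genotype file must start with an individual_id column: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(is.na(m) | m %in% 0:2), arr.ind = TRUE)
  if (length(bad))
    stop(sprintf("invalid genotype value at row %d, column '%s' in %s",
                 bad[1L, 1L], colnames(m)[bad[1L, 2L]], path))
  storage.mode(m) <- "integer"
  rownames(m) <- df$individual_id
  if (!is.null(map))
    attr(m, "modes") <- stats::setNames(
      map$mode[match(colnames(m), map$marker_id)], colnames(m))
  m
}

#' @rdname gsmass_io
#' @export
write_map <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gsmass_io
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("marker_id", "linkage_group", "position_cM", "mode")
  if (!all(need %in% names(df)))
    stop("map file must have columns ", paste(need, collapse = ", "))
  genetic_map(df$marker_id, df$linkage_group, df$position_cM, df$mode)
}

#' @rdname gsmass_io
#' @export
write_phenotypes <- function(x, path) {
  df <- data.frame(individual_id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname gsmass_io
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$individual_id
  m
}

#' @rdname gsmass_io
#' @param pop a `gs_population` whose pedigree is written.
#' @export
write_pedigree <- function(pop, path) {
  utils::write.csv(data.frame(individual_id = pop$id, dam_id = pop$dam,
                              sire_id = pop$sire,
                              generation = pop$generation),
                   path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a fitted index model to JSON (and back)
#'
#' @param model a `gs_index_model`.
#' @param path file path.
#' @export
write_index_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- stats::setNames(as.numeric(x$coefficients),
                                    x$trait_names)
  class(x) <- "gs_index_model"
  x
}

#' Serialize a G-BLUP model to JSON (and back)
#'
#' Stores the variance components, marker effects, panel version and
#' training centering — everything needed to predict new genotypes.
#'
#' @param model a `gs_gblup`.
#' @param path file path.
#' @export
write_gblup_model <- function(model, path) {
  keep <- model[c("trait_name", "panel_version", "training_ids", "mu",
                  "delta", "sigma_g2", "sigma_e2", "h2", "marker_ids",
                  "trace_scale")]
  keep$marker_effects <- unname(model$marker_effects)
  keep$centers <- unname(model$centers)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gblup_model
#' @export
read_gblup_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$marker_effects <- stats::setNames(as.numeric(x$marker_effects),
                                      x$marker_ids)
  x$centers <- stats::setNames(as.numeric(x$centers), x$marker_ids)
  class(x) <- "gs_gblup"
  x
}

#' Read dosage genotypes from a VCF file
#'
#' Maps biallelic GT fields to alternate-allele dosage {0,1,2} for use with
#' real genotype data. Requires the VariantAnnotation package (Suggests).
#'
#' @param path VCF file path.
#' @return integer matrix individuals x variants.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_dosage requires the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  dose <- function(x) {
    a <- strsplit(x, "[|/]")
    vapply(a, function(al) {
      if (any(al == ".")) return(NA_integer_)
      sum(as.integer(al) > 0L)
    }, integer(1))
  }
  m <- apply(gt, 2L, dose)
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gt),
                                   dimnames = dimnames(gt))
  t(m)
}
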