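#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per locus giving its identifier,
#' linkage group, position in centimorgans, and marker assay mode. Positions
#' must be non-negative and non-decreasing within each linkage group;
#' identifiers must be unique. `"codominant"` loci are assayed as allele
#' dosage 0/1/2, `"dominant"` loci as presence 0/1 (heterozygote and dominant
#' homozygote indistinguishable), and `"qtl"` loci are causal positions that
#' are never genotyped.
#'
#' @param marker_id character vector of unique locus identifiers.
#' @param linkage_group integer vector of 1-based linkage-group labels.
#' @param position_cM numeric vector of map positions in cM.
#' @param mode character vector, each `"codominant"`, `"dominant"` or `"qtl"`.
#' @return A `data.frame` of class `gs_map`, ordered by linkage group and
#'   position.
#' @seealso [random_map()] for a quick evenly spaced map.
#' @export
genetic_map <- function(marker_id, linkage_group, position_cM,
                        mode = "codominant") {
  n <- length(marker_id)
  if (n == 0L) stop("empty map")
  mode <- rep_len(mode, n)
  if (anyDuplicated(marker_id)) stop("marker_ids must be unique")
  if (any(position_cM < 0)) stop("map positions must be non-negative")
  if (!all(mode %in% c("codominant", "dominant", "qtl")))
    stop("mode must be 'codominant', 'dominant' or 'qtl'")
  map <- data.frame(marker_id = as.character(marker_id),
                    linkage_group = as.integer(linkage_group),
                    position_cM = as.numeric(position_cM),
                    mode = mode,
                    stringsAsFactors = FALSE)
  map <- map[order(map$linkage_group, map$position_cM), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("gs_map", "data.frame")
  map
}

#' Evenly cover linkage groups with random marker positions
#'
#' Generates `n_loci` positions uniform on each of `n_lg` linkage groups of
#' the given length. The default geometry (8 linkage groups of 100 cM)
#' matches a buckwheat-like karyotype (2n = 16).
#'
#' @param n_loci total number of loci.
#' @param n_lg number of linkage groups.
#' @param lg_length_cM length of each linkage group in cM.
#' @param dominant_fraction proportion of loci assayed as dominant.
#' @param prefix identifier prefix.
#' @return A `gs_map`.
#' @export
random_map <- function(n_loci = 2000, n_lg = 8, lg_length_cM = 100,
                       dominant_fraction = 0.5, prefix = "M") {
  lg <- sort(rep_len(seq_len(n_lg), n_loci))
  pos <- stats::runif(n_loci, 0, lg_length_cM)
  mode <- ifelse(stats::runif(n_loci) < dominant_fraction,
                 "dominant", "codominant")
  genetic_map(sprintf("%s%05d", prefix, seq_len(n_loci)), lg, pos, mode)
}

#' @export
`[.gs_map` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("gs_map", "data.frame")
  out
}

#' @export
print.gs_map <- function(x, ...) {
  cat(sprintf("<gs_map> %d loci on %d linkage group(s); %d dominant, %d qtl\n",
              nrow(x), length(unique(x$linkage_group)),
              sum(x$mode == "dominant"), sum(x$mode == "qtl")))
  invisible(x)
}

# split marker indices/positions by linkage group once; reused in meiosis
map_blocks <- function(map) {
  idx <- split(seq_len(nrow(map)), map$linkage_group)
  lapply(idx, function(i) list(idx = i, pos = map$position_cM[i],
                               len = max(map$position_cM[i])))
}

#' Haldane map function and its inverse
#'
#' `haldane_c()` converts a map distance in cM to a recombination fraction,
#' `haldane_d()` does the reverse. Distances of 0 give c = 0; c is capped
#' below 0.5.
#'
#' @param d_cM map distance in centimorgans.
#' @param c recombination fraction in [0, 0.5).
#' @return numeric vector.
#' @export
haldane_c <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' @rdname haldane_c
#' @export
haldane_d <- function(c) -50 * log(1 - 2 * c)
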