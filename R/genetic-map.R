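# Synthetic genetic map: per-chromosome physical and genetic lengths with a
# constant recombination rate, standing in for an external sex-averaged map.

# Approximate human sex-averaged autosomal genetic lengths (cM), chr1..chr22.
# Used only as a shape vector: generate_map() rescales it so the totals sum
# exactly to the requested genome length.
.human_autosome_cM <- c(
  286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0, 166.4, 181.1,
  158.2, 174.7, 125.9, 120.2, 141.9, 134.0, 128.5, 117.2, 107.9, 108.3,
  62.8, 74.1
)

#' Generate a constant-rate genetic map
#'
#' Builds a genome of `n_chrom` chromosomes whose genetic lengths are
#' proportional to a fixed human-like autosome length vector (equal lengths
#' beyond 22 chromosomes) and rescaled so they sum exactly to `total_cM`.
#' Physical coordinates follow a constant recombination rate of
#' `1/bp_per_cM` cM per bp, so physical (Mb) and genetic (cM) detection
#' thresholds are mutually consistent (1 Mb = 1 cM at the default rate).
#'
#' @param n_chrom number of autosomes (default 22).
#' @param total_cM total genetic length of the genome in centimorgans;
#'   default 3346.30 cM, the autosomal total of the sex-averaged map this
#'   toolkit emulates.
#' @param bp_per_cM physical bases per centimorgan (default 1e6).
#' @param seed unused randomness hook kept for interface stability; the map
#'   is fully deterministic given its arguments.
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `chrom`, `length_bp`, `length_cM`, plus attributes `bp_per_cM` and
#'   `L_genome`.
#' @examples
#' m <- generate_map()
#' sum(m$length_cM) # 3346.30
#' @export
generate_map <- function(n_chrom = 22L, total_cM = 3346.30, bp_per_cM = 1e6,
                         seed = NULL) {
  if (n_chrom < 1L) stop_invalid("n_chrom must be >= 1")
  if (total_cM <= 0) stop_invalid("total_cM must be > 0")
  if (bp_per_cM <= 0) stop_invalid("bp_per_cM must be > 0")
  shape <- if (n_chrom <= length(.human_autosome_cM)) {
    .human_autosome_cM[seq_len(n_chrom)]
  } else {
    rep(mean(.human_autosome_cM), n_chrom)
  }
  len_cM <- shape / sum(shape) * total_cM
  map <- data.frame(
    chrom = seq_len(n_chrom),
    length_bp = len_cM * bp_per_cM,
    length_cM = len_cM
  )
  structure(map,
    bp_per_cM = bp_per_cM,
    L_genome = sum(len_cM),
    class = c("genetic_map", "data.frame")
  )
}

#' Total genetic length of a map (cM)
#' @param map a `genetic_map`.
#' @return numeric scalar, the summed genetic length across chromosomes.
#' @export
L_genome <- function(map) {
  attr(map, "L_genome") %||% sum(map$length_cM)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "Genetic map: %d chromosomes, %.2f cM total, %.3g bp/cM\n",
    nrow(x), L_genome(x), attr(x, "bp_per_cM")
  ))
  invisible(x)
}
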