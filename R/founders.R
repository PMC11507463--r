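# Synthetic marker panel and phased founder haplotypes.  Founder sites are
# independent (no linkage disequilibrium): a tractable null in which detector
# false-positive behaviour has a closed form.  Consequence: effects driven by
# redundant, correlated SNPs on real array data are deliberately not emulated.

new_marker_panel <- function(df, map) {
  stopifnot(all(c("chrom", "pos_bp", "pos_cM", "ref", "alt", "alt_freq")
                %in% names(df)))
  structure(df,
    bp_per_cM = attr(map, "bp_per_cM"),
    L_genome = L_genome(map),
    class = c("marker_panel", "data.frame")
  )
}

#' Generate founder haplotypes over a synthetic SNP panel
#'
#' Draws a biallelic SNP panel uniformly over the genetic map and phased
#' founder haplotypes with independent sites.  Per-marker alternate-allele
#' frequencies come from `maf_law` and are restricted to `[0.05, 0.95]`,
#' mirroring a minor-allele-frequency > 0.05 inclusion filter.  Alleles are
#' drawn independently per haplotype per site, so founder genotypes are in
#' Hardy-Weinberg proportions and adjacent markers are uncorrelated.
#'
#' @param n_individuals number of founder individuals (two haplotypes each).
#' @param panel_size number of markers.
#' @param map a [generate_map()] object.
#' @param maf_law function of one argument `n` returning `n` allele
#'   frequencies in (0, 1); default `uniform(0.05, 0.5)`.
#' @param seed integer seed; the draw is deterministic given it.
#' @return list with components `panel` (a `marker_panel`) and `haplotypes`
#'   (integer 0/1 matrix, `2 * n_individuals` rows named `<id>_1`/`<id>_2`,
#'   with attribute `ids`).
#' @export
generate_founders <- function(n_individuals, panel_size, map,
                              maf_law = function(n) stats::runif(n, 0.05, 0.5),
                              seed = 1) {
  if (n_individuals < 1L) stop_invalid("n_individuals must be >= 1")
  if (panel_size < 1L) stop_invalid("panel_size must be >= 1")
  with_seed(seed, {
    n_per <- as.vector(stats::rmultinom(
      1L, panel_size, map$length_cM / sum(map$length_cM)
    ))
    bp <- vector("list", nrow(map))
    for (c in seq_len(nrow(map))) {
      if (n_per[c] == 0L) { bp[[c]] <- numeric(0); next }
      bp[[c]] <- sort(sample.int(floor(map$length_bp[c]) - 1L, n_per[c]))
    }
    chrom <- rep.int(map$chrom, n_per)
    pos_bp <- unlist(bp)
    f <- maf_law(panel_size)
    if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
      stop_invalid("maf_law must yield frequencies strictly inside (0, 1)")
    }
    f <- pmin(pmax(f, 0.05), 0.95)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, panel_size, replace = TRUE)
    alt <- sample(alleles[-1L], panel_size, replace = TRUE)
    alt <- ifelse(alt == ref, "A", alt) # any base != ref; identity impossible
    panel <- new_marker_panel(data.frame(
      chrom = chrom,
      pos_bp = pos_bp,
      pos_cM = pos_bp / attr(map, "bp_per_cM"),
      ref = ref, alt = alt,
      alt_freq = f
    ), map)
    n_hap <- 2L * n_individuals
    haps <- matrix(
      stats::rbinom(n_hap * panel_size, 1L, rep(f, each = n_hap)),
      nrow = n_hap
    )
    ids <- sprintf("P%03d", seq_len(n_individuals))
    rownames(haps) <- paste0(rep(ids, each = 2L), "_", c(1L, 2L))
    attr(haps, "ids") <- ids
    list(panel = panel, haplotypes = haps)
  })
}

#' Down-sample a marker panel and matching haplotypes
#'
#' Keeps a uniformly random subset of `n_keep` markers (without replacement,
#' genomic order preserved) and subsets haplotype columns consistently.
#' Repeated halving reproduces the panel-size ladder used in the evaluation
#' design (5265 K down to 5 K, or its scaled analogue).
#'
#' @param panel a `marker_panel`.
#' @param haplotypes matrix with one column per marker (or `NULL`).
#' @param n_keep number of markers to retain, `1 <= n_keep <= nrow(panel)`.
#' @param seed integer seed.
#' @return list with `panel`, `haplotypes` (NULL if not supplied) and `keep`,
#'   the sorted parent-panel indices retained.
#' @export
subsample_panel <- function(panel, haplotypes, n_keep, seed = 1) {
  m <- nrow(panel)
  if (n_keep < 1L || n_keep > m) {
    stop_invalid("n_keep must be between 1 and the panel size (", m, ")")
  }
  keep <- if (n_keep == m) seq_len(m) else {
    with_seed(seed, sort(sample.int(m, n_keep)))
  }
  sub <- panel[keep, , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "bp_per_cM") <- attr(panel, "bp_per_cM")
  attr(sub, "L_genome") <- attr(panel, "L_genome")
  class(sub) <- class(panel)
  list(
    panel = sub,
    haplotypes = if (!is.null(haplotypes)) haplotypes[, keep, drop = FALSE],
    keep = keep
  )
}

#' Validate marker panel invariants
#'
#' Checks biallelic coding, the MAF filter window, and sorted, strictly
#' increasing positions within chromosomes.  Called by generators; exported
#' so adapters feeding external panels can assert the same contract.
#'
#' @param panel a `marker_panel`.
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_panel <- function(panel) {
  if (is.unsorted(panel$chrom)) stop_invalid("panel not sorted by chromosome")
  for (i in seq_len(nrow(chrom_bounds(panel)))) {
    cb <- chrom_bounds(panel)
    p <- panel$pos_bp[cb$lo[i]:cb$hi[i]]
    if (any(diff(p) <= 0)) {
      stop_invalid("positions not strictly increasing on chromosome ",
                   cb$chrom[i])
    }
  }
  maf <- pmin(panel$alt_freq, 1 - panel$alt_freq)
  if (any(maf < 0.05 - 1e-12)) stop_invalid("markers below the 0.05 MAF filter")
  if (any(panel$ref == panel$alt)) stop_invalid("non-biallelic marker coding")
  invisible(TRUE)
}
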