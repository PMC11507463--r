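# Four kinship estimators: one method-of-moments estimator driven by IBS
# counts and three IBD-segment detectors (IBS-run based with marker-count and
# genetic-length minima; probability-thresholded with physical-length minima
# and an error-bridging rule; phased exact-match with a genetic-length
# minimum).  Genotypes are alt-allele dosages 0/1/2; haplotypes are 0/1.
#
# Missing calls (NA) never terminate a candidate run and are excluded from
# IBS counts: a missing site carries no evidence for or against sharing.

#' Estimator configuration
#'
#' Thresholds of the three segment detectors and the method-of-moments
#' options, at the published defaults: the IBS-run detector requires
#' segments of at least 2 cM *and* 186 markers and adds a supplemental
#' kinship constant of 0.00138; the probability-thresholded detector
#' requires a chance-match probability below 1e-8 and physical length of at
#' least 5 Mb (IBD1) / 2 Mb (IBD2), with an error-bridging window of 100
#' markers emulating its built-in genotyping-error model; the phased
#' detector requires 3 cM.
#'
#' @param ibis_min_cM,ibis_min_markers minimum genetic length (cM) and
#'   marker count of an IBS-run segment.
#' @param ibis_constant supplemental kinship coefficient added to the
#'   IBS-run kinship estimate (its published default 0.00138).
#' @param ibis_bridge_markers mismatch tolerance of the IBS-run detector: an
#'   opposite-homozygote site is bridged when no other such site lies within
#'   this many markers on either side; 0 (default) disables bridging.
#' @param ibis_ibd2 also emit identical-genotype sub-runs as IBD2 segments
#'   (on by default: without them the kinship of full sibs is
#'   underestimated by their IBD2 share, `kappa2/4`).
#' @param truffle_pmatch chance-compatibility probability threshold.
#' @param truffle_min_Mb_ibd1,truffle_min_Mb_ibd2 physical length minima (Mb).
#' @param truffle_bridge_markers error-bridging window (markers), as above;
#'   default 100, i.e. at most one isolated mismatch per 100 markers.
#' @param germline_min_cM minimum genetic length of a phased exact match.
#' @return list of class `estimator_config`.
#' @export
estimator_config <- function(ibis_min_cM = 2, ibis_min_markers = 186L,
                             ibis_constant = 0.00138,
                             ibis_bridge_markers = 0L,
                             ibis_ibd2 = TRUE,
                             truffle_pmatch = 1e-8,
                             truffle_min_Mb_ibd1 = 5,
                             truffle_min_Mb_ibd2 = 2,
                             truffle_bridge_markers = 100L,
                             germline_min_cM = 3) {
  cfg <- list(
    ibis_min_cM = ibis_min_cM, ibis_min_markers = as.integer(ibis_min_markers),
    ibis_constant = ibis_constant,
    ibis_bridge_markers = as.integer(ibis_bridge_markers),
    ibis_ibd2 = isTRUE(ibis_ibd2),
    truffle_pmatch = truffle_pmatch,
    truffle_min_Mb_ibd1 = truffle_min_Mb_ibd1,
    truffle_min_Mb_ibd2 = truffle_min_Mb_ibd2,
    truffle_bridge_markers = as.integer(truffle_bridge_markers),
    germline_min_cM = germline_min_cM
  )
  thr <- unlist(cfg[c("ibis_min_cM", "ibis_min_markers", "truffle_pmatch",
                      "truffle_min_Mb_ibd1", "truffle_min_Mb_ibd2",
                      "germline_min_cM")])
  if (any(thr <= 0)) stop_invalid("all detection thresholds must be positive")
  structure(cfg, class = "estimator_config")
}

#' Method-of-moments kinship coefficient from IBS counts
#'
#' Homogeneous-population estimator from genome-wide identity-by-state
#' counts: with `N_AaAa` the number of sites at which both individuals are
#' heterozygous, `N_AAaa` the number of opposite-homozygote sites, and
#' `N_Aa^i`, `N_Aa^j` the heterozygote counts of each individual,
#' `theta = (N_AaAa - 2 N_AAaa) / (N_Aa^i + N_Aa^j)`.
#' No allele frequencies are needed.  The estimate can be negative; sites
#' missing in either individual are excluded.
#'
#' @param geno_a,geno_b aligned dosage vectors (0/1/2, NA = missing).
#' @return kinship estimate; `NA` when neither individual has a heterozygous
#'   call (undefined estimate).
#' @export
king_theta <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b)) {
    stop_invalid("genotype vectors must be aligned")
  }
  ok <- !is.na(geno_a) & !is.na(geno_b)
  if (!any(ok)) stop_invalid("no overlapping non-missing sites")
  ga <- geno_a[ok]; gb <- geno_b[ok]
  het_a <- ga == 1L; het_b <- gb == 1L
  n_hh <- sum(het_a & het_b)
  n_opp <- sum((ga == 0L & gb == 2L) | (ga == 2L & gb == 0L))
  denom <- sum(het_a) + sum(het_b)
  if (denom == 0L) return(NA_real_)
  (n_hh - 2 * n_opp) / denom
}

# Indices of incompatible sites that survive bridging: a site is bridged
# (tolerated inside a run) iff the nearest other incompatible site on either
# side is more than `window` markers away.
effective_breaks <- function(idx, window) {
  if (window <= 0L || length(idx) == 0L) return(idx)
  gap_prev <- c(Inf, diff(idx))
  gap_next <- c(diff(idx), Inf)
  idx[!(gap_prev > window & gap_next > window)]
}

# Maximal runs free of `breaks` per chromosome; breaks is a logical vector.
chrom_runs <- function(break_sites, panel, window = 0L) {
  cb <- chrom_bounds(panel)
  out <- vector("list", nrow(cb))
  for (i in seq_len(nrow(cb))) {
    lo <- cb$lo[i]; hi <- cb$hi[i]
    idx <- lo - 1L + which(break_sites[lo:hi])
    idx <- effective_breaks(idx, window)
    out[[i]] <- runs_between(idx, lo, hi)
  }
  do.call(rbind, out)
}

check_panel_sorted <- function(panel) {
  if (isTRUE(attr(panel, "validated"))) return(invisible(TRUE))
  if (is.unsorted(panel$chrom) ||
      any(stats::ave(panel$pos_bp, panel$chrom, FUN = function(x) {
        c(1, diff(x))
      }) <= 0)) {
    stop_invalid("marker panel must be sorted with strictly increasing ",
                 "positions within chromosomes")
  }
  invisible(TRUE)
}

#' IBS-run IBD segment detection (phase-free)
#'
#' Detects IBD1 segments as maximal runs of consecutive markers containing
#' no opposite-homozygote site, emitted when the run spans at least
#' `ibis_min_cM` centimorgans *and* `ibis_min_markers` markers.  With
#' `ibis_ibd2 = TRUE`, identical-genotype sub-runs meeting the same two
#' criteria are additionally emitted as IBD2 (and excluded from IBD1).
#'
#' @param geno_a,geno_b aligned dosage vectors.
#' @param panel `marker_panel` with cM positions (sorted).
#' @param cfg [estimator_config()].
#' @return a `segment_set`.
#' @export
ibis_segments <- function(geno_a, geno_b, panel, cfg = estimator_config()) {
  check_panel_sorted(panel)
  opp <- (geno_a == 0L & geno_b == 2L) | (geno_a == 2L & geno_b == 0L)
  opp[is.na(opp)] <- FALSE
  runs <- chrom_runs(opp, panel, cfg$ibis_bridge_markers)
  keep <- (runs[, 2L] - runs[, 1L] + 1L) >= cfg$ibis_min_markers &
    (panel$pos_cM[runs[, 2L]] - panel$pos_cM[runs[, 1L]]) >= cfg$ibis_min_cM
  runs <- runs[keep, , drop = FALSE]
  if (!cfg$ibis_ibd2 || nrow(runs) == 0L) {
    return(runs_to_segments(runs, panel, "IBD1"))
  }
  neq <- geno_a != geno_b
  neq[is.na(neq)] <- FALSE
  runs2 <- chrom_runs(neq, panel, 0L)
  keep2 <- (runs2[, 2L] - runs2[, 1L] + 1L) >= cfg$ibis_min_markers &
    (panel$pos_cM[runs2[, 2L]] - panel$pos_cM[runs2[, 1L]]) >= cfg$ibis_min_cM
  runs2 <- runs2[keep2, , drop = FALSE]
  rbind(
    runs_to_segments(subtract_runs(runs, runs2), panel, "IBD1"),
    runs_to_segments(runs2, panel, "IBD2")
  )
}

#' Kinship from IBS-run segments
#'
#' Converts segment lengths to Cotterman coefficients and applies
#' `theta = kappa2/2 + kappa1/4 + c`, where `c` is the supplemental kinship
#' coefficient factor (default 0.00138) of the IBS-run tool; the estimate is
#' therefore strictly positive even with no detected segments.
#'
#' @param segset `segment_set` from [ibis_segments()].
#' @param L_genome total map length (cM).
#' @param cfg [estimator_config()].
#' @return kinship estimate (>= `ibis_constant`).
#' @export
ibis_theta <- function(segset, L_genome = 3346.30, cfg = estimator_config()) {
  theta_from_kappa(cotterman_from_segments(segset, L_genome)) +
    cfg$ibis_constant
}

# Per-site log10 chance-compatibility probabilities under HWE.
truffle_site_logp <- function(panel) {
  lp <- attr(panel, "truffle_logp")
  if (!is.null(lp)) return(lp)
  p <- panel$alt_freq
  if (is.null(p) || anyNA(p)) stop_invalid("panel allele frequencies required")
  q <- 1 - p
  p_compat1 <- 1 - 2 * p^2 * q^2          # not opposite homozygotes
  p_compat2 <- q^4 + (2 * p * q)^2 + p^4  # identical genotypes
  list(cs1 = cumsum(log10(p_compat1)), cs2 = cumsum(log10(p_compat2)))
}

run_logp <- function(cs, runs) {
  lo <- runs[, 1L] - 1L
  base <- numeric(nrow(runs))
  base[lo > 0L] <- cs[lo[lo > 0L]]
  cs[runs[, 2L]] - base
}

#' Probability-thresholded IBD segment detection (phase-free)
#'
#' Candidate IBD1 runs are maximal stretches free of opposite-homozygote
#' sites and candidate IBD2 runs are maximal stretches of identical
#' genotypes, in both cases bridging isolated mismatches within the
#' error-model window (`truffle_bridge_markers`).  A run is reported when
#' (i) the probability that an unrelated pair is compatible by chance at
#' every site of the run — the product over sites of the Hardy-Weinberg
#' compatibility probability, `1 - 2 p^2 q^2` for IBD1 and
#' `p^4 + (2pq)^2 + q^4` for IBD2 — falls below `truffle_pmatch`, and
#' (ii) its physical span reaches `truffle_min_Mb_ibd1` / `truffle_min_Mb_ibd2`
#' megabases.  Reported IBD2 intervals are removed from IBD1 segments so the
#' two classes never overlap.
#'
#' @inheritParams ibis_segments
#' @return a `segment_set`.
#' @export
truffle_segments <- function(geno_a, geno_b, panel, cfg = estimator_config()) {
  check_panel_sorted(panel)
  lp <- truffle_site_logp(panel)
  opp <- (geno_a == 0L & geno_b == 2L) | (geno_a == 2L & geno_b == 0L)
  opp[is.na(opp)] <- FALSE
  neq <- geno_a != geno_b
  neq[is.na(neq)] <- FALSE
  w <- cfg$truffle_bridge_markers
  log_thr <- log10(cfg$truffle_pmatch)

  runs1 <- chrom_runs(opp, panel, w)
  keep1 <- (panel$pos_bp[runs1[, 2L]] - panel$pos_bp[runs1[, 1L]]) >=
    cfg$truffle_min_Mb_ibd1 * 1e6 & run_logp(lp$cs1, runs1) < log_thr
  runs1 <- runs1[keep1, , drop = FALSE]

  runs2 <- chrom_runs(neq, panel, w)
  keep2 <- (panel$pos_bp[runs2[, 2L]] - panel$pos_bp[runs2[, 1L]]) >=
    cfg$truffle_min_Mb_ibd2 * 1e6 & run_logp(lp$cs2, runs2) < log_thr
  runs2 <- runs2[keep2, , drop = FALSE]

  rbind(
    runs_to_segments(subtract_runs(runs1, runs2), panel, "IBD1"),
    runs_to_segments(runs2, panel, "IBD2")
  )
}

#' Kinship from probability-thresholded segments
#'
#' `theta = kappa2/2 + kappa1/4` with Cotterman coefficients taken from the
#' summed genetic lengths of the detected IBD1/IBD2 segments.
#'
#' @param segset `segment_set` from [truffle_segments()].
#' @param L_genome total map length (cM).
#' @return kinship estimate (>= 0).
#' @export
truffle_theta <- function(segset, L_genome = 3346.30) {
  theta_from_kappa(cotterman_from_segments(segset, L_genome))
}

#' Phased exact-match IBD segment detection
#'
#' Finds maximal exactly matching stretches between every cross-individual
#' haplotype pair and keeps those spanning at least `germline_min_cM`
#' centimorgans.  Intervals on which both haplotypes of each individual are
#' matched (under either pairing) are classed IBD2; intervals with at least
#' one matching haplotype pair are otherwise IBD1.  The scan is a vectorised
#' run-length pass over the haplotype equality profile, an exact equivalent
#' of seed-and-extend word matching.
#'
#' @param hap_a1,hap_a2 phased haplotypes (0/1) of individual a.
#' @param hap_b1,hap_b2 phased haplotypes of individual b.
#' @param panel `marker_panel`.
#' @param cfg [estimator_config()].
#' @return a `segment_set`.
#' @export
germline_segments <- function(hap_a1, hap_a2, hap_b1, hap_b2, panel,
                              cfg = estimator_config()) {
  check_panel_sorted(panel)
  haps <- list(hap_a1, hap_a2, hap_b1, hap_b2)
  for (h in haps) {
    if (length(h) != nrow(panel)) stop_invalid("haplotypes must match panel")
    if (anyNA(h) || !all(h == 0L | h == 1L)) {
      stop_invalid("phased 0/1 haplotypes required")
    }
  }
  m <- nrow(panel)
  cov <- matrix(FALSE, nrow = 4L, ncol = m) # rows: a1b1, a1b2, a2b1, a2b2
  combo <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
  for (k in 1:4) {
    neq <- haps[[combo[[k]][1L]]] != haps[[combo[[k]][2L]]]
    runs <- chrom_runs(neq, panel, 0L)
    keep <- (panel$pos_cM[runs[, 2L]] - panel$pos_cM[runs[, 1L]]) >=
      cfg$germline_min_cM
    runs <- runs[keep, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      cov[k, runs[i, 1L]:runs[i, 2L]] <- TRUE
    }
  }
  ibd2 <- (cov[1L, ] & cov[4L, ]) | (cov[2L, ] & cov[3L, ])
  ibd1 <- !ibd2 & (cov[1L, ] | cov[2L, ] | cov[3L, ] | cov[4L, ])
  cls <- ifelse(ibd2, 2L, ifelse(ibd1, 1L, 0L))
  cb <- chrom_bounds(panel)
  out <- vector("list", nrow(cb))
  for (i in seq_len(nrow(cb))) {
    r <- rle(cls[cb$lo[i]:cb$hi[i]])
    hi <- cb$lo[i] - 1L + cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    keep <- r$values > 0L
    if (!any(keep)) next
    out[[i]] <- rbind(
      runs_to_segments(cbind(lo[keep & r$values == 1L],
                             hi[keep & r$values == 1L]), panel, "IBD1"),
      runs_to_segments(cbind(lo[keep & r$values == 2L],
                             hi[keep & r$values == 2L]), panel, "IBD2")
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_segment_set())
  as_segment_set(res)
}

#' Run all four kinship estimators on one pair
#'
#' @param geno_a,geno_b dosage vectors of the pair.
#' @param haps_a,haps_b 2-row phased haplotype matrices (or `NULL` to skip
#'   the phased detector).
#' @param panel `marker_panel`.
#' @param cfg [estimator_config()].
#' @param L_genome total map length (cM).
#' @return named numeric `c(KING=, IBIS=, TRUFFLE=, GERMLINE=)`; an
#'   estimator failure yields `NA` for that method, never an error.
#' @export
estimate_all <- function(geno_a, geno_b, haps_a = NULL, haps_b = NULL,
                         panel, cfg = estimator_config(),
                         L_genome = attr(panel, "L_genome")) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  c(
    KING = safe(king_theta(geno_a, geno_b)),
    IBIS = safe(ibis_theta(ibis_segments(geno_a, geno_b, panel, cfg),
                           L_genome, cfg)),
    TRUFFLE = safe(truffle_theta(truffle_segments(geno_a, geno_b, panel, cfg),
                                 L_genome)),
    GERMLINE = if (is.null(haps_a)) NA_real_ else safe(
      truffle_theta(germline_segments(haps_a[1L, ], haps_a[2L, ],
                                      haps_b[1L, ], haps_b[2L, ],
                                      panel, cfg), L_genome)
    )
  )
}

#' Estimate kinship for every designated pair of a cohort
#'
#' @param cohort a `kin_cohort` with genotypes.
#' @param cfg [estimator_config()].
#' @param methods subset of `c("KING", "IBIS", "TRUFFLE", "GERMLINE")`.
#' @return data.frame with the pair labels and one `theta_<METHOD>` column
#'   per requested method.
#' @export
estimate_cohort <- function(cohort, cfg = estimator_config(),
                            methods = c("KING", "IBIS", "TRUFFLE",
                                        "GERMLINE")) {
  panel <- cohort$panel
  check_panel_sorted(panel)
  attr(panel, "validated") <- TRUE
  attr(panel, "chrom_bounds") <- chrom_bounds(panel)
  if ("TRUFFLE" %in% methods) {
    attr(panel, "truffle_logp") <- truffle_site_logp(panel)
  }
  L <- attr(panel, "L_genome")
  res <- cohort$pairs
  for (m in methods) res[[paste0("theta_", m)]] <- NA_real_
  row <- 0L
  for (fam in cohort$families) {
    if (is.null(fam$genotypes)) {
      stop_invalid("cohort was simulated without genotypes")
    }
    for (p in seq_len(nrow(fam$pairs))) {
      row <- row + 1L
      a <- fam$pairs$id_a[p]; b <- fam$pairs$id_b[p]
      ga <- fam$genotypes[a, ]; gb <- fam$genotypes[b, ]
      if ("KING" %in% methods) {
        res$theta_KING[row] <- tryCatch(king_theta(ga, gb),
                                        error = function(e) NA_real_)
      }
      if ("IBIS" %in% methods) {
        res$theta_IBIS[row] <- ibis_theta(
          ibis_segments(ga, gb, panel, cfg), L, cfg
        )
      }
      if ("TRUFFLE" %in% methods) {
        res$theta_TRUFFLE[row] <- truffle_theta(
          truffle_segments(ga, gb, panel, cfg), L
        )
      }
      if ("GERMLINE" %in% methods) {
        ha <- fam$haplotypes[paste0(a, "_", 1:2), , drop = FALSE]
        hb <- fam$haplotypes[paste0(b, "_", 1:2), , drop = FALSE]
        res$theta_GERMLINE[row] <- truffle_theta(
          germline_segments(ha[1L, ], ha[2L, ], hb[1L, ], hb[2L, ],
                            panel, cfg), L
        )
      }
    }
  }
  res
}

#' Down-sample a cohort to a smaller marker panel
#'
#' Subsets the cohort panel with [subsample_panel()] and the per-family
#' genotype and haplotype matrices consistently; inheritance records are
#' untouched (true IBD does not depend on the panel).
#'
#' @param cohort a `kin_cohort`.
#' @param n_keep markers to retain.
#' @param seed integer seed.
#' @return a new `kin_cohort`.
#' @export
subsample_cohort <- function(cohort, n_keep, seed = 1) {
  sub <- subsample_panel(cohort$panel, NULL, n_keep, seed)
  out <- cohort
  out$panel <- sub$panel
  out$families <- lapply(cohort$families, function(fam) {
    fam$genotypes <- fam$genotypes[, sub$keep, drop = FALSE]
    fam$haplotypes <- fam$haplotypes[, sub$keep, drop = FALSE]
    fam
  })
  out
}
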