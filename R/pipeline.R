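# Experiment orchestration: the panel-size ladder, the genotyping-error
# ladder (with the fusion column), and the real-data entry point.

#' Panel-size grid: estimate, classify and score across marker ladders
#'
#' For each ladder size the cohort is down-sampled, all pairs are estimated
#' with the four approaches, and metrics are computed against reference
#' ranges taken from the largest rung (the reference panel).
#'
#' @param cohort a `kin_cohort` with genotypes.
#' @param ladder decreasing vector of marker counts; default the cohort's
#'   full panel followed by repeated halvings down to ~1/32.
#' @param cfg [estimator_config()].
#' @param seed seed for the subsampling.
#' @return list of class `panel_grid`: `estimates` (named list per size),
#'   `metrics` (named list of `metrics_report`), `ranges` (reference
#'   ranges), `AC` (data.frame `panel_size`, `method`, `AC`).
#' @export
run_panel_grid <- function(cohort, ladder = NULL, cfg = estimator_config(),
                           seed = 1) {
  m <- nrow(cohort$panel)
  ladder <- ladder %||% unique(pmax(round(m / 2^(0:5)), 1L))
  ladder <- sort(unique(as.integer(ladder)), decreasing = TRUE)
  if (ladder[1L] > m) stop_invalid("ladder exceeds the panel size (", m, ")")
  estimates <- metrics <- stats::setNames(
    vector("list", length(ladder)), as.character(ladder)
  )
  ranges <- NULL
  for (i in seq_along(ladder)) {
    sub <- if (ladder[i] == m) cohort else {
      subsample_cohort(cohort, ladder[i], seed = derive_seed(seed, ladder[i]))
    }
    est <- estimate_cohort(sub, cfg)
    estimates[[i]] <- est
    if (i == 1L) ranges <- suppressWarnings(reference_ranges(est))
    metrics[[i]] <- compute_metrics(est, ranges)
  }
  AC <- do.call(rbind, lapply(seq_along(ladder), function(i) {
    data.frame(panel_size = ladder[i], method = names(metrics[[i]]$AC),
               AC = unname(metrics[[i]]$AC))
  }))
  structure(list(estimates = estimates, metrics = metrics, ranges = ranges,
                 AC = AC),
            class = "panel_grid")
}

#' Error-rate grid: estimate, fuse, classify and score across error levels
#'
#' Injects genotyping errors at each ladder rate into the fixed panel,
#' estimates all pairs with the four approaches, adds the fusion column
#' predicted by `model`, and scores everything against reference ranges
#' from the error-free run.
#'
#' @param cohort a `kin_cohort` (the fixed minimum panel).
#' @param error_ladder error rates; default
#'   `c(0, 0.001, 0.005, 0.01, 0.05, 0.10)`.
#' @param cfg [estimator_config()].
#' @param composition error-type mix, see [error_spec()].
#' @param model a `combination_model` for the fusion column (default the
#'   bundled all-tool model M7); `NULL` drops the column.
#' @param seed seed for the error injection.
#' @return list of class `error_grid`: `estimates` (named list per rate,
#'   incl. `theta_COMBINATION`), `metrics`, `ranges`, `AC` (data.frame
#'   `error_rate`, `method`, `AC`).
#' @export
run_error_grid <- function(cohort,
                           error_ladder = c(0, 0.001, 0.005, 0.01, 0.05,
                                            0.10),
                           cfg = estimator_config(),
                           composition = c(1, 1, 1) / 3,
                           model = combination_models()$M7,
                           seed = 1) {
  if (any(error_ladder < 0 | error_ladder > 1)) {
    stop_invalid("error rates must be in [0, 1]")
  }
  error_ladder <- sort(unique(error_ladder))
  estimates <- metrics <- stats::setNames(
    vector("list", length(error_ladder)), as.character(error_ladder)
  )
  ranges <- NULL
  for (i in seq_along(error_ladder)) {
    rate <- error_ladder[i]
    noisy <- inject_cohort_errors(cohort, rate, composition,
                                  seed = derive_seed(seed, i))
    est <- estimate_cohort(noisy, cfg)
    if (!is.null(model)) {
      cols <- paste0("theta_", c("KING", "IBIS", "TRUFFLE", "GERMLINE"))
      ok <- stats::complete.cases(est[, cols])
      est$theta_COMBINATION <- NA_real_
      est$theta_COMBINATION[ok] <- predict_theta(
        model, build_features(est[ok, ])
      )
    }
    estimates[[i]] <- est
    if (i == 1L && rate == 0) {
      ranges <- suppressWarnings(reference_ranges(est))
    }
    metrics[[i]] <- compute_metrics(est, ranges)
  }
  AC <- do.call(rbind, lapply(seq_along(error_ladder), function(i) {
    data.frame(error_rate = error_ladder[i],
               method = names(metrics[[i]]$AC),
               AC = unname(metrics[[i]]$AC))
  }))
  structure(list(estimates = estimates, metrics = metrics, ranges = ranges,
                 AC = AC),
            class = "error_grid")
}

#' Kinship inference from real VCF genotype data
#'
#' Entry point for genotyped sample pairs: intersects the reference and
#' query VCFs on chromosome/position/alleles, applies the inclusion filters
#' (biallelic, MAF > `maf_min` estimated from all samples, Hardy-Weinberg
#' exact-test p > `hwe_min`), interpolates genetic positions from the map
#' file, computes the genotype discordance profile of each query sample
#' against its reference, and runs the four estimators (the phased detector
#' only when both VCFs are phased) plus degree classification.
#'
#' @param vcf_ref,vcf_query VCF paths; query samples are compared to the
#'   reference sample of the same name when present, otherwise to the first
#'   reference sample.
#' @param map_file genetic-map text file (see [read_genetic_map_file()]).
#' @param cfg [estimator_config()].
#' @param maf_min,hwe_min inclusion thresholds.
#' @param model fusion model for the combined estimate (default bundled M7).
#' @return data.frame with one row per (query, reference) pair: the four
#'   (or three, if unphased) estimates, the fused estimate, the inferred
#'   degree per method, and the discordance profile columns.
#' @export
real_data_entry <- function(vcf_ref, vcf_query, map_file,
                            cfg = estimator_config(),
                            maf_min = 0.05, hwe_min = 1e-6,
                            model = combination_models()$M7) {
  ref <- read_vcf_genotypes(vcf_ref)
  qry <- read_vcf_genotypes(vcf_query)
  key <- function(m) paste(m$chrom, m$pos_bp, m$ref, m$alt)
  shared <- intersect(key(ref$markers), key(qry$markers))
  if (length(shared) == 0L) stop_invalid("no overlapping markers")
  ri <- match(shared, key(ref$markers))
  qi <- match(shared, key(qry$markers))
  ord <- order(ref$markers$chrom[ri], ref$markers$pos_bp[ri])
  ri <- ri[ord]; qi <- qi[ord]

  geno <- rbind(ref$genotypes[, ri, drop = FALSE],
                qry$genotypes[, qi, drop = FALSE])
  p <- colMeans(geno, na.rm = TRUE) / 2
  hwe <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]; g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  keep <- pmin(p, 1 - p) > maf_min & hwe > hwe_min
  if (!any(keep)) stop_invalid("no markers pass the inclusion filters")
  ri <- ri[keep]; qi <- qi[keep]

  mt <- read_genetic_map_file(map_file)
  mk <- ref$markers[ri, ]
  panel <- data.frame(
    chrom = mk$chrom, pos_bp = mk$pos_bp,
    pos_cM = interpolate_cM(mt, mk$chrom, mk$pos_bp),
    ref = mk$ref, alt = mk$alt,
    alt_freq = pmin(pmax(p[keep], 0.05), 0.95)
  )
  class(panel) <- c("marker_panel", "data.frame")
  L <- sum(tapply(mt$pos_cM, mt$chrom, max))
  attr(panel, "L_genome") <- L

  phased <- ref$phased && qry$phased
  ref_ids <- rownames(ref$genotypes)
  out <- list()
  for (q in rownames(qry$genotypes)) {
    r <- if (q %in% ref_ids) q else ref_ids[1L]
    ga <- ref$genotypes[r, ri]; gb <- qry$genotypes[q, qi]
    prof <- classify_discordance(ga, gb)
    theta <- estimate_all(
      ga, gb,
      haps_a = if (phased) {
        ref$haplotypes[paste0(r, "_", 1:2), ri, drop = FALSE]
      },
      haps_b = if (phased) {
        qry$haplotypes[paste0(q, "_", 1:2), qi, drop = FALSE]
      },
      panel = panel, cfg = cfg, L_genome = L
    )
    comb <- if (!is.null(model) && !anyNA(theta)) {
      predict_theta(model, build_features(theta))
    } else NA_real_
    row <- data.frame(
      query = q, reference = r, n_markers = length(ri),
      theta_KING = theta[["KING"]], theta_IBIS = theta[["IBIS"]],
      theta_TRUFFLE = theta[["TRUFFLE"]],
      theta_GERMLINE = theta[["GERMLINE"]],
      theta_COMBINATION = comb,
      discordance = prof$overall_rate,
      drop_in = prof$rates[["drop_in"]],
      drop_out = prof$rates[["drop_out"]],
      switch = prof$rates[["switch"]]
    )
    for (m in c("KING", "IBIS", "TRUFFLE", "GERMLINE", "COMBINATION")) {
      th <- row[[paste0("theta_", m)]]
      row[[paste0("degree_", m)]] <- if (is.na(th)) NA_character_ else {
        classify_degree(th)
      }
    }
    out[[q]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
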