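# Independent reference implementations (naive quadratic scanners) and small
# memoised fixtures shared across test files.

theory_theta <- c(
  "1st" = 1 / 4, "2nd" = 1 / 8, "3rd" = 1 / 16, "4th" = 1 / 32,
  "5th" = 1 / 64, "6th" = 1 / 128, "7th" = 1 / 256, "unrelated" = 0
)

# --- naive run machinery -----------------------------------------------------

# Non-bridged incompatible sites: an incompatible site survives as a break
# unless no other incompatible site lies within `window` markers.
naive_breaks <- function(bad_idx, window) {
  if (window <= 0L || length(bad_idx) == 0L) return(bad_idx)
  keep <- vapply(seq_along(bad_idx), function(i) {
    any(abs(bad_idx[-i] - bad_idx[i]) <= window)
  }, logical(1))
  bad_idx[keep]
}

# Quadratic maximal-run enumeration over an ok/break profile within [lo, hi].
naive_max_runs <- function(ok, lo, hi) {
  runs <- NULL
  for (i in lo:hi) {
    if (ok[i] && (i == lo || !ok[i - 1L])) {
      j <- i
      while (j < hi && ok[j + 1L]) j <- j + 1L
      runs <- rbind(runs, c(i, j))
    }
  }
  if (is.null(runs)) matrix(integer(0), ncol = 2L) else runs
}

naive_runs <- function(bad, panel, window) {
  cb <- kinfuse:::chrom_bounds(panel)
  out <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(nrow(cb))) {
    lo <- cb$lo[k]; hi <- cb$hi[k]
    idx <- lo - 1L + which(bad[lo:hi])
    idx <- naive_breaks(idx, window)
    ok <- rep(TRUE, length(bad)); ok[idx] <- FALSE
    out <- rbind(out, naive_max_runs(ok, lo, hi))
  }
  out
}

# Per-marker coverage -> maximal class runs, rebuilt site by site.
naive_class_segments <- function(cov1, cov2, panel) {
  cls <- ifelse(cov2, 2L, ifelse(cov1, 1L, 0L))
  cb <- kinfuse:::chrom_bounds(panel)
  segs <- NULL
  for (k in seq_len(nrow(cb))) {
    for (val in 1:2) {
      ok <- cls == val
      runs <- naive_max_runs(ok, cb$lo[k], cb$hi[k])
      if (nrow(runs)) {
        segs <- rbind(segs, kinfuse:::runs_to_segments(
          runs, panel, c("IBD1", "IBD2")[val]
        ))
      }
    }
  }
  if (is.null(segs)) kinfuse:::empty_segment_set() else segs
}

sort_segments <- function(s) {
  s <- as.data.frame(s)
  s <- s[order(s$class, s$chrom, s$start_bp), ]
  rownames(s) <- NULL
  s
}

# --- naive detectors ---------------------------------------------------------

naive_ibis <- function(ga, gb, panel, cfg) {
  opp <- (ga == 0L & gb == 2L) | (ga == 2L & gb == 0L)
  runs <- naive_runs(opp, panel, cfg$ibis_bridge_markers)
  ok <- function(r) {
    (r[2L] - r[1L] + 1L) >= cfg$ibis_min_markers &&
      (panel$pos_cM[r[2L]] - panel$pos_cM[r[1L]]) >= cfg$ibis_min_cM
  }
  runs <- runs[apply(runs, 1L, ok), , drop = FALSE]
  cov1 <- rep(FALSE, nrow(panel))
  for (i in seq_len(nrow(runs))) cov1[runs[i, 1L]:runs[i, 2L]] <- TRUE
  cov2 <- rep(FALSE, nrow(panel))
  if (cfg$ibis_ibd2) {
    neq <- ga != gb
    runs2 <- naive_runs(neq, panel, 0L)
    runs2 <- runs2[apply(runs2, 1L, ok), , drop = FALSE]
    for (i in seq_len(nrow(runs2))) cov2[runs2[i, 1L]:runs2[i, 2L]] <- TRUE
  }
  naive_class_segments(cov1 & !cov2, cov2, panel)
}

naive_truffle <- function(ga, gb, panel, cfg) {
  p <- panel$alt_freq; q <- 1 - p
  pc1 <- 1 - 2 * p^2 * q^2
  pc2 <- q^4 + (2 * p * q)^2 + p^4
  w <- cfg$truffle_bridge_markers
  accept <- function(r, pc, min_mb) {
    (panel$pos_bp[r[2L]] - panel$pos_bp[r[1L]]) >= min_mb * 1e6 &&
      sum(log10(pc[r[1L]:r[2L]])) < log10(cfg$truffle_pmatch)
  }
  opp <- (ga == 0L & gb == 2L) | (ga == 2L & gb == 0L)
  runs1 <- naive_runs(opp, panel, w)
  runs1 <- runs1[apply(runs1, 1L, accept, pc = pc1,
                       min_mb = cfg$truffle_min_Mb_ibd1), , drop = FALSE]
  neq <- ga != gb
  runs2 <- naive_runs(neq, panel, w)
  runs2 <- runs2[apply(runs2, 1L, accept, pc = pc2,
                       min_mb = cfg$truffle_min_Mb_ibd2), , drop = FALSE]
  cov1 <- cov2 <- rep(FALSE, nrow(panel))
  for (i in seq_len(nrow(runs1))) cov1[runs1[i, 1L]:runs1[i, 2L]] <- TRUE
  for (i in seq_len(nrow(runs2))) cov2[runs2[i, 1L]:runs2[i, 2L]] <- TRUE
  naive_class_segments(cov1 & !cov2, cov2, panel)
}

naive_germline <- function(a1, a2, b1, b2, panel, cfg) {
  cov <- matrix(FALSE, 4L, nrow(panel))
  combos <- list(list(a1, b1), list(a1, b2), list(a2, b1), list(a2, b2))
  for (k in 1:4) {
    neq <- combos[[k]][[1L]] != combos[[k]][[2L]]
    runs <- naive_runs(neq, panel, 0L)
    runs <- runs[
      panel$pos_cM[runs[, 2L]] - panel$pos_cM[runs[, 1L]] >=
        cfg$germline_min_cM, , drop = FALSE
    ]
    for (i in seq_len(nrow(runs))) cov[k, runs[i, 1L]:runs[i, 2L]] <- TRUE
  }
  ibd2 <- (cov[1L, ] & cov[4L, ]) | (cov[2L, ] & cov[3L, ])
  ibd1 <- !ibd2 & (cov[1L, ] | cov[2L, ] | cov[3L, ] | cov[4L, ])
  naive_class_segments(ibd1, ibd2, panel)
}

# --- randomised detector instances ------------------------------------------

random_detector_instance <- function(seed) {
  kinfuse:::with_seed(seed, {
    n_chrom <- sample(1:3, 1L)
    map <- generate_map(n_chrom, total_cM = stats::runif(1, 60, 180) * n_chrom,
                        bp_per_cM = 1e6)
    m <- sample(100:1000, 1L)
    fd <- generate_founders(2L, m, map, seed = sample.int(1e6, 1L))
    haps <- fd$haplotypes
    for (s in seq_len(sample(0:3, 1L))) {
      len <- sample(20:min(200L, m - 1L), 1L)
      start <- sample.int(m - len, 1L)
      cols <- start:(start + len - 1L)
      haps[sample(3:4, 1L), cols] <- haps[sample(1:2, 1L), cols]
    }
    cfg <- estimator_config(
      ibis_min_cM = stats::runif(1, 0.5, 4),
      ibis_min_markers = sample(5:60, 1L),
      ibis_bridge_markers = sample(c(0L, 15L), 1L),
      ibis_ibd2 = sample(c(TRUE, FALSE), 1L),
      truffle_pmatch = 10^-stats::runif(1, 2, 6),
      truffle_min_Mb_ibd1 = stats::runif(1, 1, 6),
      truffle_min_Mb_ibd2 = stats::runif(1, 0.5, 3),
      truffle_bridge_markers = sample(c(0L, 15L), 1L),
      germline_min_cM = stats::runif(1, 1, 4)
    )
    list(panel = fd$panel, haps = haps,
         ga = haps[1L, ] + haps[2L, ], gb = haps[3L, ] + haps[4L, ],
         cfg = cfg)
  })
}

# --- shared small fixtures ---------------------------------------------------

.fixtures <- new.env(parent = emptyenv())

small_map <- function() {
  if (is.null(.fixtures$map)) .fixtures$map <- generate_map()
  .fixtures$map
}

# Two families on an 8 K panel: enough for pipeline and I/O tests.
small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    map <- small_map()
    fd <- generate_founders(22L, 8000L, map, seed = 42)
    .fixtures$cohort <- run_cohort(fd, fd$panel, map, n_replicates = 1L,
                                   seed = 99)
  }
  .fixtures$cohort
}

small_cohort_estimates <- function() {
  if (is.null(.fixtures$est)) {
    .fixtures$est <- estimate_cohort(small_cohort())
  }
  .fixtures$est
}

# Two-chromosome genome at reference marker density (~50 markers/cM): the
# regime where segment detectors are calibrated.
dense_fixture <- function() {
  if (is.null(.fixtures$dense)) {
    map <- generate_map(2L, 300, 1e6)
    fd <- generate_founders(22L, 15000L, map, seed = 55)
    .fixtures$dense <- list(
      map = map, panel = fd$panel,
      cohort = run_cohort(fd, fd$panel, map, n_replicates = 1L, seed = 77)
    )
  }
  .fixtures$dense
}

# Hand-built single-chromosome panel with given cM positions and frequencies.
toy_panel <- function(pos_cM, freq = 0.5, chrom_cM = max(pos_cM) + 1) {
  map <- generate_map(1L, chrom_cM, 1e6)
  kinfuse:::new_marker_panel(data.frame(
    chrom = 1L, pos_bp = pos_cM * 1e6, pos_cM = pos_cM,
    ref = "A", alt = "G", alt_freq = rep_len(freq, length(pos_cM))
  ), map)
}

# Genetic length of true IBD1 segments >= min_cM recovered by a detector
# segment set (length-weighted, interval intersection in cM).
recall_cM <- function(truth, detected, min_cM = 5) {
  truth <- truth[truth$class == "IBD1" &
                   truth$end_cM - truth$start_cM >= min_cM, , drop = FALSE]
  tot <- sum(truth$end_cM - truth$start_cM)
  if (tot == 0) return(NA_real_)
  got <- 0
  for (i in seq_len(nrow(truth))) {
    d <- detected[detected$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(d) == 0L) next
    got <- got + sum(pmax(0, pmin(d$end_cM, truth$end_cM[i]) -
                            pmax(d$start_cM, truth$start_cM[i])))
  }
  c(recall = got / tot, total = tot)
}
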