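test_that("the IBS-count kinship estimator matches hand counts", {
  # self-comparison with h heterozygous sites: theta = h / 2h = 0.5
  g <- c(0L, 1L, 2L, 1L, 1L, 0L)
  expect_equal(king_theta(g, g), 0.5)

  # 6-site toy, hand-counted: N_AaAa=1, N_AAaa=1, hets 3 and 1
  a <- c(1L, 1L, 0L, 2L, 1L, 0L)
  b <- c(1L, 0L, 0L, 0L, 2L, 0L)
  expect_equal(king_theta(a, b), (1 - 2 * 1) / (3 + 1))

  expect_error(king_theta(c(NA, NA), c(0L, 1L)), "non-missing")
  expect_true(is.na(king_theta(c(0L, 2L, 0L), c(0L, 2L, 2L))))

  # unrelated founders: mean estimate within 3 SE of zero
  dense <- dense_fixture()
  fam <- dense$cohort$families[[1L]]
  fids <- fam$members$id[fam$members$founder]
  th <- vapply(1:10, function(i) {
    king_theta(fam$genotypes[fids[i], ], fam$genotypes[fids[i + 1L], ])
  }, numeric(1))
  expect_lt(abs(mean(th)), 3 * stats::sd(th) / sqrt(length(th)))
})

test_that("IBS-run detection applies both the cM and marker-count minima", {
  cfg <- estimator_config(ibis_ibd2 = FALSE)
  # 185 perfectly-shared markers spanning 3 cM: marker criterion fails
  p185 <- toy_panel(seq(0.5, 3.5, length.out = 185))
  g <- rep(1L, 185)
  expect_equal(nrow(ibis_segments(g, g, p185, cfg)), 0L)
  # one more marker and the same span passes
  p186 <- toy_panel(seq(0.5, 3.5, length.out = 186))
  seg <- ibis_segments(rep(1L, 186), rep(1L, 186), p186, cfg)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_markers, 186L)
  # 186 markers spanning under 2 cM: length criterion fails
  p_short <- toy_panel(seq(0.5, 2.3, length.out = 186))
  expect_equal(nrow(ibis_segments(rep(1L, 186), rep(1L, 186), p_short, cfg)),
               0L)

  # parent-offspring pairs admit no opposite homozygotes: near-full coverage
  dense <- dense_fixture()
  fam <- dense$cohort$families[[1L]]
  pre <- paste0(fam$id, "_")
  seg <- ibis_segments(fam$genotypes[paste0(pre, "C1"), ],
                       fam$genotypes[paste0(pre, "D1"), ],
                       dense$panel, estimator_config())
  expect_gte(sum(segment_lengths(seg)), 0.99 * L_genome(dense$map))
})

test_that("kinship from IBS-run segments includes the supplemental constant", {
  empty <- kinfuse:::empty_segment_set()
  expect_equal(ibis_theta(empty, 3346.30), 0.00138)
  full <- kinfuse:::as_segment_set(data.frame(
    chrom = 1L, start_bp = 0, end_bp = 3346.30e6, start_cM = 0,
    end_cM = 3346.30, class = "IBD1", n_markers = 1000L
  ))
  expect_equal(ibis_theta(full, 3346.30), 0.25 + 0.00138)
  expect_gte(ibis_theta(empty, 3346.30), 0)
})

test_that("Cotterman conversion reproduces the printed formulas", {
  mk <- function(L1, L2) {
    rows <- data.frame(
      chrom = 1L, start_bp = 0, end_bp = c(L1, L2) * 1e6, start_cM = 0,
      end_cM = c(L1, L2), class = c("IBD1", "IBD2"), n_markers = 1L
    )
    kinfuse:::as_segment_set(rows[rows$end_cM > 0, , drop = FALSE])
  }
  expect_equal(
    cotterman_from_segments(mk(1673.15, 0), 3346.30)[["k1"]], 0.5
  )
  expect_equal(
    unname(cotterman_from_segments(kinfuse:::empty_segment_set(), 3346.30)),
    c(1, 0, 0)
  )
  expect_equal(
    unname(cotterman_from_segments(mk(0, 3346.30), 3346.30)), c(0, 0, 1)
  )
  k <- cotterman_from_segments(mk(500, 700), 3346.30)
  expect_equal(sum(k), 1)
  expect_error(cotterman_from_segments(mk(10, 10), -1), "positive")
  expect_warning(cotterman_from_segments(mk(3000, 3000), 3346.30), "clipping")

  # theta = kappa2/2 + kappa1/4 at the three pure configurations
  expect_equal(truffle_theta(mk(0, 3346.30), 3346.30), 0.5)
  expect_equal(truffle_theta(mk(3346.30, 0), 3346.30), 0.25)
  expect_equal(truffle_theta(kinfuse:::empty_segment_set(), 3346.30), 0)
})

test_that("probability-thresholded detection needs 138 half-frequency markers", {
  # (7/8)^138 < 1e-8 <= (7/8)^137  (closed-form logarithm oracle)
  expect_lt(138 * log10(7 / 8), -8)
  expect_gte(137 * log10(7 / 8), -8)

  cfg <- estimator_config(truffle_bridge_markers = 0L)
  run_panel <- function(n_interior) {
    m <- n_interior + 2L
    toy_panel(seq(0, by = 0.05, length.out = m), freq = 0.5,
              chrom_cM = 0.05 * m + 1)
  }
  make_pair <- function(n_interior) {
    m <- n_interior + 2L
    ga <- rep(0L, m)
    gb <- c(2L, rep(1L, n_interior), 2L) # opposite-homozygote flanks
    list(ga = ga, gb = gb)
  }
  p137 <- make_pair(137L)
  expect_equal(
    nrow(truffle_segments(p137$ga, p137$gb, run_panel(137L), cfg)), 0L
  )
  p138 <- make_pair(138L)
  seg <- truffle_segments(p138$ga, p138$gb, run_panel(138L), cfg)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$class, "IBD1")
  expect_equal(seg$n_markers, 138L)
})

test_that("probability-thresholded detection enforces physical length minima", {
  cfg <- estimator_config(truffle_bridge_markers = 0L)
  # 251 compatible markers over 4 Mb: probability passes, 5 Mb IBD1 floor
  # does not
  panel <- toy_panel(seq(0, 4, length.out = 251), freq = 0.5, chrom_cM = 5)
  ga <- rep(0L, 251)
  gb <- rep(1L, 251)
  expect_lt(251 * log10(7 / 8), -8)
  expect_equal(nrow(truffle_segments(ga, gb, panel, cfg)), 0L)
  # identical genotypes over the same span qualify as IBD2 (2 Mb floor)
  seg <- truffle_segments(ga, ga, panel, cfg)
  expect_equal(seg$class, "IBD2")

  # identical individuals at reference density: kappa2 ~ 1
  dense <- dense_fixture()
  fam <- dense$cohort$families[[1L]]
  g <- fam$genotypes[1L, ]
  seg <- truffle_segments(g, g, dense$panel, estimator_config())
  kappa <- cotterman_from_segments(seg, L_genome(dense$map))
  expect_gt(kappa[["k2"]], 0.98)
})

test_that("phased exact-match detection respects phase and length threshold", {
  dense <- dense_fixture()
  fam <- dense$cohort$families[[1L]]
  pre <- paste0(fam$id, "_")
  cfg <- estimator_config()
  hp <- function(id) fam$haplotypes[paste0(pre, id, "_", 1:2), , drop = FALSE]

  # parent-offspring: the transmitted haplotype matches everywhere
  seg <- germline_segments(hp("C1")[1L, ], hp("C1")[2L, ],
                           hp("D1")[1L, ], hp("D1")[2L, ], dense$panel, cfg)
  expect_gte(sum(segment_lengths(seg)), 0.99 * L_genome(dense$map))

  # unrelated founders at reference density: no match survives 3 cM
  fids <- fam$members$id[fam$members$founder]
  n_hit <- 0L
  for (i in 1:10) {
    ha <- fam$haplotypes[paste0(fids[i], "_", 1:2), , drop = FALSE]
    hb <- fam$haplotypes[paste0(fids[i + 1L], "_", 1:2), , drop = FALSE]
    s <- germline_segments(ha[1L, ], ha[2L, ], hb[1L, ], hb[2L, ],
                           dense$panel, cfg)
    n_hit <- n_hit + (nrow(s) > 0L)
  }
  expect_lte(n_hit, 1L)

  expect_error(
    germline_segments(rep(2L, 10), rep(0L, 10), rep(0L, 10), rep(0L, 10),
                      toy_panel(1:10 / 10)),
    "phased"
  )
})

test_that("all three detectors match their naive quadratic references", {
  for (seed in 101:112) {
    inst <- random_detector_instance(seed)
    expect_equal(
      sort_segments(ibis_segments(inst$ga, inst$gb, inst$panel, inst$cfg)),
      sort_segments(naive_ibis(inst$ga, inst$gb, inst$panel, inst$cfg)),
      info = paste("ibis seed", seed)
    )
    expect_equal(
      sort_segments(truffle_segments(inst$ga, inst$gb, inst$panel, inst$cfg)),
      sort_segments(naive_truffle(inst$ga, inst$gb, inst$panel, inst$cfg)),
      info = paste("truffle seed", seed)
    )
    expect_equal(
      sort_segments(germline_segments(inst$haps[1L, ], inst$haps[2L, ],
                                      inst$haps[3L, ], inst$haps[4L, ],
                                      inst$panel, inst$cfg)),
      sort_segments(naive_germline(inst$haps[1L, ], inst$haps[2L, ],
                                   inst$haps[3L, ], inst$haps[4L, ],
                                   inst$panel, inst$cfg)),
      info = paste("germline seed", seed)
    )
  }
})

test_that("detectors recover long true IBD1 segments at reference density", {
  dense <- dense_fixture()
  cohort <- dense$cohort
  cfg <- estimator_config()
  for (fam in cohort$families) {
    pre <- paste0(fam$id, "_")
    for (pair in list(c("C2", "D1"), c("C1", "E1"))) { # uncle, grandparent
      a <- paste0(pre, pair[1L]); b <- paste0(pre, pair[2L])
      truth <- true_ibd_segments(fam$record, a, b)
      ga <- fam$genotypes[a, ]; gb <- fam$genotypes[b, ]
      ha <- fam$haplotypes[paste0(a, "_", 1:2), , drop = FALSE]
      hb <- fam$haplotypes[paste0(b, "_", 1:2), , drop = FALSE]
      dets <- list(
        ibis_segments(ga, gb, dense$panel, cfg),
        truffle_segments(ga, gb, dense$panel, cfg),
        germline_segments(ha[1L, ], ha[2L, ], hb[1L, ], hb[2L, ],
                          dense$panel, cfg)
      )
      for (d in dets) {
        r <- recall_cM(truth, d, min_cM = 5)
        if (!is.na(r[1L])) expect_gte(r[["recall"]], 0.95)
      }
    }
  }
})

test_that("kinship is monotone in added qualifying IBD1 length", {
  base <- kinfuse:::as_segment_set(data.frame(
    chrom = 1L, start_bp = 0, end_bp = 100e6, start_cM = 0, end_cM = 100,
    class = "IBD1", n_markers = 100L
  ))
  extra <- kinfuse:::as_segment_set(data.frame(
    chrom = 2L, start_bp = 0, end_bp = 50e6, start_cM = 0, end_cM = 50,
    class = "IBD1", n_markers = 50L
  ))
  both <- rbind(base, extra)
  expect_gt(truffle_theta(both, 3346.30), truffle_theta(base, 3346.30))
  expect_gt(ibis_theta(both, 3346.30), ibis_theta(base, 3346.30))
})

test_that("estimate_all handles self pairs, founder pairs and determinism", {
  dense <- dense_fixture()
  fam <- dense$cohort$families[[2L]]
  cfg <- estimator_config()
  L <- L_genome(dense$map)
  id <- fam$members$id[1L]
  haps <- fam$haplotypes[paste0(id, "_", 1:2), , drop = FALSE]
  self <- estimate_all(fam$genotypes[id, ], fam$genotypes[id, ],
                       haps, haps, dense$panel, cfg, L)
  expect_equal(self[["KING"]], 0.5)
  expect_equal(self[["IBIS"]], 0.5 + 0.00138, tolerance = 0.02)
  expect_equal(self[["TRUFFLE"]], 0.5, tolerance = 0.02)
  expect_equal(self[["GERMLINE"]], 0.5, tolerance = 0.02)

  f <- fam$members$id[fam$members$founder][1:2]
  fa <- fam$haplotypes[paste0(f[1L], "_", 1:2), , drop = FALSE]
  fb <- fam$haplotypes[paste0(f[2L], "_", 1:2), , drop = FALSE]
  unrel <- estimate_all(fam$genotypes[f[1L], ], fam$genotypes[f[2L], ],
                        fa, fb, dense$panel, cfg, L)
  expect_equal(unrel[["TRUFFLE"]], 0)
  expect_equal(unrel[["GERMLINE"]], 0)
  expect_lt(abs(unrel[["KING"]]), 0.02)

  again <- estimate_all(fam$genotypes[f[1L], ], fam$genotypes[f[2L], ],
                        fa, fb, dense$panel, cfg, L)
  expect_identical(unrel, again)
})
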