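# Genotyping-error injection and discordance classification.  Three error
# types are modelled on biallelic genotypes: drop-in (an extra allele turns a
# homozygote into a heterozygote), drop-out (a lost allele turns a
# heterozygote into a homozygote) and switch (opposite homozygotes).

#' Genotyping-error specification
#'
#' @param rate per-genotype perturbation probability in `[0, 1]`.
#' @param composition nonnegative weights `c(drop_in, drop_out, switch)`
#'   summing to 1.  At a perturbed genotype the error type is drawn from the
#'   composition restricted to the types applicable to that genotype class
#'   (homozygote: drop-in or switch; heterozygote: drop-out); if no
#'   applicable type has positive weight the genotype is left unchanged.
#' @param seed integer seed.
#' @return list of class `error_spec`.
#' @export
error_spec <- function(rate, composition = c(drop_in = 1, drop_out = 1,
                                             switch = 1) / 3, seed = 1) {
  if (rate < 0 || rate > 1) stop_invalid("rate must be in [0, 1]")
  composition <- unlist(composition)
  if (length(composition) != 3L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9) {
    stop_invalid("composition must be three nonnegative weights summing to 1")
  }
  names(composition) <- c("drop_in", "drop_out", "switch")
  structure(list(rate = rate, composition = composition, seed = seed),
            class = "error_spec")
}

# Perturb a dosage vector in place; returns list(geno, changed index, new
# value) so haplotypes can be updated consistently.
perturb_genotypes <- function(g, spec) {
  n <- length(g)
  hit <- which(stats::runif(n) < spec$rate & !is.na(g))
  if (length(hit) == 0L) {
    return(list(geno = g, idx = integer(0), new = integer(0)))
  }
  w <- spec$composition
  gh <- g[hit]
  new <- gh
  hom <- gh != 1L
  # homozygotes: choose drop-in vs switch with renormalised weights
  if (any(hom)) {
    wa <- w[c("drop_in", "switch")]
    if (sum(wa) > 0) {
      di <- stats::runif(sum(hom)) < wa[1L] / sum(wa)
      new[hom] <- ifelse(di, 1L, 2L - gh[hom])
    }
  }
  # heterozygotes: drop-out to a random homozygote (if drop-out has mass)
  het <- !hom
  if (any(het) && w[["drop_out"]] > 0) {
    new[het] <- ifelse(stats::runif(sum(het)) < 0.5, 0L, 2L)
  }
  changed <- new != gh
  g[hit[changed]] <- new[changed]
  list(geno = g, idx = hit[changed], new = new[changed])
}

#' Inject genotyping errors into a genotype matrix
#'
#' Each genotype is independently perturbed with probability `spec$rate`;
#' the error type is drawn from the composition restricted to the types
#' applicable to the genotype class.  Missing calls are never created and
#' never perturbed.  Deterministic under `spec$seed`.
#'
#' @param genotypes dosage matrix (individuals x markers) or vector.
#' @param spec an [error_spec()].
#' @return perturbed object of the same shape.
#' @export
inject_errors <- function(genotypes, spec) {
  stopifnot(inherits(spec, "error_spec"))
  with_seed(spec$seed, {
    if (is.matrix(genotypes)) {
      out <- genotypes
      for (i in seq_len(nrow(genotypes))) {
        out[i, ] <- perturb_genotypes(genotypes[i, ], spec)$geno
      }
      out
    } else {
      perturb_genotypes(genotypes, spec)$geno
    }
  })
}

# Inject errors into a family, keeping phased haplotypes consistent with the
# perturbed genotypes (true phase retained away from perturbed sites;
# drop-in assigns the extra allele to a random strand).
inject_errors_family <- function(fam, spec) {
  with_seed(spec$seed, {
    for (i in seq_len(nrow(fam$genotypes))) {
      res <- perturb_genotypes(fam$genotypes[i, ], spec)
      fam$genotypes[i, ] <- res$geno
      if (length(res$idx) && !is.null(fam$haplotypes)) {
        r1 <- 2L * (i - 1L) + 1L; r2 <- r1 + 1L
        new <- res$new
        h1 <- fam$haplotypes[r1, res$idx]
        h1[new == 0L] <- 0L; h1[new == 2L] <- 1L
        h2 <- fam$haplotypes[r2, res$idx]
        h2[new == 0L] <- 0L; h2[new == 2L] <- 1L
        if (any(new == 1L)) {
          strand1 <- stats::runif(sum(new == 1L)) < 0.5
          h1[new == 1L] <- ifelse(strand1, 1L, 0L)
          h2[new == 1L] <- ifelse(strand1, 0L, 1L)
        }
        fam$haplotypes[r1, res$idx] <- h1
        fam$haplotypes[r2, res$idx] <- h2
      }
    }
    fam
  })
}

#' Inject genotyping errors into every family of a cohort
#'
#' Applies [inject_errors()] to each family's genotype matrix with a seed
#' derived per family, updating the phased haplotypes consistently (the
#' phased detector then sees the erroneous data under retained true phase).
#'
#' @param cohort a `kin_cohort`.
#' @param rate per-genotype error rate.
#' @param composition see [error_spec()].
#' @param seed integer seed.
#' @return a new `kin_cohort` with perturbed genotypes and haplotypes.
#' @export
inject_cohort_errors <- function(cohort, rate,
                                 composition = c(1, 1, 1) / 3, seed = 1) {
  if (rate == 0) return(cohort)
  out <- cohort
  out$families <- lapply(seq_along(cohort$families), function(i) {
    inject_errors_family(
      cohort$families[[i]],
      error_spec(rate, composition, seed = derive_seed(seed, i))
    )
  })
  out
}

#' Inject phase-switch errors into phased haplotypes
#'
#' Optional degradation of true phase: at every heterozygous site the two
#' strands are swapped from that site to the chromosome end with probability
#' `rate`, emulating statistical-phasing switch errors.  Genotypes are
#' unaffected.
#'
#' @param haplotypes 2-row phased matrix of one individual.
#' @param panel `marker_panel` (chromosome boundaries).
#' @param rate per-heterozygous-site switch probability.
#' @param seed integer seed.
#' @return phased matrix of the same shape.
#' @export
inject_phase_errors <- function(haplotypes, panel, rate, seed = 1) {
  stopifnot(nrow(haplotypes) == 2L)
  with_seed(seed, {
    het <- haplotypes[1L, ] != haplotypes[2L, ]
    sw <- het & stats::runif(ncol(haplotypes)) < rate
    cb <- chrom_bounds(panel)
    for (i in seq_len(nrow(cb))) {
      cols <- cb$lo[i]:cb$hi[i]
      flip <- cumsum(sw[cols]) %% 2L == 1L
      if (any(flip)) {
        tmp <- haplotypes[1L, cols][flip]
        haplotypes[1L, cols][flip] <- haplotypes[2L, cols][flip]
        haplotypes[2L, cols][flip] <- tmp
      }
    }
    haplotypes
  })
}

#' Classify genotype discordances between aligned call sets
#'
#' Site-wise comparison of a reference and a test genotype matrix (or
#' vector) aligned on identical markers and individuals: a homozygote called
#' heterozygous (retaining one reference allele) is a drop-in, a
#' heterozygote called homozygous is a drop-out, and opposite homozygotes
#' are a switch.  Sites with a missing call in either set are counted
#' separately and excluded from the rate denominator.
#'
#' @param ref_genotypes,test_genotypes aligned dosage objects of equal shape.
#' @return list of class `error_profile`: `counts` (drop_in, drop_out,
#'   switch, concordant, missing), `rates` (per compared genotype) and
#'   `overall_rate`.
#' @export
classify_discordance <- function(ref_genotypes, test_genotypes) {
  if (length(ref_genotypes) != length(test_genotypes)) {
    stop_invalid("call sets must be aligned on identical markers/individuals")
  }
  r <- as.vector(ref_genotypes); t <- as.vector(test_genotypes)
  missing <- is.na(r) | is.na(t)
  r <- r[!missing]; t <- t[!missing]
  counts <- c(
    drop_in = sum(r != 1L & t == 1L),
    drop_out = sum(r == 1L & t != 1L),
    switch = sum((r == 0L & t == 2L) | (r == 2L & t == 0L)),
    concordant = sum(r == t),
    missing = sum(missing)
  )
  compared <- length(r)
  rates <- counts[1:3] / max(compared, 1L)
  structure(
    list(counts = counts, compared = compared, rates = rates,
         overall_rate = sum(rates)),
    class = "error_profile"
  )
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "Genotype discordance over %d compared sites: %.4f overall\n",
    x$compared, x$overall_rate
  ))
  print(round(x$rates, 5))
  invisible(x)
}
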