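# Gamete-dropping simulation: Poisson crossovers (no interference) on the
# sex-averaged map, founder-haplotype labels tracked exactly so that true IBD
# segments are available as ground truth for the detectors.
#
# A haplotype on one chromosome is a step function over (0, L] cM stored as
# list(ends, labs): segment j covers (ends[j-1], ends[j]] and carries the
# founder-haplotype label labs[j] (1..22 within a family).

# Segments of `h` intersected with (a, b].
slice_hap <- function(h, a, b) {
  j_lo <- findInterval(a, h$ends) + 1L
  j_hi <- findInterval(b, h$ends, left.open = TRUE) + 1L
  idx <- j_lo:j_hi
  list(ends = pmin(h$ends[idx], b), labs = h$labs[idx])
}

merge_runs <- function(ends, labs) {
  if (length(labs) > 1L) {
    keep <- c(labs[-length(labs)] != labs[-1L], TRUE)
    ends <- ends[keep]; labs <- labs[keep]
  }
  list(ends = ends, labs = labs)
}

# One meiosis on one chromosome: crossover count ~ Poisson(L/100),
# breakpoints uniform in cM, starting strand random.
meiosis_chrom <- function(h1, h2, L) {
  nx <- stats::rpois(1L, L / 100)
  cuts <- if (nx > 0L) sort(stats::runif(nx, 0, L)) else numeric(0)
  cuts <- cuts[cuts > 0 & cuts < L]
  src <- sample.int(2L, 1L)
  ends <- numeric(0); labs <- integer(0)
  a <- 0
  for (b in c(cuts, L)) {
    piece <- slice_hap(if (src == 1L) h1 else h2, a, b)
    ends <- c(ends, piece$ends); labs <- c(labs, piece$labs)
    a <- b; src <- 3L - src
  }
  merge_runs(ends, labs)
}

#' Simulate one family by gamete dropping
#'
#' Fills the 11 founder slots of the pedigree template with the given founder
#' individuals and drops gametes down the pedigree: each non-founder haplotype
#' is a recombinant mosaic of its parent's two haplotypes with a
#' `Poisson(length_cM / 100)` crossover count per chromosome and uniformly
#' placed breakpoints.  Founder origin is tracked exactly in an inheritance
#' record, from which true IBD segments can be extracted.
#'
#' @param ped pedigree template (see [template_pedigree()]).
#' @param founder_ids character ids of the pool individuals filling the
#'   founder slots, in `ped$founders` order.
#' @param founder_haps integer 0/1 matrix with `2 * length(founder_ids)` rows
#'   (two consecutive rows per founder) and one column per marker, or `NULL`
#'   when `genotypes = FALSE`.
#' @param panel `marker_panel` giving marker positions (or `NULL`).
#' @param map `genetic_map` used for chromosome lengths.
#' @param seed integer seed; the whole family is deterministic given it.
#' @param prefix id prefix distinguishing families in a cohort.
#' @param genotypes logical; if `FALSE` only the inheritance record is built
#'   (cheap path for design-count and true-IBD work).
#' @return object of class `family_sim`: list with `id`, `members`
#'   (data.frame `id`, `node`, `founder` flag, `source` pool id),
#'   `genotypes` (members x markers dosage 0/1/2), `haplotypes`
#'   (2 x members rows), `record` (class `inheritance_record`) and `pairs`
#'   (the 30 designated pairs with prefixed ids and true degree).
#' @export
simulate_family <- function(ped, founder_ids, founder_haps = NULL,
                            panel = NULL, map, seed = 1, prefix = "F1_",
                            genotypes = TRUE) {
  if (length(founder_ids) != length(ped$founders)) {
    stop_invalid("need exactly ", length(ped$founders),
                 " founder individuals to fill the pedigree slots")
  }
  if (genotypes && (is.null(founder_haps) || is.null(panel))) {
    stop_invalid("founder_haps and panel are required when genotypes = TRUE")
  }
  if (genotypes && nrow(founder_haps) != 2L * length(founder_ids)) {
    stop_invalid("founder_haps must have two rows per founder")
  }
  nodes <- ped$nodes
  depth <- pedigree_depth(ped)
  order_ids <- nodes$id[order(depth[nodes$id])]
  L <- map$length_cM
  n_chrom <- nrow(map)

  with_seed(seed, {
    haps <- vector("list", nrow(nodes)); names(haps) <- nodes$id
    slot <- match(nodes$id, ped$founders)
    for (id in order_ids) {
      i <- match(id, nodes$id)
      if (!is.na(slot[i])) {
        lab1 <- 2L * (slot[i] - 1L) + 1L
        haps[[id]] <- lapply(seq_len(n_chrom), function(c) {
          list(
            h1 = list(ends = L[c], labs = lab1),
            h2 = list(ends = L[c], labs = lab1 + 1L)
          )
        })
      } else {
        fa <- haps[[nodes$father[i]]]
        mo <- haps[[nodes$mother[i]]]
        haps[[id]] <- lapply(seq_len(n_chrom), function(c) {
          list(
            h1 = meiosis_chrom(fa[[c]]$h1, fa[[c]]$h2, L[c]),
            h2 = meiosis_chrom(mo[[c]]$h1, mo[[c]]$h2, L[c])
          )
        })
      }
    }

    member_ids <- paste0(prefix, nodes$id)
    members <- data.frame(
      id = member_ids, node = nodes$id,
      founder = !is.na(slot),
      source = ifelse(is.na(slot), NA_character_, founder_ids[slot]),
      stringsAsFactors = FALSE
    )
    names(haps) <- member_ids
    record <- structure(
      list(haps = haps, map = map, founder_sources = founder_ids),
      class = "inheritance_record"
    )

    geno <- hap_mat <- NULL
    if (genotypes) {
      m <- nrow(panel)
      cb <- chrom_bounds(panel)
      hap_mat <- matrix(0L, nrow = 2L * nrow(nodes), ncol = m)
      rownames(hap_mat) <- paste0(rep(member_ids, each = 2L), "_", c(1L, 2L))
      for (i in seq_along(member_ids)) {
        h <- haps[[member_ids[i]]]
        for (c in seq_len(nrow(cb))) {
          ci <- match(cb$chrom[c], map$chrom)
          cols <- cb$lo[c]:cb$hi[c]
          cm <- panel$pos_cM[cols]
          for (s in 1:2) {
            hh <- h[[ci]][[s]]
            lab <- hh$labs[findInterval(cm, hh$ends, left.open = TRUE) + 1L]
            hap_mat[2L * (i - 1L) + s, cols] <- founder_haps[cbind(lab, cols)]
          }
        }
      }
      geno <- hap_mat[seq(1L, 2L * nrow(nodes), by = 2L), , drop = FALSE] +
        hap_mat[seq(2L, 2L * nrow(nodes), by = 2L), , drop = FALSE]
      rownames(geno) <- member_ids
    }

    pairs <- data.frame(
      id_a = paste0(prefix, ped$pairs$id_a),
      id_b = paste0(prefix, ped$pairs$id_b),
      degree = ped$pairs$degree,
      stringsAsFactors = FALSE
    )
    structure(
      list(id = sub("_$", "", prefix), members = members, genotypes = geno,
           haplotypes = hap_mat, record = record, pairs = pairs),
      class = "family_sim"
    )
  })
}

#' Simulate a cohort of families from a founder pool
#'
#' Partitions the founder pool into families of 11 per replicate (a 208
#' individual pool yields 18 families) and repeats the partition for
#' `n_replicates` replicates with fresh seeds, recycling the pool as in the
#' evaluation design (10 replicates of 18 families give 180 families).  Pair
#' labels are aggregated across families.
#'
#' @param founders list with `haplotypes` (from [generate_founders()]); its
#'   `ids` attribute defines the pool.
#' @param panel `marker_panel` matching the founder haplotypes.
#' @param map `genetic_map`.
#' @param n_replicates number of seed-changing repetitions.
#' @param n_families families per replicate; default (and maximum)
#'   `floor(pool size / 11)`.
#' @param seed integer master seed.
#' @param genotypes logical, as in [simulate_family()].
#' @return object of class `kin_cohort`: list with `panel`, `map`,
#'   `families` (list of `family_sim`), `pairs` (aggregated data.frame with
#'   `family`, `id_a`, `id_b`, `degree`) and `template`.
#' @export
run_cohort <- function(founders, panel, map, n_replicates = 1L,
                       n_families = NULL, seed = 1, genotypes = TRUE) {
  ped <- template_pedigree()
  hp <- founders$haplotypes
  ids <- attr(hp, "ids")
  k <- length(ped$founders)
  max_fam <- length(ids) %/% k
  if (max_fam < 1L) stop_invalid("founder pool smaller than ", k)
  n_families <- n_families %||% max_fam
  if (n_families > max_fam) {
    stop_invalid("founder pool supports at most ", max_fam, " families")
  }
  families <- vector("list", n_families * n_replicates)
  f <- 0L
  for (r in seq_len(n_replicates)) {
    perm <- with_seed(derive_seed(seed, r, 0L), sample(ids))
    for (j in seq_len(n_families)) {
      f <- f + 1L
      fam_founders <- perm[(j - 1L) * k + seq_len(k)]
      rows <- as.vector(rbind(2L * match(fam_founders, ids) - 1L,
                              2L * match(fam_founders, ids)))
      families[[f]] <- simulate_family(
        ped, fam_founders,
        founder_haps = if (genotypes) hp[rows, , drop = FALSE],
        panel = if (genotypes) panel,
        map = map,
        seed = derive_seed(seed, r, j),
        prefix = sprintf("R%02dF%02d_", r, j),
        genotypes = genotypes
      )
    }
  }
  pairs <- do.call(rbind, lapply(families, function(fm) {
    cbind(family = fm$id, fm$pairs, stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  structure(
    list(panel = panel, map = map, families = families, pairs = pairs,
         template = ped, seed = seed),
    class = "kin_cohort"
  )
}

#' @export
print.kin_cohort <- function(x, ...) {
  cat(sprintf(
    "Kinship cohort: %d families, %d labelled pairs, %s markers\n",
    length(x$families), nrow(x$pairs),
    if (is.null(x$panel)) "no" else format(nrow(x$panel), big.mark = ",")
  ))
  invisible(x)
}

# Founder-label step functions evaluated at points `at` (cM).
labels_at <- function(h, at) {
  h$labs[findInterval(at, h$ends, left.open = TRUE) + 1L]
}

#' True IBD segments of a simulated pair
#'
#' Reads the inheritance record and returns the maximal intervals on which
#' the pair shares founder-haplotype labels: intervals where the two
#' individuals' haplotype pairs can be matched completely are IBD2, intervals
#' with exactly one shared label are IBD1 (IBD2 regions are never
#' double-counted as IBD1).
#'
#' @param record an `inheritance_record` (from a `family_sim`).
#' @param a,b member ids simulated in the same family/cohort.
#' @param panel optional `marker_panel`; if given, `n_markers` is filled in.
#' @return `segment_set` data.frame (`chrom`, `start_bp`, `end_bp`,
#'   `start_cM`, `end_cM`, `class`, `n_markers`).
#' @export
true_ibd_segments <- function(record, a, b, panel = NULL) {
  ha <- record$haps[[a]]; hb <- record$haps[[b]]
  if (is.null(ha) || is.null(hb)) stop_invalid("pair not found in record")
  map <- record$map
  out <- vector("list", nrow(map))
  for (c in seq_len(nrow(map))) {
    ends <- sort(unique(c(ha[[c]]$h1$ends, ha[[c]]$h2$ends,
                          hb[[c]]$h1$ends, hb[[c]]$h2$ends)))
    starts <- c(0, ends[-length(ends)])
    mid <- (starts + ends) / 2
    a1 <- labels_at(ha[[c]]$h1, mid); a2 <- labels_at(ha[[c]]$h2, mid)
    b1 <- labels_at(hb[[c]]$h1, mid); b2 <- labels_at(hb[[c]]$h2, mid)
    ibd2 <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
    ibd1 <- !ibd2 & (a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2)
    cls <- ifelse(ibd2, 2L, ifelse(ibd1, 1L, 0L))
    r <- rle(cls)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    keep <- r$values > 0L
    if (!any(keep)) next
    out[[c]] <- data.frame(
      chrom = map$chrom[c],
      start_cM = starts[lo[keep]],
      end_cM = ends[hi[keep]],
      class = c("IBD1", "IBD2")[r$values[keep]]
    )
  }
  seg <- do.call(rbind, out)
  if (is.null(seg)) {
    seg <- data.frame(chrom = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), class = character(0))
  }
  bpc <- attr(map, "bp_per_cM")
  seg$start_bp <- seg$start_cM * bpc
  seg$end_bp <- seg$end_cM * bpc
  seg$n_markers <- rep(NA_integer_, nrow(seg))
  if (!is.null(panel) && nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      on_c <- panel$chrom == seg$chrom[i]
      seg$n_markers[i] <- sum(on_c & panel$pos_cM > seg$start_cM[i] &
                                panel$pos_cM <= seg$end_cM[i])
    }
  }
  as_segment_set(seg)
}
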