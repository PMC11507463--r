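# VCF and map-file interfaces.  Writing emits minimal VCF 4.2 text; parsing
# goes through vcfR.  A 3-column genetic-map text file (chrom, bp, cM)
# supplies genetic positions for real data.

#' Write genotypes (optionally phased) to a VCF file
#'
#' Minimal VCF 4.2 with GT-only FORMAT.  Coordinates are written 1-based as
#' the format requires (internal panel positions are 0-based).  When
#' `haplotypes` is supplied the GT field is phased (`|`), otherwise unphased
#' (`/`).
#'
#' @param genotypes dosage matrix, individuals x markers; rownames are
#'   sample names.
#' @param panel `marker_panel` describing the columns.
#' @param file output path.
#' @param haplotypes optional phased matrix with two rows per individual in
#'   the same order.
#' @return invisibly `file`.
#' @export
write_vcf <- function(genotypes, panel, file, haplotypes = NULL) {
  ids <- rownames(genotypes)
  if (is.null(ids)) stop_invalid("genotypes must have sample rownames")
  n <- nrow(genotypes)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kinfuse",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(panel$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  gt <- matrix("", nrow = nrow(panel), ncol = n)
  for (i in seq_len(n)) {
    g <- genotypes[i, ]
    if (is.null(haplotypes)) {
      gt[, i] <- c("0/0", "0/1", "1/1")[g + 1L]
      gt[is.na(g), i] <- "./."
    } else {
      h1 <- haplotypes[2L * i - 1L, ]; h2 <- haplotypes[2L * i, ]
      gt[, i] <- paste0(h1, "|", h2)
      gt[is.na(g), i] <- ".|."
    }
  }
  body <- cbind(
    panel$chrom, format(panel$pos_bp + 1L, scientific = FALSE, trim = TRUE),
    sprintf("snp%d", seq_len(nrow(panel))), panel$ref, panel$alt,
    ".", "PASS", ".", "GT", gt
  )
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(file)
}

#' Read genotypes from a VCF file
#'
#' Parses with `vcfR`, keeping biallelic SNP records, and converts GT to
#' alt-allele dosage.  Phased haplotypes are returned when every call uses
#' the phased separator.
#'
#' @param file VCF path (plain or gzipped).
#' @return list with `markers` (data.frame `chrom`, `pos_bp` (0-based),
#'   `ref`, `alt`), `genotypes` (individuals x markers dosage matrix),
#'   `haplotypes` (phased matrix or `NULL`), `phased` flag.
#' @export
read_vcf_genotypes <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  markers <- data.frame(
    chrom = as.integer(fix[biallelic, "CHROM"]),
    pos_bp = as.numeric(fix[biallelic, "POS"]) - 1,
    ref = fix[biallelic, "REF"], alt = fix[biallelic, "ALT"],
    stringsAsFactors = FALSE
  )
  phased <- all(grepl("\\|", gt) | gt %in% c(".", "./.", ".|."))
  dims <- dim(gt)
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1L, 1L))),
               dims[1L], dims[2L])
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3L, 3L))),
               dims[1L], dims[2L])
  geno <- t(a1 + a2)
  rownames(geno) <- colnames(gt)
  haps <- NULL
  if (phased) {
    haps <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
    haps[seq(1L, nrow(haps), 2L), ] <- t(a1)
    haps[seq(2L, nrow(haps), 2L), ] <- t(a2)
    rownames(haps) <- paste0(rep(colnames(gt), each = 2L), "_", c(1L, 2L))
  }
  list(markers = markers, genotypes = geno, haplotypes = haps,
       phased = phased)
}

#' Read a genetic-map text file
#'
#' Three whitespace-separated columns: chromosome, physical position (bp),
#' cumulative genetic position (cM).  Positions must be non-decreasing in
#' cM within each chromosome.
#'
#' @param file path.
#' @return data.frame `chrom`, `pos_bp`, `pos_cM`.
#' @export
read_genetic_map_file <- function(file) {
  mp <- utils::read.table(file, header = FALSE,
                          col.names = c("chrom", "pos_bp", "pos_cM"))
  mp <- mp[order(mp$chrom, mp$pos_bp), ]
  bad <- stats::ave(mp$pos_cM, mp$chrom, FUN = function(x) c(0, diff(x)))
  if (any(bad < 0)) stop_invalid("genetic map cM must be non-decreasing")
  mp
}

# Linear interpolation of cM positions for markers from a map table.
interpolate_cM <- function(map_table, chrom, pos_bp) {
  out <- numeric(length(pos_bp))
  for (c in unique(chrom)) {
    sel <- chrom == c
    mt <- map_table[map_table$chrom == c, ]
    if (nrow(mt) < 2L) stop_invalid("map has < 2 points on chromosome ", c)
    out[sel] <- stats::approx(mt$pos_bp, mt$pos_cM, xout = pos_bp[sel],
                              rule = 2)$y
  }
  out
}

#' Write a marker panel as a PLINK bim-like table
#'
#' Tab-separated columns chrom, marker id, genetic position (cM), physical
#' position (1-based bp), alt allele, ref allele.
#'
#' @param panel `marker_panel`.
#' @param file output path.
#' @return invisibly `file`.
#' @export
write_panel_bim <- function(panel, file) {
  utils::write.table(
    data.frame(panel$chrom, sprintf("snp%d", seq_len(nrow(panel))),
               panel$pos_cM, panel$pos_bp + 1L, panel$alt, panel$ref),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(file)
}

#' Write detected IBD segments to a TSV file
#'
#' Mirrors common IBD-segment file layouts: one row per segment with the
#' pair ids, coordinates in bp and cM, the IBD class and marker count.
#'
#' @param segset a `segment_set`.
#' @param id_a,id_b pair identifiers.
#' @param file output path.
#' @return invisibly `file`.
#' @export
write_segments_tsv <- function(segset, id_a, id_b, file) {
  df <- cbind(id_a = id_a, id_b = id_b, as.data.frame(segset))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one biallelic site: conditioning on the observed
#' allele counts, the probability of each possible heterozygote count is
#' computed by the standard recurrence and the p-value sums the
#' probabilities not exceeding that of the observed configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  probs <- numeric(length(hets))
  # start from the mid configuration and fill outward by the recurrence
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1L)) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2       # rare-allele homozygotes
      hom_c <- n - h - hom_r          # common-allele homozygotes
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c /
        ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1L) {
    for (i in mid_i:2L) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - hom_r - h
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}
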