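# IBD segment sets and the segment -> Cotterman -> kinship conversions.

as_segment_set <- function(df) {
  cols <- c("chrom", "start_bp", "end_bp", "start_cM", "end_cM",
            "class", "n_markers")
  df <- df[, cols]
  rownames(df) <- NULL
  class(df) <- c("segment_set", "data.frame")
  df
}

empty_segment_set <- function() {
  as_segment_set(data.frame(
    chrom = integer(0), start_bp = numeric(0), end_bp = numeric(0),
    start_cM = numeric(0), end_cM = numeric(0), class = character(0),
    n_markers = integer(0)
  ))
}

#' Total genetic length of a segment set per IBD class
#'
#' @param segset a `segment_set`.
#' @return named numeric `c(IBD1 = , IBD2 = )`, genetic lengths in cM.
#' @export
segment_lengths <- function(segset) {
  len <- function(cls) {
    s <- segset[segset$class == cls, , drop = FALSE]
    sum(s$end_cM - s$start_cM)
  }
  c(IBD1 = len("IBD1"), IBD2 = len("IBD2"))
}

#' Cotterman coefficients from detected IBD segments
#'
#' `kappa1 = L(IBD1) / L(genome)`, `kappa2 = L(IBD2) / L(genome)`,
#' `kappa0 = 1 - kappa1 - kappa2`, with segment lengths summed across all
#' autosomes in genetic units.  If the summed lengths exceed the genome
#' length (overlapping detector output), they are clipped proportionally
#' with a warning.
#'
#' @param segset a `segment_set`.
#' @param L_genome total genetic map length in cM (default 3346.30, the
#'   autosomal total of the adopted map).
#' @return named numeric `c(k0, k1, k2)` summing to 1.
#' @export
cotterman_from_segments <- function(segset, L_genome = 3346.30) {
  if (L_genome <= 0) stop_invalid("L_genome must be positive")
  L <- segment_lengths(segset)
  if (any(L < 0)) stop_invalid("negative segment lengths")
  if (sum(L) > L_genome) {
    warning("summed IBD length exceeds genome length; clipping",
            call. = FALSE)
    L <- L * (L_genome / sum(L))
  }
  k1 <- L[["IBD1"]] / L_genome
  k2 <- L[["IBD2"]] / L_genome
  c(k0 = 1 - k1 - k2, k1 = k1, k2 = k2)
}

# theta = kappa2/2 + kappa1/4
theta_from_kappa <- function(kappa) {
  kappa[["k2"]] / 2 + kappa[["k1"]] / 4
}

# Remove the parts of index runs (2-col matrix start,end) covered by `sub`
# runs; both in marker-index space, runs disjoint and sorted.
subtract_runs <- function(runs, sub) {
  if (nrow(runs) == 0L || nrow(sub) == 0L) return(runs)
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1L]; e <- runs[i, 2L]
    ov <- sub[sub[, 2L] >= s & sub[, 1L] <= e, , drop = FALSE]
    if (nrow(ov) == 0L) { out[[i]] <- cbind(s, e); next }
    pieces <- NULL
    cur <- s
    for (j in seq_len(nrow(ov))) {
      if (ov[j, 1L] > cur) pieces <- rbind(pieces, cbind(cur, ov[j, 1L] - 1L))
      cur <- max(cur, ov[j, 2L] + 1L)
    }
    if (cur <= e) pieces <- rbind(pieces, cbind(cur, e))
    out[[i]] <- pieces
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(0), ncol = 2L)
  colnames(res) <- c("start", "end")
  res
}

# Build a segment_set from index runs over a panel.
runs_to_segments <- function(runs, panel, class) {
  if (nrow(runs) == 0L) return(empty_segment_set())
  as_segment_set(data.frame(
    chrom = panel$chrom[runs[, 1L]],
    start_bp = panel$pos_bp[runs[, 1L]],
    end_bp = panel$pos_bp[runs[, 2L]],
    start_cM = panel$pos_cM[runs[, 1L]],
    end_cM = panel$pos_cM[runs[, 2L]],
    class = class,
    n_markers = runs[, 2L] - runs[, 1L] + 1L
  ))
}
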