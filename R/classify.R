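# Degree classification from the kinship coefficient and the four
# evaluation metrics: overlapping rate, sensitivity, positive predictive
# value, and overall accuracy.

#' Kinship-coefficient classification boundaries
#'
#' The empirical criteria place the boundary between adjacent degrees at the
#' geometric midpoint of their expected kinship values:
#' `b_k = 1/2^((2k+3)/2)` for `k = 0..7`.  Intervals are left-closed /
#' right-open; `theta >= 1/2^(3/2)` is classed twin/same individual and
#' `theta < 1/2^(17/2)` (including negative estimates) unrelated.
#'
#' @return decreasing numeric vector of the eight boundaries.
#' @export
classifier_boundaries <- function() {
  2^(-(2 * (0:7) + 3) / 2)
}

#' Classify relationship degree from a kinship coefficient
#'
#' @param theta kinship coefficient(s); finite, may be negative.
#' @param boundaries classification boundaries, default
#'   [classifier_boundaries()].
#' @return character vector of labels among [degree_levels()]; `NA` input
#'   is rejected.
#' @export
classify_degree <- function(theta, boundaries = classifier_boundaries()) {
  if (any(is.na(theta)) || any(!is.finite(theta))) {
    stop_invalid("theta must be finite (handle undefined estimates upstream)")
  }
  lv <- degree_levels()
  # number of boundaries <= theta: 0 -> unrelated bin, 8 -> twin bin
  idx <- length(boundaries) - findInterval(theta, rev(boundaries)) + 1L
  lv[pmin(idx, length(lv))]
}

#' Reference ranges of the kinship estimate per relationship class
#'
#' Summarises reference-condition estimates (error-free and/or full panel)
#' into per class and method intervals, used by the overlapping-rate metric.
#' The default interval is the observed minimum-maximum; `quantile` switches
#' to central quantile bounds (e.g. 0.005 gives the 0.5%-99.5% interval).
#'
#' @param estimates data.frame with columns `degree`, and `theta_<METHOD>`
#'   columns (as returned by [estimate_cohort()]).
#' @param quantile `NULL` (min-max) or a lower tail probability.
#' @return data.frame `method`, `degree`, `lower`, `upper`; classes absent
#'   from `estimates` are dropped with a warning.
#' @export
reference_ranges <- function(estimates, quantile = NULL) {
  methods <- sub("^theta_", "", grep("^theta_", names(estimates), value = TRUE))
  out <- list()
  for (m in methods) {
    th <- estimates[[paste0("theta_", m)]]
    for (d in unique(estimates$degree)) {
      x <- th[estimates$degree == d & !is.na(th)]
      if (length(x) == 0L) {
        warning("no estimates for class ", d, " (", m, ")", call. = FALSE)
        next
      }
      bounds <- if (is.null(quantile)) range(x) else {
        stats::quantile(x, c(quantile, 1 - quantile), names = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        method = m, degree = d, lower = bounds[1L], upper = bounds[2L]
      )
    }
  }
  do.call(rbind, out)
}

#' Evaluation metrics for kinship inference
#'
#' Classifies every estimate and computes, per method: sensitivity
#' (`Sen_c = TP_c / n_true_c`), positive predictive value
#' (`PPV_c = TP_c / n_inferred_c`), overall accuracy
#' (`AC = sum_c TP_c / n_total`), and — when reference `ranges` are given —
#' the overlapping rate, the proportion of class-c pairs whose estimate lies
#' inside the class-c reference interval.  Undefined estimates (`NA`) count
#' as misclassifications for Sen and AC and enter no PPV denominator.  The
#' twin bin exists in the classifier but no simulated pair is labelled twin,
#' so it appears only as an inferred class.
#'
#' @param estimates data.frame from [estimate_cohort()] (columns `degree`
#'   and `theta_<METHOD>`).
#' @param ranges optional data.frame from [reference_ranges()].
#' @param boundaries classification boundaries.
#' @return list of class `metrics_report`: `per_class` (data.frame `method`,
#'   `degree`, `n_true`, `n_inferred`, `TP`, `Sen`, `PPV`,
#'   `overlapping_rate`), `AC` (named per method), and `confusion` (list of
#'   true x inferred tables).
#' @export
compute_metrics <- function(estimates, ranges = NULL,
                            boundaries = classifier_boundaries()) {
  methods <- sub("^theta_", "", grep("^theta_", names(estimates), value = TRUE))
  lv <- degree_levels()
  truth <- factor(estimates$degree, levels = lv)
  if (any(is.na(truth))) stop_invalid("unknown degree label in estimates")
  per_class <- list(); AC <- stats::setNames(numeric(0), character(0))
  confusion <- list()
  for (m in methods) {
    th <- estimates[[paste0("theta_", m)]]
    ok <- !is.na(th)
    inferred <- factor(rep(NA_character_, length(th)), levels = lv)
    inferred[ok] <- classify_degree(th[ok], boundaries)
    tab <- table(true = truth, inferred = inferred, useNA = "no")
    confusion[[m]] <- tab
    AC[m] <- sum(diag(tab[lv, lv])) / length(th)
    for (d in levels(droplevels(truth))) {
      in_c <- truth == d
      tp <- sum(in_c & !is.na(inferred) & inferred == d)
      n_inf <- sum(!is.na(inferred) & inferred == d)
      ov <- NA_real_
      if (!is.null(ranges)) {
        rg <- ranges[ranges$method == m & ranges$degree == d, ]
        if (nrow(rg) == 1L) {
          ov <- mean(ok[in_c] & th[in_c] >= rg$lower & th[in_c] <= rg$upper)
        }
      }
      per_class[[length(per_class) + 1L]] <- data.frame(
        method = m, degree = d, n_true = sum(in_c), n_inferred = n_inf,
        TP = tp, Sen = tp / sum(in_c),
        PPV = if (n_inf > 0L) tp / n_inf else NA_real_,
        overlapping_rate = ov
      )
    }
  }
  structure(
    list(per_class = do.call(rbind, per_class), AC = AC,
         confusion = confusion),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Overall accuracy (AC):\n")
  print(round(x$AC, 4))
  cat("\nPer-class metrics:\n")
  df <- x$per_class
  df$Sen <- round(df$Sen, 3); df$PPV <- round(df$PPV, 3)
  df$overlapping_rate <- round(df$overlapping_rate, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
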