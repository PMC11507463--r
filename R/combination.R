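# Estimator fusion: a 13-variable feature set over the four kinship
# estimates (levels, pairwise differences, ratios with the IBS-run estimate
# as denominator — the only estimate guaranteed positive through its
# supplemental constant), fitted by stepwise multiple linear regression
# against the error-free "expected kinship coefficient" with 10-fold
# cross-validation.  Published model coefficients (M1-M7) are bundled.

fusion_feature_info <- function() {
  tools <- c("KING", "IBIS", "TRUFFLE", "GERMLINE")
  feats <- c(
    stats::setNames(as.list(tools), paste0("theta_", tools)),
    list(
      d_KING_IBIS = c("KING", "IBIS"),
      d_KING_TRUFFLE = c("KING", "TRUFFLE"),
      d_KING_GERMLINE = c("KING", "GERMLINE"),
      d_IBIS_TRUFFLE = c("IBIS", "TRUFFLE"),
      d_IBIS_GERMLINE = c("IBIS", "GERMLINE"),
      d_TRUFFLE_GERMLINE = c("TRUFFLE", "GERMLINE"),
      r_KING_IBIS = c("KING", "IBIS"),
      r_TRUFFLE_IBIS = c("TRUFFLE", "IBIS"),
      r_GERMLINE_IBIS = c("GERMLINE", "IBIS")
    )
  )
  feats
}

#' Build the 13-variable fusion feature set
#'
#' From the four kinship estimates constructs the four levels, the six
#' pairwise differences `d_A_B = theta_A - theta_B`, and the three ratios
#' `r_A_IBIS = theta_A / theta_IBIS` (the IBS-run estimate is the only one
#' bounded away from zero, by its supplemental constant, and is therefore
#' the only admissible denominator).
#'
#' @param theta named vector/list with elements `KING`, `IBIS`, `TRUFFLE`,
#'   `GERMLINE`, or a data.frame with `theta_<METHOD>` columns.
#' @return named numeric vector of length 13, or a 13-column data.frame for
#'   data.frame input.
#' @export
build_features <- function(theta) {
  if (is.data.frame(theta)) {
    g <- function(m) theta[[paste0("theta_", m)]]
  } else {
    theta <- unlist(theta)
    names(theta) <- sub("^theta_", "", names(theta))
    g <- function(m) theta[[m]]
  }
  k <- g("KING"); i <- g("IBIS"); t <- g("TRUFFLE"); m <- g("GERMLINE")
  if (any(is.na(c(k, i, t, m)))) {
    stop_invalid("all four estimates must be defined to build features")
  }
  out <- data.frame(
    theta_KING = k, theta_IBIS = i, theta_TRUFFLE = t, theta_GERMLINE = m,
    d_KING_IBIS = k - i, d_KING_TRUFFLE = k - t, d_KING_GERMLINE = k - m,
    d_IBIS_TRUFFLE = i - t, d_IBIS_GERMLINE = i - m,
    d_TRUFFLE_GERMLINE = t - m,
    r_KING_IBIS = k / i, r_TRUFFLE_IBIS = t / i, r_GERMLINE_IBIS = m / i
  )
  if (is.data.frame(theta)) out else unlist(out[1L, ])
}

#' Expected kinship coefficient of each pair
#'
#' The mean of the four method estimates computed on the error-free dataset;
#' the dependent variable of the fusion regression.
#'
#' @param estimates error-free [estimate_cohort()] output with all four
#'   `theta_` columns.
#' @return numeric vector, one value per pair.
#' @export
expected_theta <- function(estimates) {
  cols <- paste0("theta_", c("KING", "IBIS", "TRUFFLE", "GERMLINE"))
  if (!all(cols %in% names(estimates))) {
    stop_invalid("all four estimator columns required")
  }
  rowMeans(estimates[, cols])
}

new_combination_model <- function(subset, coefficients, r2 = NA_real_,
                                  cv_r2 = NA_real_, trace = character(0),
                                  provenance = "bundled") {
  structure(
    list(subset = subset, coefficients = coefficients, r2 = r2,
         cv_r2 = cv_r2, trace = trace, provenance = provenance),
    class = "combination_model"
  )
}

#' Bundled fusion models M1-M7
#'
#' The published linear fusion models for every tool subset, applied
#' verbatim as constants (refitting never overwrites them).  M7, combining
#' all four estimators, is the recommended combination model.
#'
#' @return named list of `combination_model` objects `M1` ... `M7`.
#' @export
combination_models <- function() {
  mk <- function(subset, co, r2) {
    new_combination_model(subset, co, r2 = r2, provenance = "published")
  }
  list(
    M1 = mk(c("KING", "IBIS"), c(
      "(Intercept)" = 0.00248, theta_IBIS = 0.98133,
      d_KING_IBIS = 1.24292, r_KING_IBIS = -0.00010
    ), 0.99024),
    M2 = mk(c("KING", "TRUFFLE"), c(
      "(Intercept)" = 0.00209, theta_TRUFFLE = 0.99867,
      d_KING_TRUFFLE = 1.27598
    ), 0.99064),
    M3 = mk(c("KING", "GERMLINE"), c(
      "(Intercept)" = 0.00210, theta_KING = 1.15566, theta_GERMLINE = 0.20366
    ), 0.98890),
    M4 = mk(c("KING", "IBIS", "TRUFFLE"), c(
      "(Intercept)" = 0.00279, theta_IBIS = 0.99651, d_KING_IBIS = 1.35786,
      d_IBIS_TRUFFLE = 0.37875, r_KING_IBIS = -0.00036,
      r_TRUFFLE_IBIS = -0.00002
    ), 0.99146),
    M5 = mk(c("KING", "IBIS", "GERMLINE"), c(
      "(Intercept)" = 0.00308, theta_IBIS = 0.98074,
      d_KING_GERMLINE = 1.22371, d_IBIS_GERMLINE = -1.18864,
      r_KING_IBIS = -0.00007, r_GERMLINE_IBIS = -0.00195
    ), 0.99040),
    M6 = mk(c("KING", "TRUFFLE", "GERMLINE"), c(
      "(Intercept)" = 0.00202, theta_KING = 1.25589,
      theta_TRUFFLE = -0.20160, theta_GERMLINE = -0.07663
    ), 0.99115),
    M7 = mk(c("KING", "IBIS", "TRUFFLE", "GERMLINE"), c(
      "(Intercept)" = 0.00279, theta_TRUFFLE = 0.98496,
      d_KING_IBIS = 1.24569, d_KING_GERMLINE = 0.09770,
      d_IBIS_TRUFFLE = 1.43790, r_KING_IBIS = -0.00034,
      r_TRUFFLE_IBIS = 0.00021, r_GERMLINE_IBIS = -0.00114
    ), 0.99194)
  )
}

#' Predict the combined kinship coefficient
#'
#' Linear evaluation `intercept + sum(coef * feature)` of a fusion model on
#' a feature vector or feature data.frame (see [build_features()]).
#'
#' @param model a `combination_model` (bundled or refit).
#' @param features named numeric vector or data.frame of fusion features.
#' @return predicted kinship coefficient(s).
#' @export
predict_theta <- function(model, features) {
  co <- model$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  if (is.data.frame(features)) {
    if (!all(terms %in% names(features))) {
      stop_invalid("missing features: ",
                   paste(setdiff(terms, names(features)), collapse = ", "))
    }
    X <- as.matrix(features[, terms, drop = FALSE])
  } else {
    if (!all(terms %in% names(features))) {
      stop_invalid("missing features: ",
                   paste(setdiff(terms, names(features)), collapse = ", "))
    }
    X <- matrix(features[terms], nrow = 1L,
                dimnames = list(NULL, terms))
  }
  if (any(!is.finite(X))) stop_invalid("non-finite feature values")
  drop(co[["(Intercept)"]] + X %*% co[terms])
}

#' @export
print.combination_model <- function(x, ...) {
  cat(sprintf("Fusion model [%s] over {%s}\n", x$provenance,
              paste(x$subset, collapse = ", ")))
  print(signif(x$coefficients, 6))
  cat(sprintf("R2 = %.5f", x$r2))
  if (is.finite(x$cv_r2)) cat(sprintf("  (10-fold CV R2 = %.5f)", x$cv_r2))
  cat("\n")
  invisible(x)
}

# Small-sample corrected information criterion of an OLS fit.
aicc <- function(rss, n, p) {
  k <- p + 1 # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Stepwise multiple linear regression with 10-fold cross-validation
#'
#' Bidirectional stepwise selection by a small-sample-corrected information
#' criterion over the fusion features admissible for the given tool subset
#' (only features computable from that subset's estimates), starting from
#' the intercept-only model.  The selected formula is assessed by seeded
#' 10-fold cross-validation and refit on all data.
#'
#' @param features data.frame of fusion features (see [build_features()]).
#' @param target numeric response (the expected kinship coefficient).
#' @param tool_subset tools available to the model.
#' @param seed integer seed for the fold assignment.
#' @return a `combination_model` with refit coefficients, in-sample `r2`,
#'   `cv_r2` and the selection `trace`.
#' @export
fit_stepwise <- function(features, target,
                         tool_subset = c("KING", "IBIS", "TRUFFLE",
                                         "GERMLINE"),
                         seed = 1) {
  info <- fusion_feature_info()
  admissible <- names(info)[vapply(info, function(t) all(t %in% tool_subset),
                                   logical(1))]
  admissible <- intersect(admissible, names(features))
  n <- length(target)
  if (n < 10L * (length(admissible) + 1L)) {
    stop_invalid("need at least 10x more observations than features")
  }
  X <- as.matrix(features[, admissible, drop = FALSE])
  if (any(!is.finite(X)) || any(!is.finite(target))) {
    stop_invalid("non-finite feature/target values")
  }
  # The difference features are exact linear combinations of the levels, so
  # the full design is rank-deficient by construction; selection never adds
  # an aliased feature (no RSS gain, criterion penalty) and the final fit is
  # checked for degeneracy below.
  rss_of <- function(sel) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, sel, drop = FALSE]),
                         target)
    sum(fit$residuals^2)
  }
  current <- character(0)
  best <- aicc(rss_of(current), n, 0L)
  trace <- sprintf("start: intercept only (AICc %.2f)", best)
  repeat {
    moves <- rbind(
      if (length(setdiff(admissible, current))) {
        data.frame(op = "+", term = setdiff(admissible, current))
      },
      if (length(current)) data.frame(op = "-", term = current)
    )
    if (is.null(moves)) break
    crit <- vapply(seq_len(nrow(moves)), function(i) {
      sel <- if (moves$op[i] == "+") c(current, moves$term[i]) else {
        setdiff(current, moves$term[i])
      }
      aicc(rss_of(sel), n, length(sel))
    }, numeric(1))
    if (min(crit) >= best - 1e-10) break
    i <- which.min(crit)
    current <- if (moves$op[i] == "+") c(current, moves$term[i]) else {
      setdiff(current, moves$term[i])
    }
    best <- crit[i]
    trace <- c(trace, sprintf("%s %s (AICc %.2f)", moves$op[i],
                              moves$term[i], best))
  }
  # 10-fold CV of the selected formula
  folds <- with_seed(seed, sample(rep(seq_len(10L), length.out = n)))
  press <- 0
  for (f in seq_len(10L)) {
    tr <- folds != f
    fit <- stats::lm.fit(
      cbind(1, X[tr, current, drop = FALSE]), target[tr]
    )
    pred <- cbind(1, X[!tr, current, drop = FALSE]) %*% fit$coefficients
    press <- press + sum((target[!tr] - pred)^2)
  }
  sst <- sum((target - mean(target))^2)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, current, drop = FALSE]),
                       target)
  co <- fit$coefficients
  names(co) <- c("(Intercept)", current)
  if (anyNA(co)) stop_invalid("degenerate fit: selected features collinear")
  new_combination_model(
    tool_subset, co,
    r2 = 1 - sum(fit$residuals^2) / sst,
    cv_r2 = 1 - press / sst,
    trace = trace,
    provenance = paste0("refit:", seed)
  )
}

#' Serialize a fusion model to JSON
#'
#' Writes the tool subset, intercept, named coefficients, fit statistics and
#' provenance tag (`published` or `refit:<seed>`) as a JSON object readable
#' by [read_model_json()].
#'
#' @param model a `combination_model`.
#' @param file output path.
#' @return invisibly `file`.
#' @export
write_model_json <- function(model, file) {
  co <- model$coefficients
  jsonlite::write_json(
    list(
      subset = model$subset,
      intercept = unname(co[["(Intercept)"]]),
      coefficients = as.list(co[setdiff(names(co), "(Intercept)")]),
      r2 = model$r2, cv_r2 = model$cv_r2,
      provenance = model$provenance
    ),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' Read a fusion model from JSON
#'
#' @param file path written by [write_model_json()].
#' @return a `combination_model`.
#' @export
read_model_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  co <- c("(Intercept)" = x$intercept, unlist(x$coefficients))
  new_combination_model(x$subset, co, r2 = x$r2 %||% NA_real_,
                        cv_r2 = x$cv_r2 %||% NA_real_,
                        provenance = x$provenance)
}

#' Fit a fusion model on a cohort across error levels
#'
#' Stacks one observation per pair per error level — features computed from
#' that level's four estimates, response always the pair's error-free
#' expected kinship coefficient — and runs [fit_stepwise()].  Pooling all
#' levels lets a single model serve every error rate.
#'
#' @param estimates_by_level named list of [estimate_cohort()] outputs, one
#'   per error level, aligned on pairs; must contain the element `"0"`
#'   (error-free).
#' @param tool_subset,seed passed to [fit_stepwise()].
#' @return a `combination_model`.
#' @export
fit_combination_model <- function(estimates_by_level,
                                  tool_subset = c("KING", "IBIS", "TRUFFLE",
                                                  "GERMLINE"),
                                  seed = 1) {
  if (!"0" %in% names(estimates_by_level)) {
    stop_invalid("estimates_by_level must include the error-free level \"0\"")
  }
  y0 <- expected_theta(estimates_by_level[["0"]])
  feats <- list(); target <- list()
  for (lev in names(estimates_by_level)) {
    est <- estimates_by_level[[lev]]
    ok <- stats::complete.cases(
      est[, paste0("theta_", c("KING", "IBIS", "TRUFFLE", "GERMLINE"))]
    )
    feats[[lev]] <- build_features(est[ok, ])
    target[[lev]] <- y0[ok]
  }
  fit_stepwise(do.call(rbind, feats), unlist(target), tool_subset, seed)
}
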