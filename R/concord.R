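# Repeatability, reproducibility and accuracy statistics on per-section
# neuron counts: Bland-Altman limits of agreement for paired counts,
# Pearson accuracy against the consensus reference count, and linear-model
# screening of the factors that drive (ir)repeatability.

#' Bland-Altman agreement analysis of paired counts
#'
#' Computes the bias (mean of paired differences a - b), the sample
#' standard deviation of the differences, and the 95% limits of agreement
#' bias +/- 1.96 sd. The limits are often labelled "95% confidence
#' intervals" on agreement plots; they are limits of agreement in
#' Bland-Altman's sense and are named so here.
#'
#' @param a,b paired numeric count vectors (same length, n >= 2), or `a` a
#'   two-column data.frame/matrix with `b` missing.
#' @return A `bland_altman` list: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and the per-pair `mean`/`diff` vectors for plotting.
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) {
    a <- as.data.frame(a)
    stopifnot(ncol(a) >= 2)
    b <- a[[2]]; a <- a[[1]]
  }
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n = n, mean = (a + b) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): bias %.3f, sd %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Accuracy of count estimates against a reference count
#'
#' Pearson correlation of per-section estimates against the reference
#' (e.g. the RNN), with the two-sided p-value from the t transform.
#' Reports both r and r² since published accuracy figures are quoted
#' either way.
#'
#' @param estimates numeric vector of per-section estimated counts.
#' @param reference numeric vector of reference counts (same sections).
#' @return List `r`, `r_squared`, `p_value`, `n`.
#' @export
accuracy_correlation <- function(estimates, reference) {
  stopifnot(length(estimates) == length(reference))
  keep <- is.finite(estimates) & is.finite(reference)
  estimates <- estimates[keep]; reference <- reference[keep]
  if (length(estimates) < 3) stop("need at least 3 paired counts")
  if (stats::sd(estimates) == 0 || stats::sd(reference) == 0) {
    stop("correlation undefined: zero variance in one of the variables")
  }
  ct <- stats::cor.test(estimates, reference, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(estimates))
}

#' Screen linear models for repeatability predictors
#'
#' Fits ordinary least-squares models of the (absolute) count difference
#' between repeated analyses on each candidate predictor subset, reports
#' adjusted R² for each, compares nested pairs by the ANOVA F-test, and
#' returns the best model by adjusted R². Candidate predictors typically
#' include the mean neuron count, the analysis time, analyst experience,
#' and section condition.
#'
#' @param data data.frame containing the response and predictor columns.
#' @param response name of the response column (difference between
#'   repeated counts).
#' @param candidates list of character vectors of predictor names; an
#'   empty vector denotes the intercept-only model.
#' @return List with `models` (data.frame: formula, df, adj_r2),
#'   `fits` (the lm objects), `anova` (nested comparisons), `best`
#'   (index of the best model).
#' @export
repeatability_model <- function(data, response, candidates) {
  stopifnot(length(candidates) >= 2)
  forms <- lapply(candidates, function(p) {
    rhs <- if (length(p) == 0) "1" else paste(p, collapse = " + ")
    stats::as.formula(paste(response, "~", rhs))
  })
  fits <- lapply(forms, function(f) stats::lm(f, data = data))
  for (i in seq_along(fits)) {
    qr_rank <- fits[[i]]$rank
    p_cols <- ncol(stats::model.matrix(fits[[i]]))
    if (qr_rank < p_cols) {
      bad <- names(which(is.na(stats::coef(fits[[i]]))))
      stop("rank-deficient design in model ", i, "; collinear terms: ",
           paste(bad, collapse = ", "))
    }
    if (stats::nobs(fits[[i]]) <= p_cols) {
      stop("model ", i, " has more parameters than observations")
    }
  }
  adj <- vapply(fits, function(f) summary(f)$adj.r.squared, numeric(1))
  models <- data.frame(
    model = vapply(forms, function(f) deparse(f), character(1)),
    df = vapply(fits, function(f) unname(stats::df.residual(f)), numeric(1)),
    adj_r2 = adj)
  # pairwise nested F-tests (model i nested in model j if predictors subset)
  comparisons <- list()
  for (i in seq_along(candidates)) {
    for (j in seq_along(candidates)) {
      if (i != j && all(candidates[[i]] %in% candidates[[j]]) &&
          length(candidates[[i]]) < length(candidates[[j]])) {
        an <- stats::anova(fits[[i]], fits[[j]])
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          reduced = i, full = j,
          F = an$F[2], p_value = an$`Pr(>F)`[2])
      }
    }
  }
  list(models = models, fits = fits,
       anova = if (length(comparisons)) do.call(rbind, comparisons) else NULL,
       best = which.max(adj))
}
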