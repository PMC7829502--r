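## Patient labeling, group comparisons, and covariate-adjusted
## correlations.

#' Fit the cognitive-score norm model on healthy controls
#'
#' Ordinary least squares of NCT-A and DST on age and education, fitted
#' in the healthy-control group only. The residual standard deviations
#' define the 2-SD labeling rule: a patient is labeled MHE when either
#' test deviates from its predicted value by more than
#' \code{threshold_sd} residual SDs in the impaired direction (NCT-A
#' above prediction, DST below prediction).
#'
#' @param hc data frame of healthy controls with columns \code{age},
#'   \code{education}, \code{nct_a}, \code{dst}.
#' @param threshold_sd deviation threshold in residual SDs; default 2.
#' @return a \code{label_model}.
#' @export
fit_label_model <- function(hc, threshold_sd = 2) {
  need <- c("age", "education", "nct_a", "dst")
  stopifnot(all(need %in% names(hc)))
  hc <- hc[complete.cases(hc[, need]), ]
  if (nrow(hc) < 3L) stop("need at least 3 complete HC subjects")
  fit_nct <- lm(nct_a ~ age + education, data = hc)
  fit_dst <- lm(dst ~ age + education, data = hc)
  if (any(is.na(coef(fit_nct))) || any(is.na(coef(fit_dst))))
    stop("rank-deficient norm design (age/education collinear)")
  structure(list(nct_a = fit_nct, dst = fit_dst,
                 sd_nct_a = summary(fit_nct)$sigma,
                 sd_dst = summary(fit_dst)$sigma,
                 threshold_sd = threshold_sd), class = "label_model")
}

#' Apply the 2-SD labeling rule to patients
#'
#' @param model a \code{label_model}.
#' @param patients data frame with \code{age}, \code{education},
#'   \code{nct_a}, \code{dst}.
#' @return data frame with predicted scores, per-test deviations in
#'   residual SDs (positive = impaired direction) and the assigned
#'   \code{label} ("MHE"/"noHE").
#' @export
apply_labels <- function(model, patients) {
  pred_nct <- predict(model$nct_a, newdata = patients)
  pred_dst <- predict(model$dst, newdata = patients)
  dev_nct <- (patients$nct_a - pred_nct) / model$sd_nct_a
  dev_dst <- (pred_dst - patients$dst) / model$sd_dst
  mhe <- dev_nct > model$threshold_sd | dev_dst > model$threshold_sd
  data.frame(predicted_nct_a = pred_nct, predicted_dst = pred_dst,
             dev_nct_a_sd = dev_nct, dev_dst_sd = dev_dst,
             label = ifelse(mhe, "MHE", "noHE"),
             stringsAsFactors = FALSE)
}

#' Three-group nonparametric comparison per unit with FDR control
#'
#' Kruskal-Wallis omnibus test (tie-corrected) per unit (node or
#' network), Benjamini-Hochberg adjustment across units, and pairwise
#' two-sided Mann-Whitney post hoc tests where the omnibus p is below
#' \code{posthoc_alpha}.
#'
#' @param values subjects x units numeric matrix (or data frame).
#' @param groups factor/character of group labels, one per subject.
#' @param posthoc_alpha omnibus threshold gating the post hoc tests.
#' @return data frame with one row per unit: H statistic, omnibus
#'   \code{p}, BH-adjusted \code{p_fdr}, per-group medians, and post hoc
#'   p-values for each group pair (NA where not performed).
#' @export
compare_groups <- function(values, groups, posthoc_alpha = 0.05) {
  values <- as.matrix(values)
  groups <- factor(groups)
  stopifnot(nrow(values) == length(groups), nlevels(groups) >= 2L)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  unit_names <- colnames(values)
  if (is.null(unit_names)) unit_names <- paste0("unit", seq_len(ncol(values)))
  rows <- lapply(seq_len(ncol(values)), function(u) {
    v <- values[, u]
    if (length(unique(v)) == 1L) {
      H <- 0; p <- 1     # everything tied: no evidence of any difference
    } else {
      kw <- kruskal.test(v, groups)
      H <- unname(kw$statistic); p <- kw$p.value
    }
    meds <- tapply(v, groups, median)
    row <- data.frame(unit = unit_names[u], H = H, p = p,
                      stringsAsFactors = FALSE)
    for (g in lev) row[[paste0("median_", g)]] <- unname(meds[g])
    for (j in seq_len(ncol(pairs))) {
      nm <- paste0("p_", pairs[1L, j], "_vs_", pairs[2L, j])
      row[[nm]] <- if (p < posthoc_alpha && length(unique(v)) > 1L) {
        suppressWarnings(wilcox.test(v[groups == pairs[1L, j]],
                                     v[groups == pairs[2L, j]],
                                     exact = FALSE)$p.value)
      } else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out[, c("unit", "H", "p", "p_fdr",
          setdiff(names(out), c("unit", "H", "p", "p_fdr")))]
}

#' Covariate-adjusted (partial) correlation
#'
#' Pearson correlation of the OLS residuals of \code{x} and \code{y} on
#' the covariate design (intercept included); the p-value uses the t
#' transform with \code{n - n_covariates - 2} degrees of freedom. With no
#' covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame / matrix of covariates (factors
#'   allowed in a data frame).
#' @return list with \code{r}, \code{p}, \code{df}, \code{n}.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  keep <- complete.cases(x, y,
                         if (is.null(covariates)) rep(TRUE, length(x))
                         else covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    ncov <- 0L
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    mm <- stats::model.matrix(~ ., data = cv)
    ncov <- ncol(mm) - 1L
    rx <- residuals(lm.fit_safe(mm, x))
    ry <- residuals(lm.fit_safe(mm, y))
  }
  if (n <= ncov + 2L) stop("need n > n_covariates + 2 observations")
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, df = n - ncov - 2L, n = n))
  r <- cor(rx, ry)
  df <- n - ncov - 2L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df, n = n)
}

lm.fit_safe <- function(mm, y) {
  fit <- stats::lm.fit(mm, y)
  class(fit) <- "lm"   # residuals() dispatch
  fit
}

#' Partial correlations of many units against one score
#'
#' @param values subjects x units matrix of metric values.
#' @param score numeric vector (e.g. DST, NCT-A, blood ammonia).
#' @param covariates optional covariate data frame (e.g. age, sex,
#'   education, mean FD).
#' @return data frame with \code{unit}, \code{r}, \code{p},
#'   \code{p_fdr} (BH across units), \code{n}.
#' @export
correlate_units <- function(values, score, covariates = NULL) {
  values <- as.matrix(values)
  unit_names <- colnames(values)
  if (is.null(unit_names)) unit_names <- paste0("unit", seq_len(ncol(values)))
  rows <- lapply(seq_len(ncol(values)), function(u) {
    pc <- partial_corr(values[, u], score, covariates)
    data.frame(unit = unit_names[u], r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out
}
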