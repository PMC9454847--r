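# Shapiro-Wilk normality check at level alpha. Constant samples (the test is
# undefined) and n outside [3, 5000] are treated as failing the gate, which
# routes the comparison to the rank-sum test.
passes_shapiro <- function(x, alpha) {
  n <- length(x)
  if (n < 3 || n > 5000) return(FALSE)
  if (diff(range(x)) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

comparison_row <- function(metric = NA_character_, group_high_mean = NA_real_,
                           group_low_mean = NA_real_, n_high = NA_integer_,
                           n_low = NA_integer_, test = NA_character_,
                           statistic = NA_real_, p_raw = NA_real_,
                           p_adjusted = NA_real_, note = NA_character_) {
  data.frame(metric = metric, group_high_mean = group_high_mean,
             group_low_mean = group_low_mean, n_high = n_high, n_low = n_low,
             test = test, statistic = statistic, p_raw = p_raw,
             p_adjusted = p_adjusted, note = note, stringsAsFactors = FALSE)
}

#' Compare a metric between two patient groups
#'
#' The test choice follows a normality gate: each group is screened with a
#' Shapiro-Wilk test at `alpha_normality`; when both groups pass, a two-sided
#' two-group one-way ANOVA (pooled variance, equivalent to the squared pooled
#' t statistic) is used, otherwise the Wilcoxon rank-sum test (exact when the
#' combined sample is small and untied, else normal approximation with
#' continuity and tie correction). Missing values are dropped per group.
#'
#' @param values_high,values_low Numeric metric values per patient in the
#'   HIGH and LOW stratum (NAs allowed, dropped).
#' @param alpha_normality Level of the Shapiro-Wilk gate; default 0.05.
#' @param metric Optional metric label carried into the result.
#' @return One-row data frame: group means, group sizes, `test` ("ANOVA" or
#'   "WILCOXON"), `statistic` (F or W), `p_raw`, `p_adjusted` (NA until
#'   [bh_adjust()] is applied), and `note` ("not_computable" when a group has
#'   fewer than 3 values).
#' @export
two_group_compare <- function(values_high, values_low, alpha_normality = 0.05,
                              metric = NA_character_) {
  hi <- values_high[!is.na(values_high)]
  lo <- values_low[!is.na(values_low)]
  if (length(hi) < 3 || length(lo) < 3) {
    return(comparison_row(metric = metric,
                          group_high_mean = if (length(hi)) mean(hi) else NA_real_,
                          group_low_mean = if (length(lo)) mean(lo) else NA_real_,
                          n_high = length(hi), n_low = length(lo),
                          note = "not_computable"))
  }
  normal <- passes_shapiro(hi, alpha_normality) && passes_shapiro(lo, alpha_normality)
  x <- c(hi, lo)
  grp <- factor(rep(c("HIGH", "LOW"), c(length(hi), length(lo))))
  if (normal) {
    if (stats::var(x) == 0) {
      # all values identical in both groups: no variance anywhere, F = 0
      test <- "ANOVA"; statistic <- 0; p <- 1
    } else {
      fit <- stats::oneway.test(x ~ grp, var.equal = TRUE)
      test <- "ANOVA"
      statistic <- unname(fit$statistic)
      if (!is.finite(statistic)) statistic <- 0  # zero between-group variance
      p <- fit$p.value
      if (!is.finite(p)) p <- 1
    }
  } else {
    exact <- (length(hi) + length(lo)) <= 20 && !anyDuplicated(x)
    wt <- suppressWarnings(
      stats::wilcox.test(hi, lo, exact = exact, correct = TRUE)
    )
    test <- "WILCOXON"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  comparison_row(metric = metric, group_high_mean = mean(hi),
                 group_low_mean = mean(lo), n_high = length(hi),
                 n_low = length(lo), test = test, statistic = statistic,
                 p_raw = p)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-ordering convention: the sum of
#' hypergeometric probabilities of all tables (with the observed margins) no
#' more probable than the observed one. A table with any zero margin carries
#' no information; its p-value is 1 by convention, with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param metric Optional metric label.
#' @return One-row data frame in the [two_group_compare()] layout with
#'   `test = "FISHER"` and `statistic` the conditional odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(tab, metric = NA_character_) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p = 1 by convention")
    return(comparison_row(metric = metric, test = "FISHER",
                          statistic = NA_real_, p_raw = 1,
                          note = "zero_margin"))
  }
  ft <- stats::fisher.test(tab)
  comparison_row(metric = metric, test = "FISHER",
                 statistic = unname(ft$estimate), p_raw = ft$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values (q-values) in the input order, each >= its raw
#'   p and <= 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation of a metric against a covariate
#'
#' Product-moment correlation with a two-sided p-value from the t transform;
#' pairs with a missing value in either variable are dropped.
#'
#' @param xs,ys Paired numeric vectors (e.g. HLA-DR surface-area percent and
#'   a spatial metric).
#' @param metric,covariate Optional labels.
#' @return One-row data frame: `r`, `r_squared`, `p`, `n`, `note`
#'   ("not_computable" when fewer than 3 complete pairs or either variable is
#'   constant).
#' @export
bivariate_correlation <- function(xs, ys, metric = NA_character_,
                                  covariate = NA_character_) {
  ok <- !is.na(xs) & !is.na(ys)
  x <- xs[ok]; y <- ys[ok]
  base <- data.frame(metric = metric, covariate = covariate, r = NA_real_,
                     r_squared = NA_real_, p = NA_real_, n = length(x),
                     note = NA_character_, stringsAsFactors = FALSE)
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    base$note <- "not_computable"
    return(base)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  base$r <- unname(ct$estimate)
  base$r_squared <- unname(ct$estimate)^2
  base$p <- ct$p.value
  base
}

#' Run the full two-group and correlation battery
#'
#' For every metric present in the patient-level summaries: (i) compare the
#' HIGH vs LOW HLA-DR strata with [two_group_compare()]; (ii) correlate the
#' metric with the per-patient HLA-DR surface-area percent with
#' [bivariate_correlation()]. Benjamini-Hochberg adjustment is applied to the
#' comparison p-values within each metric family (the reporting panels:
#' distances, engagement, infiltration, mixing, activation).
#'
#' @param patient_summaries Patient-level summary rows from
#'   [aggregate_patients()].
#' @param patients Patients data frame with `patient_id`, `hladr_mean_pct`,
#'   and `stratum` set (see [stratify_cohort()]).
#' @param alpha_normality Shapiro-Wilk gate level for [two_group_compare()].
#' @return List with data frames `comparisons` (one row per metric, with
#'   `family` and `p_adjusted` filled per family) and `correlations`.
#' @export
run_comparison_battery <- function(patient_summaries, patients,
                                   alpha_normality = 0.05) {
  stopifnot(all(c("patient_id", "hladr_mean_pct", "stratum") %in% names(patients)))
  if (any(is.na(patients$stratum))) stop("strata must be assigned first")
  ids <- unique(patient_summaries$metric_id)
  comp <- list(); corr <- list()
  for (mid in ids) {
    rowsm <- patient_summaries[patient_summaries$metric_id == mid, , drop = FALSE]
    m <- merge(rowsm[, c("patient_id", "value")], patients, by = "patient_id")
    cr <- two_group_compare(m$value[m$stratum == "HIGH"],
                            m$value[m$stratum == "LOW"],
                            alpha_normality = alpha_normality, metric = mid)
    cr$family <- rowsm$family[1]
    comp[[mid]] <- cr
    co <- bivariate_correlation(m$hladr_mean_pct, m$value, metric = mid,
                                covariate = "hladr_mean_pct")
    co$family <- rowsm$family[1]
    corr[[mid]] <- co
  }
  comparisons <- do.call(rbind, comp)
  rownames(comparisons) <- NULL
  for (fam in unique(comparisons$family)) {
    sel <- comparisons$family == fam & !is.na(comparisons$p_raw)
    comparisons$p_adjusted[sel] <- bh_adjust(comparisons$p_raw[sel])
  }
  correlations <- do.call(rbind, corr)
  rownames(correlations) <- NULL
  list(comparisons = comparisons, correlations = correlations)
}
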