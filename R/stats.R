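## Statistical kernel used throughout the pipeline. Each routine returns a
## plain list so callers can vapply over regions/sites without S4 overhead.
## All p-values are two-sided; directionality of hypermethylation is enforced
## downstream by the delta-beta sign filter, never by one-sided testing.

test_result <- function(statistic, df, p) {
  list(statistic = unname(statistic), df = unname(df), p_two_sided = unname(p))
}

#' Beta-value from methylated/unmethylated intensities
#'
#' beta = M / (M + U), the fraction-methylated readout of Infinium-style
#' arrays. Undefined (missing) when both intensities are zero.
#'
#' @param m_intensity Methylated signal intensity (non-negative).
#' @param u_intensity Unmethylated signal intensity (non-negative).
#' @return Beta-value in \[0, 1\]; \code{NA} where \code{m + u == 0}.
#' @export
beta_value <- function(m_intensity, u_intensity) {
  if (any(m_intensity < 0 | u_intensity < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  total <- m_intensity + u_intensity
  ifelse(total == 0, NA_real_, m_intensity / total)
}

#' Paired t-test on a vector of differences
#'
#' One-sample t-test of paired differences against zero, the region-level
#' test of the hypermethylation screen. Zero-variance input with a nonzero
#' mean is reported with \code{p = 0} and flagged \code{degenerate}; zero
#' variance with zero mean carries no information and errors.
#'
#' @param differences Numeric vector of paired differences (NAs dropped).
#' @return List with \code{statistic}, \code{df}, \code{p_two_sided}, and
#'   logical \code{degenerate}.
#' @export
paired_t <- function(differences) {
  d <- differences[is.finite(differences)]
  if (length(d) < 2) stop("paired_t needs >= 2 finite differences", call. = FALSE)
  if (sd(d) == 0) {
    if (mean(d) == 0) stop("paired_t: zero variance and zero mean (undefined)", call. = FALSE)
    res <- test_result(sign(mean(d)) * Inf, length(d) - 1, 0)
    res$degenerate <- TRUE
    return(res)
  }
  ht <- t.test(d, mu = 0)
  res <- test_result(ht$statistic, ht$parameter, ht$p.value)
  res$degenerate <- FALSE
  res
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom), used for
#' unpaired group comparisons such as smoker vs. never-smoker strata.
#'
#' @param x,y Numeric vectors, each with >= 2 finite values.
#' @return List with \code{statistic}, \code{df}, \code{p_two_sided}.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("welch_t needs >= 2 values per group", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(test_result(0, length(x) + length(y) - 2, 1))
    res <- test_result(sign(mean(x) - mean(y)) * Inf, length(x) + length(y) - 2, 0)
    return(res)
  }
  ht <- t.test(x, y, var.equal = FALSE)
  test_result(ht$statistic, ht$parameter, ht$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test; exact null distribution for small samples
#' (n <= 25 per group, no ties), normal approximation otherwise.
#'
#' @param x,y Numeric vectors, each with >= 2 finite values.
#' @return List with \code{statistic} (U), \code{df} (NA), \code{p_two_sided}.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("mann_whitney_u needs >= 2 values per group", call. = FALSE)
  exact <- length(x) <= 25 && length(y) <= 25
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  test_result(ht$statistic, NA_real_, ht$p.value)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test of differences against zero; exact null for
#' n <= 25 non-zero differences without ties, normal approximation otherwise.
#' Zero differences are dropped (standard convention); all-zero input errors.
#'
#' @param differences Numeric vector of paired differences.
#' @return List with \code{statistic} (V), \code{df} (NA), \code{p_two_sided}.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[is.finite(differences)]
  d <- d[d != 0]
  if (length(d) < 1) stop("wilcoxon_signed_rank: no non-zero differences", call. = FALSE)
  exact <- length(d) <= 25
  ht <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact, correct = !exact))
  test_result(ht$statistic, NA_real_, ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-adjusted p-values (one family per call); adjusted values are capped at
#' 1, elementwise >= raw, and order-preserving up to ties.
#'
#' @param raw_p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same order as input.
#' @export
bh_adjust <- function(raw_p) {
  if (length(raw_p) == 0) return(numeric(0))
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(raw_p, method = "BH")
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation; p-value from the t transform with n - 2 degrees of
#' freedom. Requires n >= 3 complete observations and non-constant input.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{r}, \code{p_two_sided}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("pearson_r needs >= 3 complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("pearson_r: constant input", call. = FALSE)
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_two_sided = ht$p.value, n = length(x))
}

#' Floored log2 fold change
#'
#' log2(max(treated, floor) / max(control, floor)). The floor keeps
#' qRT-PCR-style non-detects (zeros) from producing infinities.
#'
#' @param treated,control Non-negative expression values.
#' @param floor Positive detection floor (default \code{1e-3}).
#' @return Log2 fold change.
#' @export
log2_fold_change <- function(treated, control, floor = 1e-3) {
  stopifnot(floor > 0)
  if (any(treated < 0 | control < 0, na.rm = TRUE)) {
    stop("expression values must be >= 0", call. = FALSE)
  }
  log2(pmax(treated, floor) / pmax(control, floor))
}
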