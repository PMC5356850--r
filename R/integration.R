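## Validation analyses downstream of the funnel: site-level paired
## percent-methylation comparisons, methylation-expression inverse
## correlation, and smoking-status stratification.

#' Paired site-level percent-methylation comparison
#'
#' Per site: mean tumor and normal percent methylation, mean paired
#' difference, and a paired test on (tumor - normal) — paired t by default or
#' the Wilcoxon signed-rank test when \code{use_rank_test = TRUE} (the caller
#' chooses; normality is never auto-tested). P-values are BH-adjusted across
#' sites. Sites with fewer than \code{min_pairs} complete pairs or all-zero
#' differences are excluded with a warning.
#'
#' @param sites Site methylation table (site_id, sample, percent_meth).
#' @param design Paired design.
#' @param use_rank_test Use the signed-rank test instead of the paired t.
#' @param min_pairs Minimum complete pairs per site.
#' @return data.frame: site_id, n_pairs, mean_tumor_pct, mean_normal_pct,
#'   mean_paired_difference_pct, statistic, raw_p, adjusted_p.
#' @export
paired_site_comparison <- function(sites, design, use_rank_test = FALSE,
                                   min_pairs = 3) {
  design <- validate_design(design)
  sites <- validate_site_methylation(sites)
  per_site <- lapply(split(sites, sites$site_id), function(s) {
    vals <- setNames(s$percent_meth, s$sample)
    tum <- vals[design$tumor_sample]
    nor <- vals[design$normal_sample]
    ok <- !is.na(tum) & !is.na(nor)
    d <- tum[ok] - nor[ok]
    if (sum(ok) < min_pairs || all(d == 0)) return(NULL)
    res <- if (use_rank_test) wilcoxon_signed_rank(d) else paired_t(d)
    data.frame(site_id = s$site_id[1], n_pairs = sum(ok),
               mean_tumor_pct = mean(tum[ok]), mean_normal_pct = mean(nor[ok]),
               mean_paired_difference_pct = mean(d),
               statistic = res$statistic, raw_p = res$p_two_sided,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(per_site, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("paired_site_comparison: excluded %d site(s) (too few pairs or all-zero differences)",
                    dropped), call. = FALSE)
  }
  out <- do.call(rbind, per_site)
  if (is.null(out)) {
    return(data.frame(site_id = character(), n_pairs = integer(),
                      mean_tumor_pct = numeric(), mean_normal_pct = numeric(),
                      mean_paired_difference_pct = numeric(),
                      statistic = numeric(), raw_p = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  }
  out$adjusted_p <- bh_adjust(out$raw_p)
  rownames(out) <- NULL
  out
}

#' Methylation-expression correlation per (gene, site)
#'
#' Pearson correlation between site-level percent methylation and relative
#' expression, pooled across tumor and paired-normal samples by default
#' (\code{compartment = "pooled"}), or restricted to one compartment.
#' Pairs with a constant vector are flagged not-evaluable (\code{NA} result)
#' rather than erroring.
#'
#' @param sites Site methylation table.
#' @param expr Expression table (contexts \code{tumor}, \code{normal_pair};
#'   sample ids shared with \code{sites}).
#' @param gene_site_map data.frame with columns \code{gene}, \code{site_id}.
#' @param compartment \code{"pooled"}, \code{"tumor"} or \code{"normal"}.
#' @return data.frame: gene, site_id, r, p, n, evaluable.
#' @export
methylation_expression_correlation <- function(sites, expr, gene_site_map,
                                               compartment = c("pooled", "tumor", "normal")) {
  compartment <- match.arg(compartment)
  contexts <- switch(compartment, pooled = c("tumor", "normal_pair"),
                     tumor = "tumor", normal = "normal_pair")
  rows <- lapply(seq_len(nrow(gene_site_map)), function(i) {
    g <- gene_site_map$gene[i]; s <- gene_site_map$site_id[i]
    meth <- sites[sites$site_id == s, , drop = FALSE]
    ex <- expr[expr$gene == g & expr$context %in% contexts, , drop = FALSE]
    merged <- merge(meth[, c("sample", "percent_meth")],
                    ex[, c("sample", "rel_expr")], by = "sample")
    merged <- merged[complete.cases(merged), , drop = FALSE]
    base <- data.frame(gene = g, site_id = s, r = NA_real_, p = NA_real_,
                       n = nrow(merged), evaluable = FALSE,
                       stringsAsFactors = FALSE)
    if (nrow(merged) < 3 || sd(merged$percent_meth) == 0 || sd(merged$rel_expr) == 0) {
      return(base)
    }
    res <- pearson_r(merged$percent_meth, merged$rel_expr)
    base$r <- res$r; base$p <- res$p_two_sided; base$n <- res$n
    base$evaluable <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smoking-status stratified comparison
#'
#' Compares a per-sample quantity (e.g. site percent methylation or region
#' beta) between smoker (S) and never-smoker (NS) strata within one tissue
#' compartment, using Welch's t-test or (flag) the Mann-Whitney U test.
#'
#' @param values Named numeric vector, names are sample ids.
#' @param design Paired design with smoking_status.
#' @param tissue \code{"tumor"} or \code{"normal"}.
#' @param use_rank_test Use Mann-Whitney instead of Welch.
#' @return List: test result plus per-group summaries (n, mean, sd).
#' @export
smoking_stratified_comparison <- function(values, design,
                                          tissue = c("tumor", "normal"),
                                          use_rank_test = FALSE) {
  tissue <- match.arg(tissue)
  design <- validate_design(design)
  col <- if (tissue == "tumor") design$tumor_sample else design$normal_sample
  v <- values[col]
  grp <- design$smoking_status
  s_vals <- v[grp == "S" & !is.na(v)]
  ns_vals <- v[grp == "NS" & !is.na(v)]
  if (length(s_vals) == 0 || length(ns_vals) == 0) {
    stop("smoking_stratified_comparison: a stratum is empty", call. = FALSE)
  }
  res <- if (use_rank_test) mann_whitney_u(s_vals, ns_vals) else welch_t(s_vals, ns_vals)
  list(test = res,
       groups = data.frame(
         group = c("S", "NS"),
         n = c(length(s_vals), length(ns_vals)),
         mean = c(mean(s_vals), mean(ns_vals)),
         sd = c(sd(s_vals), sd(ns_vals)),
         stringsAsFactors = FALSE))
}
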