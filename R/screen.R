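## Region-level differential methylation screen: probe -> CGI aggregation,
## per-pair beta-differences, paired testing, BH correction across one family,
## threshold filtering and deterministic ranking.

#' Screen parameters
#'
#' Defaults reproduce the published screening rule: BH-adjusted p < 0.05 and
#' tumor-minus-normal beta-difference > 0.25 in the hypermethylated direction,
#' with the top 10 regions carried forward to expression follow-up.
#'
#' @param fdr_cut FDR threshold (strict \code{<}), default 0.05.
#' @param delta_cut Beta-difference threshold (strict \code{>}), default 0.25.
#' @param direction One of \code{"hyper"}, \code{"hypo"}, \code{"both"}.
#' @param top_k Size of the top-ranked view, default 10.
#' @param min_probes Minimum non-missing probes per (region, sample) summary.
#' @param min_pairs Minimum complete pairs for a region to be tested.
#' @param summary_method Per-sample probe aggregation before pair differencing
#'   (\code{"median"}, the default, or \code{"mean"}); \code{"probe_diff_median"}
#'   instead takes per-probe pair differences first and the median across
#'   probes second.
#' @return List of validated screen parameters.
#' @export
screen_params <- function(fdr_cut = 0.05, delta_cut = 0.25,
                          direction = c("hyper", "hypo", "both"),
                          top_k = 10, min_probes = 1, min_pairs = 3,
                          summary_method = c("median", "mean", "probe_diff_median")) {
  direction <- match.arg(direction)
  summary_method <- match.arg(summary_method)
  stopifnot(fdr_cut > 0, fdr_cut < 1, delta_cut > 0, delta_cut < 1,
            top_k >= 1, min_probes >= 1, min_pairs >= 2)
  list(fdr_cut = fdr_cut, delta_cut = delta_cut, direction = direction,
       top_k = as.integer(top_k), min_probes = as.integer(min_probes),
       min_pairs = as.integer(min_pairs), summary_method = summary_method)
}

#' Assign probes to CGI regions by coordinate containment
#'
#' A probe belongs to every region whose half-open interval contains its
#' 1-based CpG position. Regions without any probe are dropped (count
#' reported via \code{message}).
#'
#' @param manifest Probe manifest (probe_id, chrom, pos).
#' @param regions Region table from [read_regions_bed()].
#' @return Named list: region_id -> character vector of member probe ids.
#' @export
assign_probes <- function(manifest, regions) {
  probe_gr <- GenomicRanges::GRanges(
    manifest$chrom, IRanges::IRanges(manifest$pos, manifest$pos))
  region_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(region_gr, probe_gr)
  mapping <- split(manifest$probe_id[S4Vectors::subjectHits(hits)],
                   regions$region_id[S4Vectors::queryHits(hits)])
  n_empty <- nrow(regions) - length(mapping)
  if (n_empty > 0) {
    message(sprintf("assign_probes: dropped %d region(s) with no probes", n_empty))
  }
  mapping[intersect(regions$region_id, names(mapping))]
}

#' Summarize probe beta-values per region and sample
#'
#' Per (region, sample): the median (default) of the non-missing member-probe
#' beta-values; \code{NA} when fewer than \code{min_probes} probes have data.
#'
#' @param beta Probe x sample beta matrix.
#' @param mapping Output of [assign_probes()].
#' @param min_probes Minimum number of non-missing probe values.
#' @param method \code{"median"} or \code{"mean"}.
#' @return Region x sample numeric matrix of summary beta-values.
#' @export
summarize_regions <- function(beta, mapping, min_probes = 1, method = "median") {
  stopifnot(length(mapping) > 0)
  fun <- switch(method, median = median, mean = mean,
                stop("unknown summary method: ", method))
  out <- t(vapply(mapping, function(probes) {
    sub <- beta[probes, , drop = FALSE]
    s <- apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < min_probes) NA_real_ else fun(v)
    })
    s
  }, numeric(ncol(beta))))
  colnames(out) <- colnames(beta)
  out
}

#' Per-pair beta-differences
#'
#' Delta-beta(region, pair) = tumor summary beta minus matched normal summary
#' beta; \code{NA} when either side is missing.
#'
#' @param summary Region x sample summary matrix from [summarize_regions()].
#' @param design Paired design data.frame.
#' @return Region x pair matrix of delta-beta, columns named by patient_id.
#' @export
paired_differences <- function(summary, design) {
  design <- validate_design(design)
  check_design_samples(design, colnames(summary))
  diff <- summary[, design$tumor_sample, drop = FALSE] -
    summary[, design$normal_sample, drop = FALSE]
  colnames(diff) <- design$patient_id
  diff
}

#' Paired t-test + BH correction per region
#'
#' For each region with at least \code{min_pairs} complete pair differences
#' and non-degenerate variance: mean delta-beta, paired t statistic, raw
#' two-sided p, and BH-adjusted p computed across all tested regions as one
#' family (hyper- and hypomethylated tails together).
#'
#' @param diff_matrix Region x pair delta-beta matrix.
#' @param min_pairs Minimum complete pairs per region.
#' @return data.frame with one row per tested region: region_id, n_pairs,
#'   delta_beta, t_stat, raw_p, adjusted_p.
#' @export
differential_test <- function(diff_matrix, min_pairs = 3) {
  n_ok <- rowSums(is.finite(diff_matrix))
  sds <- apply(diff_matrix, 1, function(d) sd(d[is.finite(d)]))
  testable <- n_ok >= min_pairs & !is.na(sds) & sds > 0
  if (any(!testable)) {
    warning(sprintf("differential_test: excluded %d region(s) with < %d pairs or degenerate variance",
                    sum(!testable), min_pairs), call. = FALSE)
  }
  kept <- diff_matrix[testable, , drop = FALSE]
  stats <- t(apply(kept, 1, function(d) {
    res <- paired_t(d)
    c(mean(d[is.finite(d)]), res$statistic, res$p_two_sided)
  }))
  data.frame(
    region_id = rownames(kept),
    n_pairs = as.integer(n_ok[testable]),
    delta_beta = stats[, 1],
    t_stat = stats[, 2],
    raw_p = stats[, 3],
    adjusted_p = bh_adjust(stats[, 3]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Filter and rank differential regions
#'
#' Keeps regions with \code{adjusted_p < fdr_cut} (strict) and a directional
#' delta-beta (hyper: \code{> delta_cut}; hypo: \code{< -delta_cut}; both:
#' \code{|delta| > delta_cut}); sorts ascending by adjusted p, ties broken by
#' descending |delta-beta|, then region id. Truncation to the top-k view is a
#' separate step ([top_regions()]).
#'
#' @param records Output of [differential_test()].
#' @param params Output of [screen_params()].
#' @return The selected records, ranked, with a \code{rank} column.
#' @export
select_and_rank <- function(records, params = screen_params()) {
  keep <- records$adjusted_p < params$fdr_cut
  keep <- keep & switch(params$direction,
    hyper = records$delta_beta > params$delta_cut,
    hypo = records$delta_beta < -params$delta_cut,
    both = abs(records$delta_beta) > params$delta_cut)
  sel <- records[keep, , drop = FALSE]
  ord <- order(sel$adjusted_p, -abs(sel$delta_beta), sel$region_id)
  sel <- sel[ord, , drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' @rdname select_and_rank
#' @param ranked Ranked records from [select_and_rank()].
#' @param k Number of top regions to keep.
#' @export
top_regions <- function(ranked, k = 10) {
  head(ranked, k)
}

#' Run the full region-level differential methylation screen
#'
#' Convenience wrapper: probe assignment, per-sample region summaries,
#' per-pair differences, paired testing with BH correction, and ranking.
#' Region annotation (coordinates, gene, context) is joined onto the output.
#'
#' @param beta Probe x sample beta matrix.
#' @param manifest Probe manifest.
#' @param regions Region table.
#' @param design Paired design.
#' @param params Screen parameters from [screen_params()].
#' @return List with \code{records} (all tested regions, annotated, with
#'   \code{selected} flag and \code{rank} for selected ones), \code{selected}
#'   (ranked subset) and \code{top} (top-k view).
#' @export
screen_regions <- function(beta, manifest, regions, design,
                           params = screen_params()) {
  mapping <- assign_probes(manifest, regions)
  if (params$summary_method == "probe_diff_median") {
    design <- validate_design(design)
    check_design_samples(design, colnames(beta))
    probe_diff <- beta[, design$tumor_sample, drop = FALSE] -
      beta[, design$normal_sample, drop = FALSE]
    colnames(probe_diff) <- design$patient_id
    diff <- summarize_regions(probe_diff, mapping, params$min_probes)
  } else {
    summary <- summarize_regions(beta, mapping, params$min_probes,
                                 method = params$summary_method)
    diff <- paired_differences(summary, design)
  }
  records <- differential_test(diff, params$min_pairs)
  records$n_probes <- lengths(mapping)[records$region_id]
  ann <- regions[match(records$region_id, regions$region_id),
                 c("chrom", "start", "end", "gene", "gene_context")]
  records <- cbind(records, ann)
  rownames(records) <- NULL
  selected <- select_and_rank(records, params)
  records$selected <- records$region_id %in% selected$region_id
  records$rank <- selected$rank[match(records$region_id, selected$region_id)]
  list(records = records, selected = selected,
       top = top_regions(selected, params$top_k), params = params)
}

#' Volcano-plot export
#'
#' Per tested region: delta-beta (x) and -log10 adjusted p (y), plus the
#' selection flag — the data behind the conventional volcano display.
#'
#' @param records Annotated records from [screen_regions()].
#' @return data.frame with columns region_id, delta_beta, neg_log10_adj_p,
#'   selected.
#' @export
volcano_data <- function(records) {
  data.frame(
    region_id = records$region_id,
    delta_beta = records$delta_beta,
    neg_log10_adj_p = -log10(records$adjusted_p),
    selected = records$selected,
    stringsAsFactors = FALSE
  )
}
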