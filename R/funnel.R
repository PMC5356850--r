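## Four-criterion candidate funnel over gene-level relative expression:
## (1) expressed in normal lung, (2) frequently downregulated in tumors vs
## paired normals, (3) frequently silenced in cancer cell lines vs normal
## lung, (4) frequently re-expressed after demethylating treatment.
## All ratio/fold-change comparisons are strict (">" / "<"); frequency
## criteria compare k against panel-rescaled minimum counts.

#' Funnel thresholds
#'
#' Defaults encode the published evidence rules: >50% tumor downregulation
#' (ratio < 0.5) in at least 6 of 11 cases; >80% cell-line reduction
#' (ratio < 0.2) in at least 8 of 14 lines; >4-fold (log2 > 2) re-expression
#' under 5-aza-2'-deoxycytidine in at least 2 of 3 treated lines. When a
#' panel's actual size differs from the reference size, the minimum count is
#' rescaled as \code{ceiling(min_count / panel_ref * panel_actual)}, which
#' reproduces 6/11, 8/14 and 2/3 exactly at the reference sizes.
#'
#' @param tumor_ratio_cut Tumor/normal ratio cut (strict \code{<}), default 0.5.
#' @param tumor_min_count,tumor_panel Minimum silenced pairs per reference
#'   panel size (6 of 11).
#' @param cell_ratio_cut Cell-line/normal-lung ratio cut (strict \code{<}),
#'   default 0.2.
#' @param cell_min_count,cell_panel Minimum silenced lines per reference panel
#'   size (8 of 14).
#' @param restore_log2_cut Log2 fold-change cut (strict \code{>}), default 2.
#' @param restore_min_count,restore_panel Minimum restored lines per reference
#'   panel size (2 of 3).
#' @param detect_floor Expression detection floor, default 1e-3.
#' @return List of validated thresholds.
#' @export
funnel_thresholds <- function(tumor_ratio_cut = 0.5, tumor_min_count = 6, tumor_panel = 11,
                              cell_ratio_cut = 0.2, cell_min_count = 8, cell_panel = 14,
                              restore_log2_cut = 2, restore_min_count = 2, restore_panel = 3,
                              detect_floor = 1e-3) {
  stopifnot(tumor_ratio_cut > 0, cell_ratio_cut > 0, restore_log2_cut > 0,
            detect_floor > 0,
            tumor_min_count <= tumor_panel, cell_min_count <= cell_panel,
            restore_min_count <= restore_panel)
  list(tumor_ratio_cut = tumor_ratio_cut, tumor_min_count = tumor_min_count,
       tumor_panel = tumor_panel, cell_ratio_cut = cell_ratio_cut,
       cell_min_count = cell_min_count, cell_panel = cell_panel,
       restore_log2_cut = restore_log2_cut, restore_min_count = restore_min_count,
       restore_panel = restore_panel, detect_floor = detect_floor)
}

#' Rescale a frequency minimum count to an observed panel size
#'
#' @param min_count,panel_ref Reference rule (e.g. 6 of 11).
#' @param n_actual Observed panel size.
#' @return Integer minimum count for the observed panel.
#' @export
rescale_min_count <- function(min_count, panel_ref, n_actual) {
  as.integer(ceiling(min_count / panel_ref * n_actual))
}

expr_values <- function(expr, gene_, context_) {
  expr$rel_expr[expr$gene == gene_ & expr$context == context_]
}

expr_by_sample <- function(expr, gene_, context_) {
  sub <- expr[expr$gene == gene_ & expr$context == context_, , drop = FALSE]
  setNames(sub$rel_expr, sub$sample)
}

#' Classify normal-lung expression status
#'
#' A gene is \code{very_low} when every normal-reference and paired-normal
#' value sits below the detection floor (qRT-PCR "undetermined"), and when no
#' normal records exist at all; otherwise \code{expressed}. \code{very_low}
#' genes short-circuit the funnel: the remaining criteria are not evaluated.
#'
#' @param expr Expression table.
#' @param gene Gene symbol.
#' @param detect_floor Detection floor.
#' @return \code{"expressed"} or \code{"very_low"}.
#' @export
classify_normal_expression <- function(expr, gene, detect_floor = 1e-3) {
  vals <- c(expr_values(expr, gene, "normal_reference"),
            expr_values(expr, gene, "normal_pair"))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0 || all(vals < detect_floor)) "very_low" else "expressed"
}

#' Tumor-silencing fraction
#'
#' k = number of tumor/paired-normal sample pairs whose expression ratio falls
#' strictly below \code{tumor_ratio_cut}; pairs whose normal-side value is
#' below the detection floor are excluded from the denominator (a ratio
#' against a non-detect is meaningless).
#'
#' @param expr Expression table (contexts \code{tumor} and \code{normal_pair}
#'   matched by sample id).
#' @param gene Gene symbol.
#' @param thresholds Output of [funnel_thresholds()].
#' @return List \code{(k, n)}; \code{n = 0} marks the criterion not evaluable.
#' @export
tumor_silencing <- function(expr, gene, thresholds = funnel_thresholds()) {
  tum <- expr_by_sample(expr, gene, "tumor")
  nor <- expr_by_sample(expr, gene, "normal_pair")
  shared <- intersect(names(tum), names(nor))
  nor <- nor[shared]; tum <- tum[shared]
  usable <- !is.na(tum) & !is.na(nor) & nor >= thresholds$detect_floor
  ratio <- tum[usable] / nor[usable]
  list(k = sum(ratio < thresholds$tumor_ratio_cut), n = sum(usable))
}

#' Cell-line silencing fraction
#'
#' k = number of cell lines whose expression relative to the normal-lung
#' reference falls strictly below \code{cell_ratio_cut}. The reference is the
#' mean of \code{normal_reference} records.
#'
#' @inheritParams tumor_silencing
#' @return List \code{(k, n)}; \code{n = 0} when the reference is missing or
#'   below the detection floor.
#' @export
cellline_silencing <- function(expr, gene, thresholds = funnel_thresholds()) {
  ref <- expr_values(expr, gene, "normal_reference")
  ref <- mean(ref[!is.na(ref)])
  lines <- expr_values(expr, gene, "cell_line")
  lines <- lines[!is.na(lines)]
  if (!is.finite(ref) || ref < thresholds$detect_floor || length(lines) == 0) {
    return(list(k = 0L, n = 0L))
  }
  list(k = sum(lines / ref < thresholds$cell_ratio_cut), n = length(lines))
}

#' Pharmacologic restoration fraction
#'
#' k = number of treated cell lines whose floored log2 fold change
#' (treated vs. matched vehicle, same sample id) strictly exceeds
#' \code{restore_log2_cut}.
#'
#' @inheritParams tumor_silencing
#' @return List \code{(k, n)}; \code{n = 0} when no treated/vehicle pairs.
#' @export
restoration <- function(expr, gene, thresholds = funnel_thresholds()) {
  trt <- expr_by_sample(expr, gene, "treated")
  veh <- expr_by_sample(expr, gene, "vehicle")
  shared <- intersect(names(trt), names(veh))
  trt <- trt[shared]; veh <- veh[shared]
  ok <- !is.na(trt) & !is.na(veh)
  lfc <- log2_fold_change(trt[ok], veh[ok], thresholds$detect_floor)
  list(k = sum(lfc > thresholds$restore_log2_cut), n = sum(ok))
}

#' Compute per-gene funnel evidence from expression data
#'
#' @param expr Expression table.
#' @param genes Character vector of candidate gene symbols.
#' @param thresholds Output of [funnel_thresholds()].
#' @return Evidence data.frame (one row per gene) accepted by
#'   [evaluate_funnel()]. Criteria of \code{very_low} genes are reported as
#'   \code{NA} fractions, mirroring the dashes of printed evidence tables.
#' @export
compute_gene_evidence <- function(expr, genes, thresholds = funnel_thresholds()) {
  rows <- lapply(genes, function(g) {
    status <- classify_normal_expression(expr, g, thresholds$detect_floor)
    if (status == "very_low") {
      return(data.frame(gene = g, gene_context = NA_character_,
                        normal_expression = status,
                        tumor_k = NA_integer_, tumor_n = NA_integer_,
                        cell_k = NA_integer_, cell_n = NA_integer_,
                        restore_k = NA_integer_, restore_n = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    tf <- tumor_silencing(expr, g, thresholds)
    cf <- cellline_silencing(expr, g, thresholds)
    rf <- restoration(expr, g, thresholds)
    data.frame(gene = g, gene_context = NA_character_, normal_expression = status,
               tumor_k = as.integer(tf$k), tumor_n = as.integer(tf$n),
               cell_k = as.integer(cf$k), cell_n = as.integer(cf$n),
               restore_k = as.integer(rf$k), restore_n = as.integer(rf$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the four funnel criteria to a gene-evidence table
#'
#' Pass rules: \code{expressed} in normal lung; tumor k >= rescaled minimum
#' count; cell-line k >= rescaled minimum count; restoration k >= rescaled
#' minimum count. A criterion with \code{n = 0} or \code{NA} fraction is not
#' evaluable and fails. Output is sorted by (passes_all desc, number of
#' criteria passed desc, tumor fraction desc, gene) for a deterministic
#' ranking.
#'
#' @param evidence Evidence data.frame ([compute_gene_evidence()] or
#'   [read_evidence()]).
#' @param thresholds Output of [funnel_thresholds()].
#' @return Evidence with per-criterion pass flags, \code{n_criteria_passed}
#'   and \code{passes_all}, ranked; thresholds attached as attribute
#'   \code{"thresholds"}.
#' @export
evaluate_funnel <- function(evidence, thresholds = funnel_thresholds()) {
  frac_pass <- function(k, n, min_count, panel_ref) {
    need <- rescale_min_count(min_count, panel_ref, n)
    !is.na(k) & !is.na(n) & n > 0 & k >= need
  }
  ev <- evidence
  ev$pass_normal <- ev$normal_expression == "expressed"
  ev$pass_tumor <- frac_pass(ev$tumor_k, ev$tumor_n,
                             thresholds$tumor_min_count, thresholds$tumor_panel)
  ev$pass_cell <- frac_pass(ev$cell_k, ev$cell_n,
                            thresholds$cell_min_count, thresholds$cell_panel)
  ev$pass_restore <- frac_pass(ev$restore_k, ev$restore_n,
                               thresholds$restore_min_count, thresholds$restore_panel)
  ev$n_criteria_passed <- ev$pass_normal + ev$pass_tumor + ev$pass_cell + ev$pass_restore
  ev$passes_all <- ev$pass_normal & ev$pass_tumor & ev$pass_cell & ev$pass_restore
  tumor_frac <- ifelse(is.na(ev$tumor_n) | ev$tumor_n == 0, -1, ev$tumor_k / ev$tumor_n)
  ord <- order(-ev$passes_all, -ev$n_criteria_passed, -tumor_frac, ev$gene)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "thresholds") <- thresholds
  ev
}

#' Run the candidate funnel on expression data
#'
#' Computes per-gene evidence with [compute_gene_evidence()] and applies the
#' criteria with [evaluate_funnel()]. An empty candidate list yields an empty
#' report.
#'
#' @param genes Candidate gene symbols (typically the genes annotated to the
#'   top regions of [screen_regions()]).
#' @param expr Expression table.
#' @param thresholds Output of [funnel_thresholds()].
#' @return Ranked funnel report data.frame (see [evaluate_funnel()]).
#' @export
run_funnel <- function(genes, expr, thresholds = funnel_thresholds()) {
  genes <- unique(genes[!is.na(genes)])
  if (length(genes) == 0) {
    ev <- evaluate_funnel(data.frame(
      gene = character(), gene_context = character(),
      normal_expression = character(),
      tumor_k = integer(), tumor_n = integer(),
      cell_k = integer(), cell_n = integer(),
      restore_k = integer(), restore_n = integer(),
      stringsAsFactors = FALSE), thresholds)
    return(ev)
  }
  evaluate_funnel(compute_gene_evidence(expr, genes, thresholds), thresholds)
}

#' Write a funnel report
#'
#' TSV plus JSON companions; the JSON embeds the thresholds that produced the
#' report so every output names its parameters.
#'
#' @param report Output of [run_funnel()] / [evaluate_funnel()].
#' @param path Output TSV path (a sibling \code{.json} is written too).
#' @return Invisibly, \code{path}.
#' @export
write_funnel_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(thresholds = attr(report, "thresholds"),
         report = report),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
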