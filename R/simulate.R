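## Seeded synthetic-cohort generator. Emulates the statistical structure the
## screen assumes: low non-tumor CGI methylation (beta ~ 0.1-0.2), planted
## tumor-specific hypermethylation of configurable effect size in a fraction
## of regions, and expression panels in which the genes of planted regions
## are silenced in tumors/cell lines and re-expressed after demethylating
## treatment. Ground-truth labels accompany every cohort.

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

## All random streams derive from one master seed so partial regeneration is
## reproducible: stream k uses ((seed + 1000003 * k) mod (2^31 - 2)) + 1.
derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483646) + 1000003 * stream) %% 2147483646 + 1
}

#' Simulation configuration
#'
#' Defaults mirror the discovery-cohort design the pipeline targets: 12
#' tumor/normal pairs split 6 smokers / 6 never-smokers, 1000 CGI regions of
#' 3-15 probes, a Beta(3, 17) baseline (mean 0.15, the 0.1-0.2 band typical
#' of unmethylated CGIs), hypermethylation planted in 5% of regions with mean
#' effect delta-beta 0.3 (the regime of top published screen hits,
#' delta-beta 0.25-0.37), per-probe noise sd 0.03, 14 cell lines of which 3
#' carry treated/vehicle arms, and 5-50x re-expression of silenced genes
#' under demethylating treatment.
#'
#' @param n_pairs Number of tumor/normal pairs (default 12).
#' @param n_regions Number of CGI regions (default 1000).
#' @param probes_per_region Inclusive range of probes per region, default
#'   \code{c(3, 15)}.
#' @param baseline_shape1,baseline_shape2 Beta-distribution parameters of the
#'   non-tumor baseline (default 3 and 17, mean 0.15).
#' @param planted_fraction Fraction of regions with planted hypermethylation.
#' @param effect_delta Mean planted tumor shift in beta (default 0.3).
#' @param effect_sd SD of the planted per-region shift (default 0.05).
#' @param probe_noise_sd Per-probe, per-sample noise sd (default 0.03).
#' @param smoking_split Integer c(S, NS) split of the pairs (default 6/6).
#' @param coupling Couple expression silencing to planted methylation
#'   (default TRUE); when FALSE all genes follow the null expression model.
#' @param tumor_silenced_prob Probability a tumor/normal pair of a silenced
#'   gene shows a ratio below 0.5 (default 0.9).
#' @param cell_silenced_prob Probability a cell line of a silenced gene falls
#'   below 20% of normal lung (default 0.75, i.e. about 10 of 14 lines).
#' @param restore_fold_range Fold-change range for re-expression of silenced
#'   genes under treatment (default 5-50).
#' @param n_cell_lines Cell-line panel size (default 14).
#' @param n_restore_lines Lines with treated/vehicle arms (default 3).
#' @param seed Master seed; all streams derive from it.
#' @return Validated configuration list.
#' @export
sim_config <- function(n_pairs = 12, n_regions = 1000,
                       probes_per_region = c(3, 15),
                       baseline_shape1 = 3, baseline_shape2 = 17,
                       planted_fraction = 0.05, effect_delta = 0.3,
                       effect_sd = 0.05, probe_noise_sd = 0.03,
                       smoking_split = c(6, 6), coupling = TRUE,
                       tumor_silenced_prob = 0.9, cell_silenced_prob = 0.75,
                       restore_fold_range = c(5, 50),
                       n_cell_lines = 14, n_restore_lines = 3, seed = 1) {
  stopifnot(n_pairs >= 2, n_regions >= 1,
            length(probes_per_region) == 2,
            probes_per_region[1] >= 1,
            probes_per_region[1] <= probes_per_region[2],
            baseline_shape1 > 0, baseline_shape2 > 0,
            planted_fraction >= 0, planted_fraction <= 1,
            effect_sd >= 0, probe_noise_sd >= 0,
            length(smoking_split) == 2, sum(smoking_split) == n_pairs,
            tumor_silenced_prob >= 0, tumor_silenced_prob <= 1,
            cell_silenced_prob >= 0, cell_silenced_prob <= 1,
            length(restore_fold_range) == 2,
            restore_fold_range[1] <= restore_fold_range[2],
            n_restore_lines <= n_cell_lines)
  baseline_mean <- baseline_shape1 / (baseline_shape1 + baseline_shape2)
  if (baseline_mean + effect_delta > 1) {
    stop("infeasible configuration: baseline mean + effect_delta exceeds 1", call. = FALSE)
  }
  as.list(environment())[c(
    "n_pairs", "n_regions", "probes_per_region", "baseline_shape1",
    "baseline_shape2", "planted_fraction", "effect_delta", "effect_sd",
    "probe_noise_sd", "smoking_split", "coupling", "tumor_silenced_prob",
    "cell_silenced_prob", "restore_fold_range", "n_cell_lines",
    "n_restore_lines", "seed")]
}

#' Simulate a paired methylation cohort with ground truth
#'
#' Normal-sample probe beta-values are a clipped Beta-distributed probe
#' baseline plus Gaussian probe noise; tumor values add the region's true
#' delta (drawn once per planted region from N(effect_delta, effect_sd^2),
#' zero elsewhere) plus noise, clipped to \[0.001, 0.999\]. Deterministic
#' given the config seed.
#'
#' @param config Output of [sim_config()].
#' @return List: \code{beta} (probe x sample matrix), \code{manifest},
#'   \code{regions}, \code{design}, \code{truth} (planted region/gene ids,
#'   per-region true delta, per-gene silencing status).
#' @export
simulate_methylation_cohort <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, 1))
  n_reg <- config$n_regions

  n_probes_per <- sample(seq(config$probes_per_region[1],
                             config$probes_per_region[2]),
                         n_reg, replace = TRUE)
  region_start0 <- (seq_len(n_reg) - 1L) * 10000L
  region_len <- 2000L
  regions <- data.frame(
    region_id = sprintf("CGI%05d", seq_len(n_reg)),
    chrom = "chr1",
    start = region_start0,
    end = region_start0 + region_len,
    gene = sprintf("GENE%04d", seq_len(n_reg)),
    gene_context = sample(GENE_CONTEXTS, n_reg, replace = TRUE),
    stringsAsFactors = FALSE
  )

  probe_region <- rep(seq_len(n_reg), n_probes_per)
  pos <- unlist(lapply(seq_len(n_reg), function(i) {
    sort(sample(seq_len(region_len), n_probes_per[i])) + region_start0[i]
  }))
  manifest <- data.frame(
    probe_id = sprintf("cg%08d", seq_along(pos)),
    chrom = "chr1",
    pos = as.integer(pos),
    stringsAsFactors = FALSE
  )

  n_planted <- round(config$planted_fraction * n_reg)
  planted_idx <- if (n_planted > 0) sort(sample(n_reg, n_planted)) else integer(0)
  true_delta <- numeric(n_reg)
  true_delta[planted_idx] <- rnorm(n_planted, config$effect_delta, config$effect_sd)

  n_probes <- nrow(manifest)
  n_pairs <- config$n_pairs
  baseline <- clip01(rbeta(n_probes, config$baseline_shape1, config$baseline_shape2))
  probe_delta <- true_delta[probe_region]
  normal <- clip01(baseline + matrix(rnorm(n_probes * n_pairs, 0, config$probe_noise_sd),
                                     n_probes, n_pairs))
  tumor <- clip01(baseline + probe_delta +
                    matrix(rnorm(n_probes * n_pairs, 0, config$probe_noise_sd),
                           n_probes, n_pairs))
  beta <- cbind(tumor, normal)
  rownames(beta) <- manifest$probe_id
  colnames(beta) <- c(sprintf("T%02d", seq_len(n_pairs)),
                      sprintf("N%02d", seq_len(n_pairs)))

  design <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n_pairs)),
    tumor_sample = sprintf("T%02d", seq_len(n_pairs)),
    normal_sample = sprintf("N%02d", seq_len(n_pairs)),
    smoking_status = rep(c("S", "NS"), config$smoking_split),
    stringsAsFactors = FALSE
  )

  truth <- list(
    planted_region_ids = regions$region_id[planted_idx],
    planted_gene_ids = regions$gene[planted_idx],
    true_delta = setNames(true_delta, regions$region_id),
    silenced = setNames(seq_len(n_reg) %in% planted_idx & config$coupling,
                        regions$gene),
    gene_of_region = setNames(regions$gene, regions$region_id)
  )
  list(beta = beta, manifest = manifest, regions = regions,
       design = design, truth = truth)
}

#' Simulate gene-level expression panels
#'
#' For genes of planted (silenced) regions: tumor/normal expression ratios
#' fall below 0.5 with probability \code{tumor_silenced_prob} per pair,
#' cell-line expression falls below 20% of normal lung with probability
#' \code{cell_silenced_prob} per line, and treated/vehicle fold changes are
#' drawn from \code{restore_fold_range} (all above 4x). Non-silenced genes
#' follow a null model with ratios centered at 1. With \code{coupling =
#' FALSE} every gene follows the null model, making expression independent
#' of the methylation truth.
#'
#' @param truth Truth labels from [simulate_methylation_cohort()].
#' @param config The same [sim_config()].
#' @param genes Genes to simulate (default: all genes in \code{truth}).
#' @return Expression table data.frame.
#' @export
simulate_expression_panels <- function(truth, config = sim_config(), genes = NULL) {
  set.seed(derive_seed(config$seed, 2))
  if (is.null(genes)) genes <- names(truth$silenced)
  silenced <- truth$silenced[genes] & config$coupling
  silenced[is.na(silenced)] <- FALSE
  n_g <- length(genes)
  n_pairs <- config$n_pairs
  n_cl <- config$n_cell_lines
  n_rl <- config$n_restore_lines
  patients <- sprintf("P%02d", seq_len(n_pairs))
  lines <- sprintf("CL%02d", seq_len(n_cl))

  ## paired tumor/normal panel
  normal_val <- matrix(exp(rnorm(n_g * n_pairs, 0, 0.3)), n_g, n_pairs)
  low <- matrix(runif(n_g * n_pairs, 0.05, 0.45), n_g, n_pairs)
  high <- matrix(runif(n_g * n_pairs, 0.55, 1.3), n_g, n_pairs)
  is_low <- matrix(rbinom(n_g * n_pairs, 1, config$tumor_silenced_prob) == 1,
                   n_g, n_pairs)
  null_ratio <- matrix(exp(rnorm(n_g * n_pairs, 0, 0.35)), n_g, n_pairs)
  sil_pair <- matrix(silenced, n_g, n_pairs)
  ratio <- ifelse(sil_pair, ifelse(is_low, low, high), null_ratio)
  tumor_val <- normal_val * ratio

  ## cell-line panel, relative to a normal-lung reference of 1
  cl_low <- matrix(runif(n_g * n_cl, 0.01, 0.19), n_g, n_cl)
  cl_high <- matrix(runif(n_g * n_cl, 0.25, 0.8), n_g, n_cl)
  cl_is_low <- matrix(rbinom(n_g * n_cl, 1, config$cell_silenced_prob) == 1,
                      n_g, n_cl)
  cl_null <- matrix(exp(rnorm(n_g * n_cl, 0, 0.4)), n_g, n_cl)
  sil_cl <- matrix(silenced, n_g, n_cl)
  cl_val <- ifelse(sil_cl, ifelse(cl_is_low, cl_low, cl_high), cl_null)

  ## treated/vehicle arms on the first n_restore_lines lines
  veh_sil <- matrix(runif(n_g * n_rl, 0.005, 0.03), n_g, n_rl)
  veh_null <- matrix(exp(rnorm(n_g * n_rl, 0, 0.3)), n_g, n_rl)
  sil_rl <- matrix(silenced, n_g, n_rl)
  veh <- ifelse(sil_rl, veh_sil, veh_null)
  fold_sil <- matrix(runif(n_g * n_rl, config$restore_fold_range[1],
                           config$restore_fold_range[2]), n_g, n_rl)
  fold_null <- matrix(exp(rnorm(n_g * n_rl, 0, 0.5)), n_g, n_rl)
  trt <- veh * ifelse(sil_rl, fold_sil, fold_null)

  rbind(
    data.frame(gene = rep(genes, n_pairs),
               sample = rep(patients, each = n_g),
               context = "tumor", rel_expr = as.vector(tumor_val),
               stringsAsFactors = FALSE),
    data.frame(gene = rep(genes, n_pairs),
               sample = rep(patients, each = n_g),
               context = "normal_pair", rel_expr = as.vector(normal_val),
               stringsAsFactors = FALSE),
    data.frame(gene = rep(genes, n_cl),
               sample = rep(lines, each = n_g),
               context = "cell_line", rel_expr = as.vector(cl_val),
               stringsAsFactors = FALSE),
    data.frame(gene = genes, sample = "NormalLung",
               context = "normal_reference", rel_expr = 1,
               stringsAsFactors = FALSE),
    data.frame(gene = rep(genes, n_rl),
               sample = rep(lines[seq_len(n_rl)], each = n_g),
               context = "vehicle", rel_expr = as.vector(veh),
               stringsAsFactors = FALSE),
    data.frame(gene = rep(genes, n_rl),
               sample = rep(lines[seq_len(n_rl)], each = n_g),
               context = "treated", rel_expr = as.vector(trt),
               stringsAsFactors = FALSE)
  )
}

#' Simulate a site-level pyrosequencing-style panel
#'
#' Percent methylation is 100 x the probe-level beta model at single CpG
#' sites: a hypermethylated site (tumor shift \code{effect_delta}) linked to
#' the first planted gene, and a stable null site. Smoking status has no
#' effect by construction (the expected null for validation analyses). When
#' \code{config$coupling} is TRUE a coupled expression table is also drawn,
#' with expression decaying in percent methylation.
#'
#' @param truth Truth labels from [simulate_methylation_cohort()].
#' @param config The same [sim_config()].
#' @param n_pairs Validation panel size (default 46 pairs).
#' @param smoking_split Integer c(S, NS) split (default 25/21).
#' @return List: \code{sites}, \code{design}, \code{gene_site_map}, and (if
#'   coupling) \code{expression}.
#' @export
simulate_site_panel <- function(truth, config = sim_config(), n_pairs = 46,
                                smoking_split = c(25, 21)) {
  stopifnot(sum(smoking_split) == n_pairs)
  set.seed(derive_seed(config$seed, 3))
  hyper_gene <- if (length(truth$planted_gene_ids) > 0) {
    truth$planted_gene_ids[1]
  } else {
    names(truth$silenced)[1]
  }
  null_gene <- setdiff(names(truth$silenced), truth$planted_gene_ids)[1]
  map <- data.frame(gene = c(hyper_gene, null_gene),
                    site_id = c("site_hyper_01", "site_null_01"),
                    stringsAsFactors = FALSE)

  design <- data.frame(
    patient_id = sprintf("V%02d", seq_len(n_pairs)),
    tumor_sample = sprintf("VT%02d", seq_len(n_pairs)),
    normal_sample = sprintf("VN%02d", seq_len(n_pairs)),
    smoking_status = rep(c("S", "NS"), smoking_split),
    stringsAsFactors = FALSE
  )

  draw_site <- function(shift) {
    base <- clip01(rbeta(n_pairs, config$baseline_shape1, config$baseline_shape2))
    normal <- clip01(base + rnorm(n_pairs, 0, config$probe_noise_sd))
    tumor <- clip01(base + shift + rnorm(n_pairs, 0, config$probe_noise_sd))
    list(normal = 100 * normal, tumor = 100 * tumor)
  }
  hyper <- draw_site(config$effect_delta)
  null <- draw_site(0)
  sites <- rbind(
    data.frame(site_id = "site_hyper_01",
               sample = c(design$tumor_sample, design$normal_sample),
               percent_meth = c(hyper$tumor, hyper$normal),
               stringsAsFactors = FALSE),
    data.frame(site_id = "site_null_01",
               sample = c(design$tumor_sample, design$normal_sample),
               percent_meth = c(null$tumor, null$normal),
               stringsAsFactors = FALSE)
  )

  out <- list(sites = sites, design = design, gene_site_map = map)
  if (isTRUE(config$coupling)) {
    pct <- c(hyper$tumor, hyper$normal)
    expr <- data.frame(
      gene = hyper_gene,
      sample = c(design$tumor_sample, design$normal_sample),
      context = rep(c("tumor", "normal_pair"), each = n_pairs),
      rel_expr = exp(-3 * pct / 100 + rnorm(2 * n_pairs, 0, 0.2)),
      stringsAsFactors = FALSE
    )
    ## site table uses tumor/normal sample ids directly, matching expr samples
    out$expression <- expr
  }
  out
}

#' Write a complete synthetic cohort directory
#'
#' Emits beta.tsv, manifest.tsv, regions.bed, samples.tsv, expression.tsv,
#' sites.tsv, site_samples.tsv and truth.json through the package writers,
#' guaranteeing format fidelity with the readers.
#'
#' @param dir Output directory (created if needed).
#' @param config Output of [sim_config()].
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_methylation_cohort(config)
  expr <- simulate_expression_panels(cohort$truth, config)
  panel <- simulate_site_panel(cohort$truth, config)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_probe_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_regions_bed(cohort$regions, file.path(dir, "regions.bed"))
  write_sample_sheet(cohort$design, file.path(dir, "samples.tsv"))
  write_expression(expr, file.path(dir, "expression.tsv"))
  write_site_methylation(panel$sites, file.path(dir, "sites.tsv"))
  write_sample_sheet(panel$design, file.path(dir, "site_samples.tsv"))
  jsonlite::write_json(
    list(planted_region_ids = cohort$truth$planted_region_ids,
         planted_gene_ids = cohort$truth$planted_gene_ids,
         true_delta = as.list(cohort$truth$true_delta),
         silenced = as.list(cohort$truth$silenced)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
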