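## End-to-end orchestration: config handling, the screen -> funnel ->
## validation run, and report assembly. Configs are plain named lists, or
## YAML files with the same structure; every output embeds the thresholds
## and seed that produced it.

## Small polynomial rolling hash over the deparsed config for provenance
## stamping (not cryptographic; just a stable fingerprint).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Load and validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with optional blocks:
#' \code{simulate} (arguments to [sim_config()]), \code{inputs} (paths:
#' \code{beta}, \code{manifest}, \code{regions}, \code{samples},
#' \code{expression}, \code{sites}, \code{site_samples}, \code{evidence}),
#' \code{screen} (arguments to [screen_params()]), \code{funnel} (arguments
#' to [funnel_thresholds()]), and \code{seed}. Exactly one of
#' \code{simulate} / \code{inputs$beta} must provide methylation data unless
#' only the funnel is run from an evidence file. Referenced paths must exist.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config with parameter objects materialized.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    config$simulate <- do.call(sim_config, sim_args)
  }
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  config$screen <- do.call(screen_params, as.list(config$screen))
  config$funnel <- do.call(funnel_thresholds, as.list(config$funnel))
  config
}

load_methylation_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    simulate_methylation_cohort(config$simulate)
  } else {
    inp <- config$inputs
    for (key in c("beta", "manifest", "regions", "samples")) {
      if (is.null(inp[[key]])) {
        stop(sprintf("config must provide inputs$%s (or a simulate block)", key),
             call. = FALSE)
      }
    }
    list(beta = read_beta_matrix(inp$beta),
         manifest = read_probe_manifest(inp$manifest),
         regions = read_regions_bed(inp$regions),
         design = read_sample_sheet(inp$samples),
         truth = NULL)
  }
}

#' Run the differential methylation screen stage
#'
#' Loads (or simulates) methylation inputs, runs [screen_regions()], and
#' writes \code{screen.tsv} (all tested regions, annotated, with selection
#' flag and rank) and \code{volcano.tsv} (delta-beta vs -log10 adjusted p)
#' under \code{out_dir}.
#'
#' @param config Pipeline config (list or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return The [screen_regions()] result, invisibly augmented with paths.
#' @export
run_screen_stage <- function(config, out_dir = NULL) {
  config <- load_pipeline_config(config)
  inputs <- load_methylation_inputs(config)
  screen <- screen_regions(inputs$beta, inputs$manifest, inputs$regions,
                           inputs$design, config$screen)
  screen$truth <- inputs$truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    recs <- screen$records
    recs$region_label <- region_label(recs)
    write.table(recs, file.path(out_dir, "screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(volcano_data(screen$records), file.path(out_dir, "volcano.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message(sprintf("screen: %d region(s) tested, %d selected (FDR < %g, |delta beta| > %g)",
                  nrow(screen$records), nrow(screen$selected),
                  config$screen$fdr_cut, config$screen$delta_cut))
  invisible(screen)
}

#' Run the full pipeline: screen, funnel, validation, report
#'
#' Stages run in order; any stage error aborts with the stage name. Candidate
#' genes for the funnel are the gene annotations of the top-k screen regions
#' (every selected region's gene when \code{candidates = "selected"}). With
#' an \code{inputs$evidence} file and no methylation inputs, only the funnel
#' is evaluated ("funnel-only mode"). The JSON report embeds a provenance
#' block (config hash, seed, thresholds).
#'
#' @param config Pipeline config (list or YAML path).
#' @param out_dir Output directory; stage TSVs plus \code{report.json}.
#' @param candidates \code{"top"} (default) or \code{"selected"}.
#' @return List with stage results and the report, invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cgiscreen_run_"),
                         candidates = c("top", "selected")) {
  candidates <- match.arg(candidates)
  config <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(provenance = list(
    config_hash = config_hash(config),
    seed = config$seed,
    screen_params = config$screen,
    funnel_thresholds = config$funnel
  ))

  funnel_only <- is.null(config$simulate) && is.null(config$inputs$beta) &&
    !is.null(config$inputs$evidence)

  screen <- NULL
  if (!funnel_only) {
    screen <- tryCatch(run_screen_stage(config, out_dir),
                       error = function(e) stop("screen stage: ", conditionMessage(e), call. = FALSE))
  }

  funnel <- tryCatch({
    if (funnel_only) {
      evidence <- read_evidence(config$inputs$evidence)
      evaluate_funnel(evidence, config$funnel)
    } else {
      pool <- if (candidates == "top") screen$top else screen$selected
      genes <- unique(pool$gene[!is.na(pool$gene)])
      expr <- if (!is.null(config$inputs$expression)) {
        read_expression(config$inputs$expression)
      } else if (!is.null(config$simulate)) {
        simulate_expression_panels(screen$truth, config$simulate)
      } else {
        NULL
      }
      if (is.null(expr)) NULL else run_funnel(genes, expr, config$funnel)
    }
  }, error = function(e) stop("funnel stage: ", conditionMessage(e), call. = FALSE))
  if (!is.null(funnel)) {
    write_funnel_report(funnel, file.path(out_dir, "funnel.tsv"))
  }

  validation <- tryCatch({
    if (!is.null(config$inputs$sites) && !is.null(config$inputs$site_samples)) {
      sites <- read_site_methylation(config$inputs$sites)
      site_design <- read_sample_sheet(config$inputs$site_samples)
      cmp <- paired_site_comparison(sites, site_design)
      write.table(cmp, file.path(out_dir, "site_comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cmp
    } else {
      NULL
    }
  }, error = function(e) stop("validation stage: ", conditionMessage(e), call. = FALSE))

  report$n_regions_tested <- if (is.null(screen)) NA_integer_ else nrow(screen$records)
  report$n_regions_selected <- if (is.null(screen)) NA_integer_ else nrow(screen$selected)
  report$candidates <- if (is.null(funnel)) character(0) else funnel$gene[funnel$passes_all]
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(screen = screen, funnel = funnel, validation = validation,
                 report = report, out_dir = out_dir))
}
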