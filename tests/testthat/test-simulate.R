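test_that("configuration is validated, including clipping feasibility", {
  expect_error(sim_config(baseline_shape1 = 10, baseline_shape2 = 2,
                          effect_delta = 0.3), "infeasible")
  expect_error(sim_config(smoking_split = c(5, 5)))
  expect_silent(sim_config())
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_regions = 40, seed = 101)
  a <- simulate_methylation_cohort(cfg)
  b <- simulate_methylation_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_expression_panels(a$truth, cfg),
                   simulate_expression_panels(b$truth, cfg))
  expect_identical(simulate_site_panel(a$truth, cfg)$sites,
                   simulate_site_panel(b$truth, cfg)$sites)

  c2 <- simulate_methylation_cohort(sim_config(n_regions = 40, seed = 102))
  expect_false(identical(a$beta, c2$beta))
})

test_that("generated values respect their ranges and cohort structure", {
  cfg <- sim_config(n_regions = 60, seed = 103)
  co <- simulate_methylation_cohort(cfg)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_identical(ncol(co$beta), 24L)
  expect_identical(nrow(co$design), 12L)
  expect_identical(as.vector(table(co$design$smoking_status)[c("S", "NS")]),
                   c(6L, 6L))
  expect_identical(length(co$truth$planted_region_ids),
                   as.integer(round(0.05 * 60)))
  # planted truth effects center on the configured delta
  expect_equal(mean(co$truth$true_delta[co$truth$planted_region_ids]), 0.3,
               tolerance = 0.1)
  expr <- simulate_expression_panels(co$truth, cfg)
  expect_true(all(expr$rel_expr >= 0))
  panel <- simulate_site_panel(co$truth, cfg)
  expect_true(all(panel$sites$percent_meth >= 0 & panel$sites$percent_meth <= 100))
  expect_identical(as.vector(table(panel$design$smoking_status)[c("S", "NS")]),
                   c(25L, 21L))
})

test_that("null cohorts carry no region-level signal", {
  cfg <- sim_config(n_regions = 200, planted_fraction = 0, seed = 104)
  co <- simulate_methylation_cohort(cfg)
  mapping <- suppressMessages(assign_probes(co$manifest, co$regions))
  summ <- summarize_regions(co$beta, mapping)
  diffs <- paired_differences(summ, co$design)
  expect_lt(mean(abs(rowMeans(diffs))), 0.02)
})

test_that("planted regions realize their configured effect within 2 SE", {
  cfg <- sim_config(n_regions = 300, seed = 105)
  co <- simulate_methylation_cohort(cfg)
  mapping <- suppressMessages(assign_probes(co$manifest, co$regions))
  summ <- summarize_regions(co$beta, mapping)
  diffs <- paired_differences(summ, co$design)
  realized <- rowMeans(diffs)[co$truth$planted_region_ids]
  n <- length(realized)
  se <- cfg$effect_sd / sqrt(n)
  expect_lt(abs(mean(realized) - cfg$effect_delta), 2 * se + 0.01)
})

test_that("planted genes pass the funnel at the rate the draw probabilities imply", {
  # per-criterion binomial bounds at the defaults (12 pairs -> need 7;
  # 14 lines at p=0.75 -> need 8; 3/3 restorations guaranteed by the fold
  # range) put the planted pass probability near 0.96 and the null pass
  # probability below 1e-4
  passes <- vapply(1:40, function(s) {
    cfg <- sim_config(n_regions = 2, n_pairs = 12, planted_fraction = 0.5,
                      seed = 200 + s)
    truth <- list(silenced = c(GP = TRUE, GN = FALSE))
    expr <- simulate_expression_panels(truth, cfg, genes = c("GP", "GN"))
    res <- run_funnel(c("GP", "GN"), expr)
    c(res$passes_all[res$gene == "GP"], res$passes_all[res$gene == "GN"])
  }, logical(2))
  expect_gte(mean(passes[1, ]), 0.85)  # planted: expected ~0.96
  expect_identical(sum(passes[2, ]), 0L)  # null gene never passes

  # coupling off: planted and non-planted behave identically (both null)
  cfg_off <- sim_config(n_regions = 2, coupling = FALSE, seed = 300)
  expr_off <- simulate_expression_panels(
    list(silenced = c(GP = TRUE, GN = FALSE)), cfg_off, genes = c("GP", "GN"))
  res_off <- run_funnel(c("GP", "GN"), expr_off)
  expect_identical(sum(res_off$passes_all), 0L)
})

test_that("smoking status has no effect on the site panel by construction", {
  stats <- vapply(1:30, function(s) {
    cfg <- sim_config(n_regions = 10, seed = 400 + s)
    co <- simulate_methylation_cohort(cfg)
    panel <- simulate_site_panel(co$truth, cfg)
    vals <- with(subset(panel$sites, site_id == "site_hyper_01"),
                 setNames(percent_meth, sample))
    smoking_stratified_comparison(vals, panel$design, "normal")$test$statistic
  }, numeric(1))
  expect_lt(abs(mean(stats)), 0.5)
})

test_that("a cohort directory round-trips through the package writers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_regions = 20, seed = 500)
  write_cohort(dir, cfg)
  expect_true(all(file.exists(file.path(dir,
    c("beta.tsv", "manifest.tsv", "regions.bed", "samples.tsv",
      "expression.tsv", "sites.tsv", "site_samples.tsv", "truth.json")))))
  co <- simulate_methylation_cohort(cfg)
  expect_equal(read_beta_matrix(file.path(dir, "beta.tsv")), co$beta)
  expect_equal(read_regions_bed(file.path(dir, "regions.bed"))$region_id,
               co$regions$region_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(unlist(truth$planted_region_ids),
                   co$truth$planted_region_ids)
})
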