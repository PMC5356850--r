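make_site_table <- function(design, tumor, normal, site_id = "s1") {
  data.frame(site_id = site_id,
             sample = c(design$tumor_sample, design$normal_sample),
             percent_meth = c(tumor, normal),
             stringsAsFactors = FALSE)
}

test_that("paired site comparison detects shifts and excludes flat sites", {
  set.seed(61)
  design <- tiny_design(46)
  normal <- runif(46, 10, 30)
  shifted <- make_site_table(design, normal + rnorm(46, 30, 10), normal, "hit")
  flat <- make_site_table(design, normal, normal, "flat")
  expect_warning(res <- paired_site_comparison(rbind(shifted, flat), design),
                 "excluded 1")
  expect_identical(res$site_id, "hit")
  expect_equal(res$mean_paired_difference_pct,
               mean(shifted$percent_meth[1:46] - normal))
  expect_lt(res$adjusted_p, 0.01)

  # closed-form cross-check of the paired t behind the comparison
  d <- shifted$percent_meth[1:46] - normal
  expect_equal(res$statistic, paired_t_oracle(d)$statistic, tolerance = 1e-10)

  # antisymmetry under label swap
  swapped <- design
  swapped$tumor_sample <- design$normal_sample
  swapped$normal_sample <- design$tumor_sample
  res_sw <- suppressWarnings(paired_site_comparison(rbind(shifted, flat), swapped))
  expect_equal(res_sw$mean_paired_difference_pct, -res$mean_paired_difference_pct)

  # rank-test flag switches the statistic
  res_rank <- suppressWarnings(
    paired_site_comparison(rbind(shifted, flat), design, use_rank_test = TRUE))
  expect_lt(res_rank$adjusted_p, 0.01)
})

test_that("methylation-expression correlation flags and measures coupling", {
  design <- tiny_design(10)
  pct <- seq(5, 95, length.out = 20)
  sites <- data.frame(site_id = "s1",
                      sample = c(design$tumor_sample, design$normal_sample),
                      percent_meth = pct)
  expr <- data.frame(gene = "G1",
                     sample = c(design$tumor_sample, design$normal_sample),
                     context = rep(c("tumor", "normal_pair"), each = 10),
                     rel_expr = 100 - pct)
  map <- data.frame(gene = "G1", site_id = "s1")
  res <- methylation_expression_correlation(sites, expr, map)
  expect_equal(res$r, -1)
  expect_true(res$evaluable)
  expect_identical(res$n, 20L)

  # constant methylation is not evaluable, not an error
  sites$percent_meth <- 50
  res2 <- methylation_expression_correlation(sites, expr, map)
  expect_false(res2$evaluable)
  expect_true(is.na(res2$r))

  # synthetic coupled panel shows strong inverse correlation
  cfg <- sim_config(n_regions = 40, seed = 17)
  co <- simulate_methylation_cohort(cfg)
  panel <- simulate_site_panel(co$truth, cfg, n_pairs = 17, smoking_split = c(9, 8))
  cres <- methylation_expression_correlation(
    panel$sites, panel$expression, panel$gene_site_map[1, , drop = FALSE])
  expect_identical(cres$n, 34L)
  expect_lt(cres$r, -0.5)
  expect_lt(cres$p, 0.01)
})

test_that("coupled correlation is negative across repeated seeds", {
  rs <- vapply(1:25, function(s) {
    cfg <- sim_config(n_regions = 20, seed = s)
    co <- simulate_methylation_cohort(cfg)
    panel <- simulate_site_panel(co$truth, cfg, n_pairs = 17,
                                 smoking_split = c(9, 8))
    methylation_expression_correlation(
      panel$sites, panel$expression, panel$gene_site_map[1, , drop = FALSE])$r
  }, numeric(1))
  expect_lt(mean(rs), 0)
})

test_that("smoking stratification compares S vs NS within one compartment", {
  design <- tiny_design(12)
  design$smoking_status <- rep(c("S", "NS"), each = 6)
  vals <- setNames(rep(10, 24), c(design$tumor_sample, design$normal_sample))
  res <- smoking_stratified_comparison(vals, design, "normal")
  expect_equal(res$test$statistic, 0)
  expect_identical(res$groups$n, c(6L, 6L))

  set.seed(71)
  shifted <- vals
  shifted[design$normal_sample] <- rnorm(12, 10, 5) +
    ifelse(design$smoking_status == "S", 30, 0)
  res2 <- smoking_stratified_comparison(shifted, design, "normal")
  expect_lt(res2$test$p_two_sided, 0.01)

  # permuting sample order within groups changes nothing
  perm <- sample(seq_len(nrow(design)))
  res3 <- smoking_stratified_comparison(shifted, design[perm, ], "normal")
  expect_equal(res3$test$p_two_sided, res2$test$p_two_sided)

  # rank-test flag
  res4 <- smoking_stratified_comparison(shifted, design, "normal",
                                        use_rank_test = TRUE)
  expect_lt(res4$test$p_two_sided, 0.05)

  empty <- design
  empty$smoking_status <- rep("S", 12)
  expect_error(smoking_stratified_comparison(vals, empty, "normal"), "stratum")
})

test_that("single-probe regions agree between beta and percent pipelines", {
  cfg <- sim_config(n_regions = 25, probes_per_region = c(1, 1), seed = 23)
  co <- simulate_methylation_cohort(cfg)
  mapping <- suppressMessages(assign_probes(co$manifest, co$regions))
  summ <- summarize_regions(co$beta, mapping)
  diffs <- paired_differences(summ, co$design)

  # run the site-level machinery on the same values expressed as percent
  one_region <- names(mapping)[1]
  probe <- mapping[[one_region]]
  sites <- data.frame(site_id = one_region,
                      sample = colnames(co$beta),
                      percent_meth = 100 * co$beta[probe, ])
  res <- paired_site_comparison(sites, co$design, min_pairs = 2)
  expect_equal(res$mean_paired_difference_pct,
               100 * mean(diffs[one_region, ]), tolerance = 1e-10)
})
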