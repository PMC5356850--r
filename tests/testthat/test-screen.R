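make_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, path)
  read_regions_bed(path)
}

test_that("probes are assigned by coordinate containment, boundaries included", {
  regions <- make_bed("chr1\t248020329\t248021252\tR1")
  manifest <- data.frame(
    probe_id = c("cgA", "cgB", "cgC", "cgD", "cgE"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    pos = c(248020330L, 248021252L, 248021253L, 248020500L, 248020329L))
  mapping <- suppressMessages(assign_probes(manifest, regions))
  # display start and end are contained; past-the-end, wrong-chrom and the
  # position before the 1-based start are not
  expect_identical(mapping$R1, c("cgA", "cgB"))
})

test_that("regions without probes are dropped with a count", {
  regions <- make_bed(c("chr1\t0\t100\tR1", "chr1\t1000\t1100\tR2"))
  manifest <- data.frame(probe_id = "cgA", chrom = "chr1", pos = 50L)
  expect_message(mapping <- assign_probes(manifest, regions), "dropped 1")
  expect_identical(names(mapping), "R1")
})

test_that("region summaries are per-sample medians of available probes", {
  beta <- matrix(c(0.1, 0.2, 0.9,
                   0.1, NA, 0.3), ncol = 2,
                 dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  mapping <- list(R1 = c("p1", "p2", "p3"))
  s <- summarize_regions(beta, mapping, min_probes = 2)
  expect_equal(s["R1", "S1"], 0.2)   # median of 0.1, 0.2, 0.9
  expect_equal(s["R1", "S2"], 0.2)   # median of the two available values
  s1 <- summarize_regions(beta, mapping, min_probes = 3)
  expect_true(is.na(s1["R1", "S2"])) # too few non-missing probes

  single <- summarize_regions(beta, list(R1 = "p3"), min_probes = 1)
  expect_equal(unname(single["R1", ]), c(0.9, 0.3))
})

test_that("paired differences subtract normal from tumor and are antisymmetric", {
  s <- matrix(c(0.5, 0.2, 0.4, 0.35), nrow = 1,
              dimnames = list("R1", c("T01", "N01", "T02", "N02")))
  design <- tiny_design(2)
  d <- paired_differences(s, design)
  expect_equal(unname(d["R1", ]), c(0.3, 0.05))

  swapped <- design
  swapped$tumor_sample <- design$normal_sample
  swapped$normal_sample <- design$tumor_sample
  expect_equal(unname(paired_differences(s, swapped)), -unname(d))
})

test_that("differential_test scores regions and excludes degenerate ones", {
  set.seed(5)
  d_planted <- rnorm(12, 0.3, 0.05)
  diff <- rbind(planted = d_planted,
                null = rnorm(12, 0, 0.05),
                flat = rep(0, 12))
  expect_warning(rec <- differential_test(diff, min_pairs = 3), "excluded 1")
  expect_identical(sort(rec$region_id), c("null", "planted"))
  planted <- rec[rec$region_id == "planted", ]
  ora <- paired_t_oracle(d_planted)
  expect_equal(planted$t_stat, ora$statistic, tolerance = 1e-10)
  expect_equal(planted$delta_beta, mean(d_planted))
  expect_lt(planted$raw_p, 1e-4)
  expect_true(all(rec$adjusted_p >= rec$raw_p))

  # permuting pair order changes nothing
  rec2 <- suppressWarnings(differential_test(diff[, sample(12)], min_pairs = 3))
  expect_equal(rec2[order(rec2$region_id), -1],
               rec[order(rec$region_id), -1], tolerance = 1e-12)
})

test_that("selection applies strict thresholds and deterministic ranking", {
  rec <- data.frame(
    region_id = c("a", "b", "c", "d", "e"),
    n_pairs = 12L,
    delta_beta = c(0.26, 0.24, 0.40, 0.30, 0.26),
    t_stat = 5, raw_p = 0.001,
    adjusted_p = c(0.04, 0.04, 0.06, 0.04, 0.04))
  sel <- select_and_rank(rec, screen_params())
  expect_identical(sel$region_id, c("d", "a", "e"))  # q then |delta| then id
  expect_false("b" %in% sel$region_id)  # delta 0.24 < 0.25: dropped
  expect_false("c" %in% sel$region_id)  # q 0.06 >= 0.05: dropped
  expect_identical(sel$rank, 1:3)

  # boundary values fail the strict inequalities
  border <- data.frame(region_id = c("x", "y"), n_pairs = 12L,
                       delta_beta = c(0.25, 0.30), t_stat = 5, raw_p = 0.001,
                       adjusted_p = c(0.01, 0.05))
  expect_identical(nrow(select_and_rank(border, screen_params())), 0L)
})

test_that("hypo direction on a label-swapped design mirrors the hyper screen", {
  cfg <- sim_config(n_regions = 60, seed = 3)
  co <- simulate_methylation_cohort(cfg)
  hyper <- suppressWarnings(suppressMessages(
    screen_regions(co$beta, co$manifest, co$regions, co$design,
                   screen_params(direction = "hyper"))))
  swapped <- co$design
  swapped$tumor_sample <- co$design$normal_sample
  swapped$normal_sample <- co$design$tumor_sample
  hypo <- suppressWarnings(suppressMessages(
    screen_regions(co$beta, co$manifest, co$regions, swapped,
                   screen_params(direction = "hypo"))))
  expect_identical(hyper$selected$region_id, hypo$selected$region_id)
  expect_equal(hyper$selected$delta_beta, -hypo$selected$delta_beta)
})

test_that("screen output is annotated and the top view truncates", {
  cfg <- sim_config(n_regions = 80, seed = 9)
  co <- simulate_methylation_cohort(cfg)
  scr <- suppressWarnings(suppressMessages(
    screen_regions(co$beta, co$manifest, co$regions, co$design)))
  expect_true(all(c("gene", "gene_context", "chrom", "n_probes", "selected") %in%
                    names(scr$records)))
  expect_lte(nrow(scr$top), 10L)
  expect_identical(scr$top$region_id, head(scr$selected$region_id, 10))
  vd <- volcano_data(scr$records)
  expect_equal(vd$neg_log10_adj_p, -log10(scr$records$adjusted_p))

  # the probe-difference-first config switch yields comparable calls
  alt <- suppressWarnings(suppressMessages(
    screen_regions(co$beta, co$manifest, co$regions, co$design,
                   screen_params(summary_method = "probe_diff_median"))))
  planted <- intersect(co$truth$planted_region_ids, scr$records$region_id)
  expect_gt(length(intersect(planted, alt$selected$region_id)) /
              max(length(planted), 1), 0.7)
})
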