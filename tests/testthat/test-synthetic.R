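test_that("the normal methylome generator is deterministic and well formed", {
  a <- simulate_normal_methylome(n_cpgs = 600, n_windows = 60, seed = 7)
  b <- simulate_normal_methylome(n_cpgs = 600, n_windows = 60, seed = 7)
  expect_identical(a$profile$sites, b$profile$sites)
  expect_identical(a$epialleles$counts, b$epialleles$counts)
  expect_identical(a$regions, b$regions)

  expect_equal(nrow(a$profile$sites), 600L)
  expect_equal(nrow(a$epialleles$windows), 60L)
  expect_true(all(a$profile$sites$total >= 10))
  # 4-CpG windows span less than 100 bp (one read)
  expect_true(all(a$epialleles$windows$pos4 - a$epialleles$windows$pos1 < 100))

  none <- simulate_normal_methylome(n_cpgs = 300, n_windows = 0, seed = 1)
  expect_equal(nrow(none$epialleles$windows), 0L)
  expect_equal(nrow(none$profile$sites), 300L)

  expect_error(simulate_normal_methylome(n_cpgs = 100, n_windows = 50),
               "too small")
})

test_that("an island-only genome is globally hypomethylated", {
  isl <- simulate_normal_methylome(n_cpgs = 10000, n_windows = 300, seed = 3,
                                   layout = "island")
  expect_lt(mean(isl$profile$sites$beta), 0.3)
  mixed <- simulate_normal_methylome(n_cpgs = 2000, n_windows = 100, seed = 3)
  expect_gt(mean(mixed$profile$sites$beta), 0.3)
})

test_that("stage presets encode the planted trends", {
  stages <- c("AAH", "AIS", "MIA", "ADC")
  ps <- lapply(stages, stage_params)
  totals <- vapply(ps, function(p) p$n_gain_dmrs + p$n_loss_dmrs, numeric(1))
  expect_true(all(diff(totals) > 0))               # strictly increasing
  expect_equal(ps[[1]]$n_loss_dmrs, 0L)            # no losses at AAH
  expect_true(all(diff(vapply(ps, `[[`, numeric(1),
                              "line1_delta")) > 0))
  expect_true(all(diff(vapply(ps, `[[`, numeric(1),
                              "dirichlet_alpha")) < 0))
  expect_error(stage_params("AAH", bogus = 1), "unknown")
})

test_that("lesion simulation honours presets and records ground truth", {
  nm <- simulate_normal_methylome(n_cpgs = 1200, n_windows = 120, seed = 5)
  aah <- simulate_lesion(nm, stage_params("AAH"), n_regions = 2, seed = 9)
  expect_equal(nrow(aah$truth$loss_dmrs), 0L)
  expect_equal(aah$truth$private_direction, "gain")
  expect_equal(length(aah$specimens), 2L)

  adc <- simulate_lesion(nm, stage_params("ADC"), n_regions = 1, seed = 9)
  expect_equal(nrow(adc$truth$gain_dmrs), 26L)
  expect_equal(nrow(adc$truth$loss_dmrs), 24L)
  tru <- planted_dmrs(adc, 1)
  expect_true(all(tru$end <= nm$truth$genome_length))
  expect_true(all(tru$start >= 1))

  # trunk mutations are shared; private mutations are not
  two <- simulate_lesion(nm, stage_params("ADC"), n_regions = 2, seed = 11)
  v1 <- two$specimens[[1]]$mutations$variants
  v2 <- two$specimens[[2]]$mutations$variants
  expect_true(all(two$truth$trunk_mutations %in% intersect(v1, v2)))
  expect_equal(length(intersect(two$truth$private_mutations[[1]], v2)), 0L)

  expect_error(simulate_lesion(nm, stage_params("ADC", n_gain_dmrs = 10000)),
               "gain DMRs")
})

test_that("lower Dirichlet concentration produces more epiallele diversity", {
  nm <- simulate_normal_methylome(n_cpgs = 1600, n_windows = 200, seed = 5)
  hi <- simulate_lesion(nm, stage_params("ADC", dirichlet_alpha = 100),
                        seed = 21)
  lo <- simulate_lesion(nm, stage_params("ADC", dirichlet_alpha = 0.5),
                        seed = 21)
  epi_hi <- mean(epipolymorphism(hi$specimens[[1]]$epialleles$counts))
  epi_lo <- mean(epipolymorphism(lo$specimens[[1]]$epialleles$counts))
  expect_gt(epi_lo, epi_hi)
})

test_that("full coupling aligns shared methylation events with shared mutations", {
  nm <- simulate_normal_methylome(n_cpgs = 1600, n_windows = 160, seed = 5)
  cors <- vapply(1:20, function(r) {
    les <- simulate_lesion(nm, stage_params("ADC", coupling = 1),
                           n_regions = 4, seed = 600 + r)
    loads <- les$truth$clone_loads
    suppressWarnings(stats::cor(loads$n_private_mut, loads$n_private_meth,
                                method = "spearman"))
  }, numeric(1))
  expect_gt(mean(cors, na.rm = TRUE), 0)
})

test_that("cohort simulation writes a deterministic, reader-consumable bundle", {
  cfg <- default_cohort_config(n_patients = 2, stages = c("AAH", "ADC"),
                               multi_region_patient = 1, n_regions = 2,
                               n_cpgs = 1100, n_windows = 80)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- simulate_cohort(cfg, seed = 2, outdir = d1)
  s2 <- simulate_cohort(cfg, seed = 2, outdir = d2)
  expect_identical(s1$manifest$files, s2$manifest$files)

  cohort <- load_cohort(d1)
  # 2 normals + patient 1 (2 lesions x 2 regions) + patient 2 (2 x 1 region)
  expect_equal(nrow(cohort$samples), 2L + 4L + 2L)
  expect_true(all(c("promoter", "LINE1", "PMD", "TSS") %in%
                    names(cohort$regions)))
  # every tumor coverage file loads into a sorted, deduplicated profile
  for (p in cohort$profiles) {
    expect_false(is.unsorted(p$sites$pos))
    expect_equal(anyDuplicated(paste(p$sites$chrom, p$sites$pos)), 0L)
  }

  dup <- cfg
  dup$patients[[2]]$patient_id <- dup$patients[[1]]$patient_id
  expect_error(simulate_cohort(dup, seed = 2), "conflicting sample ids")
})
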