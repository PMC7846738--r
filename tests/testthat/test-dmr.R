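test_that("triangular smoothing matches hand-evaluated kernel sums", {
  # three CpGs at 0(+1), 50, 100 with h = 100: middle gets w = (0.5, 1, 0.5)
  p <- make_profile(pos = c(1, 51, 101), meth = c(10, 0, 10),
                    total = c(20, 20, 20))
  sm <- smooth_counts(p, kernel_halfwidth = 100)
  expect_equal(sm$meth_sm[2], 0.5 * 10 + 1 * 0 + 0.5 * 10)
  expect_equal(sm$total_sm[2], 0.5 * 20 + 20 + 0.5 * 20)

  # isolated CpG keeps its raw counts
  iso <- make_profile(pos = c(1, 5000), meth = c(4, 7), total = c(10, 14))
  smi <- smooth_counts(iso, kernel_halfwidth = 100)
  expect_equal(smi$meth_sm, c(4, 7))
  expect_equal(smi$total_sm, c(10, 14))

  # h -> 0+ reduces smoothing to the identity
  sm0 <- smooth_counts(p, kernel_halfwidth = 1e-9)
  expect_equal(sm0$meth_sm, p$sites$meth)
  expect_equal(sm0$total_sm, p$sites$total)
})

test_that("the vectorised two-sided Fisher p matches stats::fisher.test", {
  set.seed(21)
  for (i in 1:60) {
    a <- rpois(1, 20); b <- rpois(1, 20)
    c_ <- rpois(1, 20); d <- rpois(1, 20)
    ref <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(methevo:::fisher2_p(a, b, c_, d), ref, tolerance = 1e-9)
  }
})

test_that("a planted gain block is called as exactly one gain DMR", {
  # 11 CpGs spaced 50 bp, normal beta 0.05, tumor 0.90, coverage 40, plus
  # flanking unchanged CpGs far away
  pos <- c(1000, 1000 + 50 * (1:10), 5000, 9000)
  nb <- c(rep(0.05, 11), 0.5, 0.5)
  tb <- c(rep(0.90, 11), 0.5, 0.5)
  tumor <- make_profile(pos, round(40 * tb), rep(40, 13), sample_id = "T")
  normal <- make_profile(pos, round(40 * nb), rep(40, 13), sample_id = "N",
                         role = "normal")
  dm <- call_dmrs(tumor, normal)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$direction, "gain")
  expect_equal(dm$start, 1000)
  expect_equal(dm$end, 1500)
  expect_equal(dm$n_cpgs, 11L)
  expect_lt(dm$p_value, 0.01)

  # oracle: per-CpG Fisher on hand-smoothed counts flags the same CpGs
  st <- smooth_counts(tumor, 100); sn <- smooth_counts(normal, 100)
  pv <- mapply(function(a, b, c_, d)
    stats::fisher.test(matrix(round(c(a, b, c_, d)), 2, byrow = TRUE))$p.value,
    st$meth_sm, st$total_sm - st$meth_sm, sn$meth_sm,
    sn$total_sm - sn$meth_sm)
  manual <- which(pv < 0.01 & abs(st$beta_sm - sn$beta_sm) >= 0.2)
  expect_equal(range(tumor$sites$pos[manual]), c(dm$start, dm$end))
})

test_that("identical profiles and under-sized runs yield no DMRs", {
  p <- make_profile(pos = 100 * (1:20), meth = rep(10, 20),
                    total = rep(40, 20))
  expect_equal(nrow(call_dmrs(p, p)), 0L)

  # 3 differential CpGs fail a min_cpgs = 4 gate
  pos <- c(1000, 1050, 1100)
  tumor <- make_profile(pos, rep(36, 3), rep(40, 3), sample_id = "T")
  normal <- make_profile(pos, rep(2, 3), rep(40, 3), sample_id = "N")
  expect_equal(nrow(call_dmrs(tumor, normal,
                              dmr_params(min_cpgs = 4))), 0L)
  dm3 <- call_dmrs(tumor, normal, dmr_params(min_cpgs = 3))
  expect_equal(nrow(dm3), 1L)
})

test_that("swapping tumor and normal mirrors gain DMRs into loss DMRs", {
  set.seed(22)
  pos <- sort(sample(1:20000, 60))
  nb <- runif(60, 0.4, 0.6)
  tb <- nb
  block <- which(pos >= 5000 & pos <= 8000)
  tb[block] <- pmin(0.95, nb[block] + 0.5)
  tumor <- make_profile(pos, rbinom(60, 50, tb), rep(50, 60), sample_id = "T")
  normal <- make_profile(pos, rbinom(60, 50, nb), rep(50, 60),
                         sample_id = "N")
  fwd <- call_dmrs(tumor, normal)
  rev <- call_dmrs(normal, tumor)
  expect_equal(nrow(fwd), nrow(rev))
  if (nrow(fwd)) {
    expect_equal(fwd$start, rev$start)
    expect_equal(fwd$end, rev$end)
    expect_true(all(fwd$direction == "gain"))
    expect_true(all(rev$direction == "loss"))
  }
})

test_that("CpG classification applies the 20% normal-methylation rule", {
  pos <- c(100L, 200L, 300L, 5000L)
  tumor <- make_profile(pos, c(35, 35, 8, 20), rep(40, 4), sample_id = "T")
  normal <- make_profile(pos, c(6, 8, 36, 20), rep(40, 4), sample_id = "N")
  dmrs <- data.frame(chrom = "chr1", start = c(50L, 250L),
                     end = c(250L, 350L), direction = c("gain", "loss"),
                     stringsAsFactors = FALSE)
  cl <- classify_cpg_sites(tumor, normal, dmrs)
  expect_equal(cl$label, c("hyper", "hyper", "hypo", "none"))
  # inside gain DMR but normal beta above 20% -> none
  normal2 <- make_profile(pos, c(12, 10, 36, 20), rep(40, 4), sample_id = "N")
  cl2 <- classify_cpg_sites(tumor, normal2, dmrs)
  expect_equal(cl2$label[1], "none")  # 12/40 = 0.30 > 0.20
  # labels only appear inside reported DMRs
  expect_true(all(cl$label[cl$pos == 5000] == "none"))
})

test_that("count normalization rescales by the cohort mean of assessed units", {
  expect_equal(normalized_counts(c(50, 30), c(1000, 3000)), c(100, 20))
  expect_equal(normalized_counts(c(5, 7), c(100, 100)), c(5, 7))  # identity
  expect_equal(normalized_counts(0, 100), 0)
  expect_warning(out <- normalized_counts(c(1, 2), c(10, 0)), "zero assessed")
  expect_true(is.na(out[2]))
})

test_that("DMR stratification counts overlapping classes and partitions", {
  dmrs <- data.frame(chrom = "chr1", start = c(100L, 1000L, 5000L),
                     end = c(300L, 1200L, 5100L),
                     direction = c("gain", "loss", "gain"),
                     stringsAsFactors = FALSE)
  sets <- list(promoter = region_set("chr1", 90, 150, name = "promoter"),
               enhancer = region_set("chr1", 250, 1100, name = "enhancer"),
               PMD = region_set("chr1", 1, 2000, name = "PMD"))
  st <- stratify_dmrs(dmrs, sets, partitions = "PMD")
  get <- function(nm, col) st[st$stratum == nm, col]
  expect_equal(get("all", "n_total"), 3L)
  expect_equal(get("promoter", "n_total"), 1L)
  expect_equal(get("enhancer", "n_total"), 2L)  # DMR 1 in both classes
  expect_equal(get("PMD", "n_total"), 2L)
  expect_equal(get("outside_PMD", "n_total"), 1L)
  expect_equal(get("PMD", "n_total") + get("outside_PMD", "n_total"),
               nrow(dmrs))
})

test_that("tile aggregation anchors 5-kb tiles at position 1", {
  p <- make_profile(pos = c(100, 4900, 5001), meth = c(2, 8, 5),
                    total = c(10, 10, 10))
  tl <- aggregate_tiles(p, tile_size = 5000, min_reads = 10)
  expect_equal(nrow(tl), 2L)
  expect_equal(tl$tile_start, c(1L, 5001L))
  expect_equal(tl$mean_beta[1], 0.5)  # mean of 0.2 and 0.8
  expect_equal(tl$n_cpgs, c(2L, 1L))
  empty <- make_profile(pos = 100, meth = 1, total = 5)
  expect_equal(nrow(aggregate_tiles(empty, min_reads = 10)), 0L)
})
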