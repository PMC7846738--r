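test_that("the LINE-1 surrogate averages qualifying member CpGs", {
  l1 <- region_set("chr1", c(100, 1000), c(200, 1100), name = "LINE1")
  p <- make_profile(pos = c(150, 160, 1050, 5000),
                    meth = c(8, 6, 7, 1), total = rep(10, 4))
  expect_equal(line1_methylation(p, l1), mean(c(0.8, 0.6, 0.7)))

  # a member CpG below the read threshold is excluded
  p2 <- make_profile(pos = c(150, 160), meth = c(8, 0), total = c(10, 9))
  expect_equal(line1_methylation(p2, l1), 0.8)

  p3 <- make_profile(pos = c(150, 160), meth = c(10, 10), total = c(10, 10))
  expect_equal(line1_methylation(p3, l1), 1)

  p4 <- make_profile(pos = 5000, meth = 5, total = 10)
  expect_error(line1_methylation(p4, l1), "no CpG")
})

test_that("burden correlations are two-tailed Spearman with guards", {
  r <- burden_correlation(c(0.9, 0.8, 0.7, 0.6), c(1, 2, 3, 4))
  expect_equal(r$coefficient, -1)
  expect_error(burden_correlation(rep(0.5, 4), 1:4), "constant")
  expect_error(burden_correlation(1:2, 1:2), "at least 3")
  # shuffled pairing has near-zero correlation in expectation
  set.seed(41)
  x <- rnorm(200); y <- sample(x)
  expect_lt(abs(burden_correlation(x, y)$coefficient), 0.2)
})

test_that("TSS distances are signed by strand and pick the nearest site", {
  tss <- region_set("chr1", c(10000, 10400), c(10000, 10400),
                    strand = c("+", "+"), name = "TSS")
  win <- data.frame(chrom = "chr1",
                    pos1 = c(9985, 9485, 10085),
                    pos4 = c(10015, 9515, 10115))
  d <- nearest_tss_distance(win, tss)
  expect_equal(d[1], 0)      # midpoint exactly at the TSS
  expect_equal(d[2], -500)   # 500 bp 5' of a + strand TSS
  expect_equal(d[3], 100)    # nearest of the two TSSs chosen (100 vs 300)

  minus <- region_set("chr1", 10000, 10000, strand = "-", name = "TSS")
  expect_equal(nearest_tss_distance(win[2, ], minus), 500)  # downstream on -
  unstranded <- region_set("chr1", 10000, 10000, name = "TSS")
  expect_equal(nearest_tss_distance(win[2, ], unstranded), 500)
  expect_error(nearest_tss_distance(win, region_set(character(0), integer(0),
                                                    integer(0), name = "TSS")),
               "empty")
})

test_that("enrichment p-values equal the exhaustive hypergeometric tail", {
  # query 8/10 hits vs remaining background 12/90 hits
  bg <- data.frame(chrom = "chr1", start = 1000 * (1:100),
                   end = 1000 * (1:100) + 10)
  target_rows <- c(1:8, 11:22)           # 20 background regions are hits
  targets <- list(mark = region_set("chr1", 1000 * target_rows,
                                    1000 * target_rows + 5, name = "mark"))
  query <- bg[1:10, ]                     # 8 of 10 query regions are hits
  res <- regionset_enrichment(query, bg, targets)
  expect_equal(res$query_hits, 8L)
  expect_equal(res$bg_hits, 12L)
  # brute-force enumeration of the upper tail
  brute <- sum(vapply(8:10, function(x)
    stats::dhyper(x, 20, 80, 10), numeric(1)))
  expect_equal(res$p_value, brute, tolerance = 1e-12)
  expect_equal(res$q_value, res$p_value)  # single target: BY with m = 1

  # query proportions equal to background -> p >= 0.5
  query2 <- bg[c(1:2, 31:38), ]           # 2/10 hits vs 18/90
  res2 <- regionset_enrichment(query2, bg, targets)
  expect_gte(res2$p_value, 0.5)
})

test_that("query regions outside the background are dropped with a warning", {
  bg <- data.frame(chrom = "chr1", start = c(100, 200), end = c(150, 250))
  q <- data.frame(chrom = "chr1", start = c(100, 999), end = c(150, 1099))
  ts <- list(t = region_set("chr1", 100, 120, name = "t"))
  expect_warning(res <- regionset_enrichment(q, bg, ts), "dropped")
  expect_equal(res$query_hits + res$query_misses, 1L)
})

test_that("BY adjustment dominates BH and is monotone in p-value rank", {
  set.seed(42)
  p <- sort(runif(12))
  by <- stats::p.adjust(p, "BY")
  bh <- stats::p.adjust(p, "BH")
  expect_true(all(by >= bh))
  expect_true(all(diff(by) >= -1e-15))
  # the enrichment table uses BY across target sets
  bg <- data.frame(chrom = "chr1", start = 1000 * (1:60),
                   end = 1000 * (1:60) + 10)
  sets <- lapply(1:4, function(k) {
    rows <- seq(k, 60, by = k + 1)
    region_set("chr1", 1000 * rows, 1000 * rows + 5, name = paste0("s", k))
  })
  names(sets) <- paste0("s", 1:4)
  res <- regionset_enrichment(bg[1:15, ], bg, sets)
  expect_equal(res$q_value,
               stats::p.adjust(res$p_value, "BY"))
  expect_true(all(res$q_value >= res$p_value))
})
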