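test_that("combinatorial entropy matches hand-computed values and bounds", {
  expect_equal(combinatorial_entropy(mono_counts()), 0)
  expect_equal(combinatorial_entropy(uniform_counts()), -100)
  two <- stats::setNames(c(30L, 30L), c("0000", "1111"))
  expect_equal(combinatorial_entropy(make_epi(list(two))$counts), -25)
  expect_error(combinatorial_entropy(rep(0, 16)), "zero total")
})

test_that("entropy agrees with a high-precision direct evaluation on random distributions", {
  set.seed(11)
  for (i in 1:200) {
    p <- rgamma(16, shape = runif(1, 0.2, 5))
    p <- p / sum(p)
    # independent oracle: direct evaluation in natural logs at full precision
    oracle <- 25 * sum(ifelse(p > 0, p * log(p), 0)) / log(2)
    expect_equal(combinatorial_entropy(p), oracle, tolerance = 1e-9)
    expect_gte(combinatorial_entropy(p), -100)
    expect_lte(combinatorial_entropy(p), 0)
  }
})

test_that("epipolymorphism conventions are complementary and bounded", {
  expect_equal(epipolymorphism(mono_counts()), 0)
  expect_equal(epipolymorphism(uniform_counts()), 0.9375)
  expect_equal(epipolymorphism(uniform_counts(), "as_printed"), 0.0625)
  set.seed(12)
  for (i in 1:50) {
    cnt <- stats::setNames(rpois(16, 5) + 1L, epiallele_patterns())
    d <- epipolymorphism(cnt)
    a <- epipolymorphism(cnt, "as_printed")
    expect_equal(d + a, 1)
    expect_gte(d, 0); expect_lte(d, 0.9375)
  }
})

test_that("entropy shifts score shared windows with the strict eloci cutoff", {
  ref <- make_epi(list(mono_counts(), mono_counts(), uniform_counts()),
                  sample_id = "N")
  smp <- make_epi(list(mono_counts(), uniform_counts(), uniform_counts()),
                  sample_id = "T")
  rec <- entropy_shift(smp, ref)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$delta_S, c(0, -100, 0))
  expect_equal(rec$is_elocus, c(FALSE, TRUE, FALSE))

  # delta_S of exactly -60 is NOT an elocus ("below -60" is strict)
  rec2 <- entropy_shift(smp, ref, elocus_threshold = -100)
  expect_false(any(rec2$is_elocus))

  disjoint <- make_epi(list(mono_counts()), sample_id = "X")
  disjoint$windows$pos1 <- 99999L
  disjoint$windows$pos2 <- 100010L
  disjoint$windows$pos3 <- 100020L
  disjoint$windows$pos4 <- 100030L
  expect_warning(e <- entropy_shift(disjoint, ref), "no shared windows")
  expect_equal(nrow(e), 0L)
})

test_that("eloci normalization follows the cohort-mean formula", {
  recA <- data.frame(is_elocus = c(rep(TRUE, 5), rep(FALSE, 95)))
  recB <- data.frame(is_elocus = c(rep(TRUE, 10), rep(FALSE, 190)))
  out <- summarize_eloci(list(A = recA, B = recB))
  expect_equal(out$normalized_eloci, c(7.5, 7.5))

  single <- summarize_eloci(list(A = recA))
  expect_equal(single$normalized_eloci, 5)  # own mean: normalized = raw

  none <- data.frame(is_elocus = rep(FALSE, 50))
  expect_equal(summarize_eloci(list(A = none, B = recA))$normalized_eloci[1],
               0)
  empty <- data.frame(is_elocus = logical(0))
  expect_warning(out2 <- summarize_eloci(list(A = recA, Z = empty)),
                 "zero assessed")
  expect_equal(out2$sample_id, "A")
})

test_that("the shift ECDF is a right-continuous step function", {
  f <- shift_ecdf(c(-10, -20, -30))
  expect_equal(f(-20), 2 / 3)
  expect_equal(f(-31), 0)
  expect_equal(f(-10), 1)
  expect_equal(f(5), 1)
  expect_error(shift_ecdf(numeric(0)), "empty")
})

test_that("group quantiles minimize pinball loss with lower-endpoint ties", {
  q <- group_quantile(1:100, rep("g", 100), 0.5)
  expect_equal(q$estimate, 50)  # minimizing interval [50, 51], lower end

  # brute-force pinball-loss oracle on a fine grid
  set.seed(13)
  x <- rnorm(37)
  for (tau in c(0.01, 0.25, 0.5, 0.9)) {
    grid <- sort(unique(x))
    loss <- vapply(grid, function(qv) {
      u <- x - qv
      sum(u * (tau - (u < 0)))
    }, numeric(1))
    oracle <- grid[which.min(loss)]
    expect_equal(group_quantile(x, rep("g", length(x)), tau)$estimate,
                 oracle)
    # cross-check against the inverse-ECDF quantile definition
    expect_equal(group_quantile(x, rep("g", length(x)), tau)$estimate,
                 unname(stats::quantile(x, tau, type = 1)))
  }

  expect_equal(group_quantile(c(7), "g", 0.2)$estimate, 7)
  shifted <- group_quantile(c(1:10, 11:20 + 10), rep(c("a", "b"), each = 10),
                            0.3)
  expect_equal(diff(shifted$estimate), 20)
  expect_error(group_quantile(1:5, rep("g", 5), 1.5), "tau")
})

test_that("windows stratify into every overlapping region class", {
  rec <- data.frame(chrom = "chr1", pos1 = c(100L, 300L, 900L),
                    pos2 = c(110L, 310L, 910L), pos3 = c(120L, 320L, 920L),
                    pos4 = c(130L, 330L, 930L))
  sets <- list(
    promoter = region_set("chr1", 90, 140, name = "promoter"),
    enhancer = region_set("chr1", 125, 350, name = "enhancer"),
    PMD = region_set("chr1", 1, 500, name = "PMD"))
  st <- stratify_shift_records(rec, sets, partitions = "PMD")
  expect_equal(nrow(st$all), 3L)
  expect_equal(st$promoter$pos1, 100L)
  # window 1 overlaps promoter AND enhancer (multi-assignment)
  expect_true(100L %in% st$enhancer$pos1)
  expect_equal(st$PMD$pos1, c(100L, 300L))
  expect_equal(st$outside_PMD$pos1, 900L)
  # inside/outside PMD is a binary partition
  expect_equal(nrow(st$PMD) + nrow(st$outside_PMD), nrow(rec))
})
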