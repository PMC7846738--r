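test_that("methylation distance is Euclidean over the filtered feature space", {
  p1 <- make_profile(pos = c(100, 200, 300), meth = c(0, 0, 0),
                     total = rep(50, 3), sample_id = "A")
  p2 <- make_profile(pos = c(100, 200, 300), meth = c(50, 50, 50),
                     total = rep(50, 3), sample_id = "B")
  d <- methylation_distance(list(p1, p2), min_reads = 10, min_mad = 0)
  expect_equal(unname(d["A", "B"]), sqrt(3))
  expect_equal(diag(d), c(A = 0, B = 0))

  d0 <- methylation_distance(list(p1, p1), min_reads = 10, min_mad = 0)
  expect_equal(unname(d0[1, 2]), 0)

  # MAD filter removes invariant CpGs: identical values at one CpG do not
  # change the distance when that CpG is excluded
  p3 <- make_profile(pos = c(100, 200), meth = c(0, 25), total = c(50, 50),
                     sample_id = "C")
  p4 <- make_profile(pos = c(100, 200), meth = c(50, 25), total = c(50, 50),
                     sample_id = "D")
  dmad <- methylation_distance(list(p3, p4), min_reads = 10, min_mad = 10)
  expect_equal(attr(dmad, "n_features"), 1L)
  expect_equal(unname(dmad[1, 2]), 1)
  expect_error(methylation_distance(list(p3, p4), min_reads = 100,
                                    min_mad = 0), "coverage filter")
})

test_that("mutation distance is the symmetric set difference", {
  a <- mutation_profile("A", c("m1", "m2", "m3"))
  b <- mutation_profile("B", c("m1", "m4"))
  c_ <- mutation_profile("C", c("x1", "x2"))
  d <- mutation_distance(list(a, b, c_))
  expect_equal(unname(d["A", "B"]), 3)
  expect_equal(unname(d["A", "C"]), 5)   # disjoint: 3 + 2
  expect_equal(unname(d["A", "A"]), 0)
  expect_true(isSymmetric(d))
})

test_that("neighbor joining recovers additive trees and the 3-taxon closed form", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- ape::cophenetic.phylo(tr)
  out <- nj_tree(d, root_label = "A")
  expect_equal(ape::cophenetic.phylo(out)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)

  # equilateral 3-taxon matrix: star with branch lengths 1
  d3 <- matrix(2, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  diag(d3) <- 0
  t3 <- nj_tree(d3, root_label = "X")
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["X", "Y"], 2)
  expect_equal(cp["Y", "Z"], 2)

  dz <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  tz <- nj_tree(dz, "X")
  expect_true(all(tz$edge.length <= 1e-12))

  expect_error(nj_tree(d3[1:2, 1:2], "X"), "at least 3")
  expect_error(nj_tree(d3, "Q"), "not among")
})

test_that("relabelling taxa permutes leaves without changing the topology", {
  set.seed(31)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.5, 2))
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(d))
  d2 <- d[perm, perm]
  t1 <- nj_tree(d, root_label = rownames(d)[1])
  t2 <- nj_tree(d2, root_label = rownames(d)[1])
  expect_equal(ape::cophenetic.phylo(t2)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(t1)[rownames(d), rownames(d)],
               tolerance = 1e-9)
})

test_that("pairwise normalization divides by the within-group maximum", {
  d <- matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  np <- normalize_pairwise(d)
  expect_equal(sort(np$normalized), c(0.5, 0.5, 1.0))
  single <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_equal(normalize_pairwise(single)$normalized, 1.0)
  zeros <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(normalize_pairwise(zeros)$normalized, 0)
})

test_that("distance correlation reproduces brute-force Spearman ranks", {
  expect_equal(distance_correlation(1:5, 2 * (1:5) + 3)$coefficient, 1)
  expect_equal(distance_correlation(1:5, -(1:5))$coefficient, -1)
  g <- c(1, 2, 3, 4); m <- c(2, 1, 3, 4)
  r <- distance_correlation(g, m)
  # hand-ranked Spearman: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  dd <- rank(g) - rank(m)
  expect_equal(r$coefficient, 1 - 6 * sum(dd^2) / (4 * 15))
  expect_equal(r$n, 4L)
  expect_error(distance_correlation(1:2, 1:2), "at least 3")
})
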