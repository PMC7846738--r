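#' Euclidean methylation distance between specimens
#'
#' Builds the methylation feature space shared by all specimens of a
#' patient or lesion: CpGs covered by at least `min_reads` reads in EVERY
#' profile, optionally restricted to a region set (e.g. promoters, defined
#' as 1 kb upstream to 500 bp downstream of annotated TSSs), and filtered
#' to the most variable sites by mean absolute deviation (MAD) of beta on
#' the percent scale: \eqn{MAD = \frac{1}{n}\sum_s |100\beta_s -
#' \overline{100\beta}|}. The distance between two specimens is the
#' Euclidean distance between their beta vectors (fraction scale) over the
#' retained CpGs.
#'
#' Two canonical filter presets follow common practice for bisulfite
#' phylogenies: tree building uses `min_reads = 50, min_mad = 10` on
#' promoter CpGs; distance-correlation analyses use `min_reads = 20,
#' min_mad = 20` on all CpGs.
#'
#' @param profiles list of [meth_profile()] objects (>= 2).
#' @param min_reads per-CpG coverage required in all profiles.
#' @param min_mad MAD threshold in percentage points (sites with MAD >=
#'   `min_mad` are retained; 0 disables the filter).
#' @param regions optional [region_set()] restricting the feature space.
#' @return Symmetric distance matrix with zero diagonal, labelled by
#'   sample ids; the retained CpG count is attached as attribute
#'   `n_features`.
#' @export
methylation_distance <- function(profiles, min_reads = 50L, min_mad = 10,
                                 regions = NULL) {
  stopifnot(length(profiles) >= 2L)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  keys <- lapply(profiles, function(p) {
    s <- p$sites[p$sites$total >= min_reads, , drop = FALSE]
    paste(s$chrom, s$pos)
  })
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L) {
    stop("no CpG passes the coverage filter (>= ", min_reads,
         " reads in all samples)")
  }
  B <- vapply(profiles, function(p) {
    k <- paste(p$sites$chrom, p$sites$pos)
    p$sites$beta[match(shared, k)]
  }, numeric(length(shared)))
  coords <- do.call(rbind, strsplit(shared, " ", fixed = TRUE))
  chrom <- coords[, 1L]
  pos <- as.integer(coords[, 2L])
  keep <- rep(TRUE, length(shared))
  if (!is.null(regions)) keep <- overlaps_regions(chrom, pos, pos, regions)
  if (min_mad > 0) {
    pct <- 100 * B
    mad_ <- rowMeans(abs(pct - rowMeans(pct)))
    keep <- keep & mad_ >= min_mad
  }
  if (!any(keep)) {
    stop("no CpG passes the feature filters (regions / MAD >= ", min_mad, ")")
  }
  d <- as.matrix(stats::dist(t(B[keep, , drop = FALSE]), method = "euclidean"))
  dimnames(d) <- list(ids, ids)
  attr(d, "n_features") <- sum(keep)
  d
}

#' Hamming mutation distance between specimens
#'
#' The genetic distance between two specimens is the Hamming distance of
#' their variant presence/absence vectors over the union of all variants in
#' the group, i.e. the size of the symmetric difference of their variant
#' sets.
#'
#' @param profiles list of [mutation_profile()] objects.
#' @return Symmetric integer distance matrix labelled by sample ids.
#' @export
mutation_distance <- function(profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- profiles[[i]]$variants
      b <- profiles[[j]]$variants
      d[i, j] <- d[j, i] <- length(setdiff(a, b)) + length(setdiff(b, a))
    }
  }
  d
}

#' Neighbor-joining tree rooted at the matched normal
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) on a labelled
#' distance matrix, re-rooted at the specified label (the matched normal
#' specimen). Negative branch-length estimates, which NJ can produce for
#' non-additive matrices, are clamped to zero with the deficit transferred
#' to the sibling edge so that root-to-leaf distances are preserved as far
#' as possible.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @param root_label label to root at; must be among the matrix labels.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, root_label) {
  d <- as.matrix(d)
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must be labelled")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!root_label %in% labs) {
    stop("root label '", root_label, "' not among matrix labels")
  }
  tr <- ape::nj(stats::as.dist(d))
  tr <- ape::root(tr, outgroup = root_label, resolve.root = TRUE)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent)
    sib <- setdiff(sibs, e)
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
    }
  }
  tr
}

#' Normalize off-diagonal pairwise distances to [0, 1]
#'
#' Divides every off-diagonal distance by the maximum off-diagonal distance
#' of the matrix, putting each lesion's pairwise distances on a common
#' [0, 1] scale before pooling across lesions. An all-zero matrix maps to
#' all zeros.
#'
#' @param d symmetric distance matrix.
#' @return data.frame `from`, `to`, `distance`, `normalized` with one row
#'   per unordered off-diagonal pair.
#' @export
normalize_pairwise <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d) %||% as.character(seq_len(nrow(d)))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  if (nrow(ij) == 0L) stop("matrix has no off-diagonal pair")
  vals <- d[ij]
  mx <- max(vals)
  data.frame(from = labs[ij[, 1L]], to = labs[ij[, 2L]], distance = vals,
             normalized = if (mx > 0) vals / mx else rep(0, length(vals)),
             stringsAsFactors = FALSE)
}

#' Spearman correlation between genetic and methylation distances
#'
#' Two-tailed Spearman rank correlation between aligned pairwise distance
#' lists (e.g. Hamming mutation distance vs Euclidean methylation distance
#' for the same specimen pairs). The p-value uses the exact permutation
#' distribution when n <= 9 pairs (and no ties) and the large-sample
#' approximation otherwise.
#'
#' @param genetic,methylation aligned numeric vectors (same specimen pair
#'   at each index; n >= 3).
#' @return List of class `correlation_result` with `coefficient`, `n`,
#'   `p_value`, `method`.
#' @export
distance_correlation <- function(genetic, methylation) {
  stopifnot(length(genetic) == length(methylation))
  n <- length(genetic)
  if (n < 3L) stop("correlation needs at least 3 pairs")
  ct <- suppressWarnings(
    stats::cor.test(genetic, methylation, method = "spearman",
                    alternative = "two.sided", exact = n <= 9L))
  structure(list(coefficient = unname(ct$estimate), n = n,
                 p_value = ct$p.value, method = "spearman"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s rho = %.4f (n = %d, p = %.3g)\n",
              x$method, x$coefficient, x$n, x$p_value))
  invisible(x)
}
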