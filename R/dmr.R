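#' DMR-calling parameters
#'
#' Defaults mirror the documented defaults of kernel-smoothing noise-filter
#' DMR callers for bisulfite data: a 100 bp triangular kernel half-width,
#' per-CpG two-sided Fisher test at p < 0.01, smoothed methylation
#' difference of at least 0.2, at least 4 differential CpGs per region,
#' differential CpGs merged when within 200 bp, and a minimum region width
#' of 50 bp. All are exposed here and recorded in pipeline manifests.
#'
#' @param kernel_halfwidth triangular kernel half-width in bp.
#' @param max_p per-CpG Fisher p-value cutoff.
#' @param min_abs_delta_beta minimum |smoothed beta difference|.
#' @param min_cpgs minimum differential CpGs per region.
#' @param merge_gap maximum bp between merged differential CpGs.
#' @param min_width minimum region width in bp.
#' @param min_reads minimum reads per CpG in BOTH paired samples.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(kernel_halfwidth = 100, max_p = 0.01,
                       min_abs_delta_beta = 0.2, min_cpgs = 4L,
                       merge_gap = 200, min_width = 50, min_reads = 10L) {
  stopifnot(kernel_halfwidth > 0, max_p > 0, min_cpgs >= 1,
            merge_gap > 0, min_width > 0, min_reads >= 1,
            min_abs_delta_beta > 0, min_abs_delta_beta < 1)
  structure(list(kernel_halfwidth = kernel_halfwidth, max_p = max_p,
                 min_abs_delta_beta = min_abs_delta_beta,
                 min_cpgs = as.integer(min_cpgs), merge_gap = merge_gap,
                 min_width = min_width, min_reads = as.integer(min_reads)),
            class = "dmr_params")
}

#' Triangular-kernel smoothing of methylation read counts
#'
#' Smooths the methylated and total read counts at each CpG by a triangular
#' kernel over its genomic neighborhood: for the CpG at position x,
#' \eqn{\tilde M(x) = \sum_j w_j M_j} with
#' \eqn{w_j = \max(0, 1 - |x_j - x| / h)}, and likewise for total reads.
#' The site itself always enters with weight 1, so an isolated CpG keeps
#' its raw counts, and as \eqn{h \to 0^+} smoothing reduces to the identity.
#'
#' @param profile a [meth_profile()] (sites sorted; enforced by the class).
#' @param kernel_halfwidth kernel half-width h in bp.
#' @return data.frame `chrom`, `pos`, `meth_sm`, `total_sm`, `beta_sm`.
#' @export
smooth_counts <- function(profile, kernel_halfwidth = 100) {
  stopifnot(kernel_halfwidth > 0)
  s <- profile$sites
  meth_sm <- total_sm <- numeric(nrow(s))
  for (ch in unique(s$chrom)) {
    i <- which(s$chrom == ch)
    p <- s$pos[i]
    lo <- findInterval(p - kernel_halfwidth, p, left.open = TRUE) + 1L
    hi <- findInterval(p + kernel_halfwidth, p)
    for (k in seq_along(i)) {
      j <- lo[k]:hi[k]
      w <- 1 - abs(p[j] - p[k]) / kernel_halfwidth
      w <- pmax(w, 0)
      meth_sm[i[k]] <- sum(w * s$meth[i][j])
      total_sm[i[k]] <- sum(w * s$total[i][j])
    }
  }
  data.frame(chrom = s$chrom, pos = s$pos, meth_sm = meth_sm,
             total_sm = total_sm, beta_sm = meth_sm / total_sm,
             stringsAsFactors = FALSE)
}

## Vectorised two-sided Fisher exact p for 2x2 tables
## rows (a, b) vs (c, d); two-sided by summing hypergeometric point
## probabilities <= that of the observed table (the classical definition,
## as in stats::fisher.test, but fast enough for per-CpG use).
fisher2_p <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    N <- a[i] + b[i] + c[i] + d[i]
    m1 <- a[i] + c[i]           # column margin (methylated)
    k <- a[i] + b[i]            # row margin (sample 1)
    if (N == 0L || m1 == 0L || m1 == N || k == 0L || k == N) {
      p[i] <- 1
      next
    }
    support <- max(0L, k - (N - m1)):min(k, m1)
    dens <- stats::dhyper(support, m1, N - m1, k)
    pobs <- stats::dhyper(a[i], m1, N - m1, k)
    p[i] <- min(1, sum(dens[dens <= pobs * (1 + 1e-7)]))
  }
  p
}

#' Call differentially methylated regions between paired samples
#'
#' Paired-sample DMR calling with kernel noise filtering: both profiles are
#' restricted to shared CpGs covered by at least `min_reads` in each
#' sample, counts are smoothed with a triangular kernel
#' ([smooth_counts()]), and each CpG is tested by a two-sided Fisher exact
#' test on the rounded smoothed counts (methylated vs unmethylated, tumor
#' vs normal). A CpG is differential when p < `max_p` and the smoothed
#' methylation difference exceeds `min_abs_delta_beta` in absolute value;
#' consecutive differential CpGs of the same direction within `merge_gap`
#' bp are merged into a region, and regions with fewer than `min_cpgs`
#' differential CpGs or narrower than `min_width` bp are dropped. The
#' region p-value is the minimum member-CpG p-value.
#'
#' @param tumor,normal [meth_profile()] objects from the same patient.
#' @param params a [dmr_params()] list.
#' @return data.frame of class `dmr_set`: `chrom`, `start`, `end` (1-based
#'   inclusive CpG span), `direction` (`"gain"` = hypermethylated in tumor),
#'   `n_cpgs`, `mean_beta_tumor`, `mean_beta_normal`, `delta_beta`,
#'   `p_value`.
#' @export
call_dmrs <- function(tumor, normal, params = dmr_params()) {
  kt <- paste(tumor$sites$chrom, tumor$sites$pos)
  kn <- paste(normal$sites$chrom, normal$sites$pos)
  tt <- tumor$sites[tumor$sites$total >= params$min_reads, , drop = FALSE]
  nn <- normal$sites[normal$sites$total >= params$min_reads, , drop = FALSE]
  shared <- intersect(paste(tt$chrom, tt$pos), paste(nn$chrom, nn$pos))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_cpgs = integer(0), mean_beta_tumor = numeric(0),
                      mean_beta_normal = numeric(0), delta_beta = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("dmr_set", "data.frame")
  if (length(shared) == 0L) {
    warning("no shared CpGs with >= ", params$min_reads,
            " reads in both samples")
    return(empty)
  }
  tt <- tt[match(shared, paste(tt$chrom, tt$pos)), , drop = FALSE]
  nn <- nn[match(shared, paste(nn$chrom, nn$pos)), , drop = FALSE]
  o <- order(tt$chrom, tt$pos)
  tt <- tt[o, , drop = FALSE]
  nn <- nn[o, , drop = FALSE]
  pt <- meth_profile(tt[, c("chrom", "pos", "meth", "total")],
                     tumor$sample_id, role = "tumor")
  pn <- meth_profile(nn[, c("chrom", "pos", "meth", "total")],
                     normal$sample_id, role = "normal")
  st <- smooth_counts(pt, params$kernel_halfwidth)
  sn <- smooth_counts(pn, params$kernel_halfwidth)
  a <- round(st$meth_sm); b <- round(st$total_sm) - a
  c_ <- round(sn$meth_sm); d <- round(sn$total_sm) - c_
  pv <- fisher2_p(a, b, c_, d)
  dbeta <- st$beta_sm - sn$beta_sm
  diff <- pv < params$max_p & abs(dbeta) >= params$min_abs_delta_beta
  if (!any(diff)) return(empty)
  idx <- which(diff)
  dirn <- ifelse(dbeta[idx] > 0, "gain", "loss")
  newrun <- c(TRUE,
              st$chrom[idx[-1]] != st$chrom[idx[-length(idx)]] |
                dirn[-1] != dirn[-length(idx)] |
                (st$pos[idx[-1]] - st$pos[idx[-length(idx)]]) >
                params$merge_gap)
  run <- cumsum(newrun)
  regions <- lapply(split(seq_along(idx), run), function(ii) {
    j <- idx[ii]
    data.frame(chrom = st$chrom[j[1]], start = st$pos[j[1]],
               end = st$pos[j[length(j)]], direction = dirn[ii[1]],
               n_cpgs = length(j),
               mean_beta_tumor = mean(st$beta_sm[j]),
               mean_beta_normal = mean(sn$beta_sm[j]),
               delta_beta = mean(dbeta[j]),
               p_value = min(pv[j]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  keep <- out$n_cpgs >= params$min_cpgs &
    (out$end - out$start + 1) >= params$min_width
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Classify CpG sites as hyper-/hypomethylated relative to DMRs
#'
#' A shared CpG (covered by at least `min_reads` in both samples) is
#' labelled `hyper` when it lies inside a gain DMR and its methylation in
#' the matched normal is at most 20%, `hypo` when it lies inside a loss DMR
#' and its normal methylation is at least 20%, and `none` otherwise.
#'
#' @param tumor,normal [meth_profile()] objects.
#' @param dmrs a `dmr_set` from [call_dmrs()].
#' @param min_reads per-CpG coverage filter in both samples.
#' @param normal_beta_cut the 20% normal-methylation rule (default 0.20).
#' @return data.frame `chrom`, `pos`, `beta_tumor`, `beta_normal`, `label`.
#' @export
classify_cpg_sites <- function(tumor, normal, dmrs, min_reads = 10L,
                               normal_beta_cut = 0.20) {
  tt <- tumor$sites[tumor$sites$total >= min_reads, , drop = FALSE]
  nn <- normal$sites[normal$sites$total >= min_reads, , drop = FALSE]
  shared <- intersect(paste(tt$chrom, tt$pos), paste(nn$chrom, nn$pos))
  tt <- tt[match(shared, paste(tt$chrom, tt$pos)), , drop = FALSE]
  nn <- nn[match(shared, paste(nn$chrom, nn$pos)), , drop = FALSE]
  label <- rep("none", length(shared))
  if (nrow(dmrs)) {
    gain <- dmrs[dmrs$direction == "gain", , drop = FALSE]
    loss <- dmrs[dmrs$direction == "loss", , drop = FALSE]
    in_gain <- overlaps_regions(tt$chrom, tt$pos, tt$pos,
                                region_set(gain$chrom, gain$start, gain$end,
                                           name = "gain"))
    in_loss <- overlaps_regions(tt$chrom, tt$pos, tt$pos,
                                region_set(loss$chrom, loss$start, loss$end,
                                           name = "loss"))
    label[in_gain & nn$beta <= normal_beta_cut] <- "hyper"
    label[in_loss & nn$beta >= normal_beta_cut] <- "hypo"
  }
  data.frame(chrom = tt$chrom, pos = tt$pos, beta_tumor = tt$beta,
             beta_normal = nn$beta, label = label, stringsAsFactors = FALSE)
}

#' Coverage-normalized per-sample counts
#'
#' Normalizes per-sample counts (eloci, DMR-overlapping CpGs, DMRs) for
#' unequal numbers of assessed units: `count / assessed * mean(assessed)`
#' over the cohort. When all samples assessed the same number of units the
#' normalization is the identity.
#'
#' @param counts per-sample counts.
#' @param assessed per-sample assessed-unit totals (same length).
#' @return Numeric vector of normalized counts (NA where `assessed` is 0,
#'   with a warning; such samples are excluded from the cohort mean).
#' @export
normalized_counts <- function(counts, assessed) {
  stopifnot(length(counts) == length(assessed))
  ok <- assessed > 0
  if (any(!ok)) warning(sum(!ok), " sample(s) with zero assessed units")
  out <- rep(NA_real_, length(counts))
  out[ok] <- counts[ok] / assessed[ok] * mean(assessed[ok])
  out
}

#' Count DMRs per genomic region class
#'
#' A DMR is counted in a class when it overlaps any interval of that class
#' by at least 1 bp. Chromatin-state classes may overlap each other; for
#' sets named in `partitions` (repeats, PMDs) the complementary
#' `outside_<name>` class is also counted, so those pairs form a binary
#' partition of the DMR set.
#'
#' @param dmrs a `dmr_set`.
#' @param region_sets named list of [region_set()] objects.
#' @param partitions names of sets whose complement should also be counted.
#' @return data.frame `stratum`, `n_gain`, `n_loss`, `n_total`.
#' @export
stratify_dmrs <- function(dmrs, region_sets, partitions = character(0)) {
  strata <- list(all = rep(TRUE, nrow(dmrs)))
  for (nm in names(region_sets)) {
    hit <- overlaps_regions(dmrs$chrom, dmrs$start, dmrs$end,
                            region_sets[[nm]])
    strata[[nm]] <- hit
    if (nm %in% partitions) strata[[paste0("outside_", nm)]] <- !hit
  }
  data.frame(
    stratum = names(strata),
    n_gain = vapply(strata, function(h) sum(h & dmrs$direction == "gain"),
                    integer(1)),
    n_loss = vapply(strata, function(h) sum(h & dmrs$direction == "loss"),
                    integer(1)),
    n_total = vapply(strata, sum, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Average methylation over fixed genomic tiles
#'
#' Averages per-CpG beta values over nonoverlapping tiles anchored at
#' position 1 of each chromosome (so positions 1..tile_size form tile 1).
#' Only CpGs with at least `min_reads` reads contribute; tiles containing
#' no qualifying CpG are absent from the output. Tile values are unweighted
#' means of member-CpG betas.
#'
#' @param profile a [meth_profile()].
#' @param tile_size tile width in bp (default 5 kb).
#' @param min_reads per-CpG coverage filter.
#' @return data.frame `chrom`, `tile_start`, `tile_end`, `n_cpgs`,
#'   `mean_beta`.
#' @export
aggregate_tiles <- function(profile, tile_size = 5000, min_reads = 10L) {
  s <- profile$sites[profile$sites$total >= min_reads, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(data.frame(chrom = character(0), tile_start = integer(0),
                      tile_end = integer(0), n_cpgs = integer(0),
                      mean_beta = numeric(0)))
  }
  tile <- (s$pos - 1L) %/% tile_size
  key <- paste(s$chrom, tile)
  agg <- tapply(s$beta, key, mean)
  cnt <- tapply(s$beta, key, length)
  first <- !duplicated(key)
  ord <- order(s$chrom[first], tile[first])
  kk <- key[first][ord]
  data.frame(chrom = s$chrom[first][ord],
             tile_start = as.integer(tile[first][ord] * tile_size + 1L),
             tile_end = as.integer((tile[first][ord] + 1L) * tile_size),
             n_cpgs = as.integer(cnt[kk]),
             mean_beta = as.numeric(agg[kk]),
             stringsAsFactors = FALSE, row.names = NULL)
}
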