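#' LINE-1 surrogate for global methylation
#'
#' Mean methylation over CpGs falling inside evolutionarily young LINE-1
#' repeat elements (L1HS/L1PA subfamilies), a standard surrogate for the
#' global methylation level of a sample. CpGs must be covered by at least
#' `min_reads` reads; the value is the unweighted mean of the qualifying
#' per-CpG betas.
#'
#' @param profile a [meth_profile()].
#' @param line1_regions [region_set()] of L1HS/L1PA intervals.
#' @param min_reads per-CpG coverage filter (default 10).
#' @return Mean beta of qualifying LINE-1 CpGs.
#' @export
line1_methylation <- function(profile, line1_regions, min_reads = 10L) {
  s <- profile$sites[profile$sites$total >= min_reads, , drop = FALSE]
  hit <- overlaps_regions(s$chrom, s$pos, s$pos, line1_regions)
  if (!any(hit)) {
    stop("no CpG with >= ", min_reads, " reads inside the LINE-1 regions for '",
         profile$sample_id, "'")
  }
  mean(s$beta[hit])
}

#' Spearman correlation between a methylation summary and a genomic burden
#'
#' Two-tailed Spearman correlation between aligned per-specimen values,
#' e.g. LINE-1 methylation vs copy-number burden, allelic-imbalance event
#' count, (log2) tumor mutation burden, or clonal-mutation fraction.
#'
#' @param values per-specimen methylation summary (e.g. LINE-1 means).
#' @param burden aligned per-specimen burden values.
#' @return A `correlation_result` (see [distance_correlation()]).
#' @export
burden_correlation <- function(values, burden) {
  stopifnot(length(values) == length(burden))
  if (length(values) < 3L) stop("correlation needs at least 3 specimens")
  if (stats::sd(values) == 0 || stats::sd(burden) == 0) {
    stop("correlation undefined for a constant input")
  }
  distance_correlation(values, burden)
}

#' Signed distance from eloci to the nearest TSS
#'
#' Distance from each elocus window midpoint to the nearest transcription
#' start site. For stranded TSS entries the sign is negative upstream of
#' the TSS (5' on its strand) and positive downstream; unstranded entries
#' yield absolute distances. The TSS point of a stranded interval is its
#' strand-aware start (`start` on `+`, `end` on `-`).
#'
#' @param windows data.frame with `chrom`, `pos1`, `pos4` (e.g. eloci rows
#'   of a `shift_records` data.frame).
#' @param tss [region_set()] of TSS positions (1 bp intervals or wider).
#' @return Numeric vector of signed distances, one per window (NA when the
#'   window's chromosome has no TSS).
#' @export
nearest_tss_distance <- function(windows, tss) {
  if (nrow(tss) == 0L) stop("TSS region set is empty")
  mid <- floor((windows$pos1 + windows$pos4) / 2)
  tss_point <- ifelse(tss$strand == "-", tss$end, tss$start)
  out <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0L) next
    for (k in wi) {
      dd <- mid[k] - tss_point[ti]
      j <- ti[which.min(abs(dd))]
      delta <- mid[k] - tss_point[match(j, seq_len(nrow(tss)))]
      out[k] <- switch(tss$strand[j],
                       "+" = delta,
                       "-" = -delta,
                       abs(delta))
    }
  }
  out
}

#' Region-set enrichment by one-sided Fisher test
#'
#' Locus-overlap enrichment of a query region set (e.g. eloci of one stage)
#' against a background universe (e.g. all loci assessed at >= 60 reads):
#' for each target set, regions are classified as hits (>= 1 bp overlap
#' with the target) or misses, and over-representation of hits among the
#' query relative to the background-minus-query is tested by a one-sided
#' Fisher exact test (upper hypergeometric tail). Query regions must be a
#' subset of the background; violators are dropped with a warning.
#' q-values are Benjamini-Yekutieli adjusted across all target sets tested,
#' which controls the FDR under arbitrary dependence between target sets.
#'
#' @param query data.frame/`region_set` with `chrom`, `start`, `end` (for
#'   4-CpG loci, use pos1/pos4 as start/end).
#' @param background data.frame/`region_set` covering the query.
#' @param target_sets named list of [region_set()] objects.
#' @return data.frame of class `enrichment_result`: `target`, `query_hits`,
#'   `query_misses`, `bg_hits`, `bg_misses`, `odds_ratio`, `p_value`,
#'   `q_value` (BY).
#' @export
regionset_enrichment <- function(query, background, target_sets) {
  if (nrow(query) == 0L) stop("query region set is empty")
  qkey <- paste(query$chrom, query$start, query$end)
  bkey <- paste(background$chrom, background$start, background$end)
  outside <- !qkey %in% bkey
  if (any(outside)) {
    warning(sum(outside), " query region(s) not in the background dropped")
    query <- query[!outside, , drop = FALSE]
    qkey <- qkey[!outside]
    if (nrow(query) == 0L) stop("query region set is empty after enforcing query ⊆ background")
  }
  rest <- background[!bkey %in% qkey, , drop = FALSE]
  res <- lapply(names(target_sets), function(nm) {
    ts <- target_sets[[nm]]
    qh <- sum(overlaps_regions(query$chrom, query$start, query$end, ts))
    bh <- sum(overlaps_regions(rest$chrom, rest$start, rest$end, ts))
    a <- qh; b <- nrow(query) - qh
    c_ <- bh; d <- nrow(rest) - bh
    ## one-sided (greater) Fisher p = upper hypergeometric tail
    p <- stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
    or <- (a * d) / (b * c_)
    data.frame(target = nm, query_hits = a, query_misses = b,
               bg_hits = c_, bg_misses = d, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BY")
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
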