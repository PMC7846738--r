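#' Combinatorial entropy of an epiallele distribution
#'
#' For a 4-CpG locus with epiallele frequencies \eqn{F_1..F_16} over the 16
#' binary patterns, the combinatorial entropy is
#' \deqn{S = \frac{100}{4} \sum_{i=1}^{16} F_i \log_2 F_i,}
#' with \eqn{0 \log_2 0 := 0}. S lives on the \eqn{[-100, 0]} scale:
#' 0 for a monoclonal locus (one pattern at frequency 1) and -100 for the
#' uniform distribution over all 16 patterns.
#'
#' @param counts numeric vector of 16 pattern counts (or frequencies), or a
#'   matrix with 16 columns for vectorised evaluation over loci.
#' @return Numeric vector of S values, one per locus.
#' @export
#' @examples
#' x <- c(30, 30, rep(0, 14))
#' combinatorial_entropy(x)  # two patterns at 0.5 -> -25
combinatorial_entropy <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (ncol(m) != 16L) stop("expected 16 pattern slots, got ", ncol(m))
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("combinatorial entropy undefined for a locus with zero total reads")
  }
  f <- m / tot
  lf <- log2(f)
  lf[f == 0] <- 0
  as.numeric(25 * rowSums(f * lf))
}

#' Epipolymorphism of an epiallele distribution
#'
#' Epiallele diversity built from \eqn{\sum_i F_i^2} over the 16 pattern
#' frequencies. Two conventions are offered: `"as_printed"` returns
#' \eqn{\sum F_i^2} itself (1 for a monoclonal locus, 1/16 for uniform);
#' the default `"diversity"` returns its complement \eqn{1 - \sum F_i^2}
#' (0 monoclonal, 15/16 uniform), which increases with epiallele diversity
#' and is the scale on which epipolymorphism is usually compared across
#' lesions. The two conventions sum to one exactly.
#'
#' @inheritParams combinatorial_entropy
#' @param convention `"diversity"` (default) or `"as_printed"`.
#' @return Numeric vector, one value per locus.
#' @export
epipolymorphism <- function(counts, convention = c("diversity", "as_printed")) {
  convention <- match.arg(convention)
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (ncol(m) != 16L) stop("expected 16 pattern slots, got ", ncol(m))
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("epipolymorphism undefined for a locus with zero total reads")
  }
  ssq <- rowSums((m / tot)^2)
  if (convention == "as_printed") as.numeric(ssq) else as.numeric(1 - ssq)
}

#' Epiallele entropy shifts between a sample and its matched reference
#'
#' Scores every 4-CpG window present (at the read threshold of the input
#' tables, 60 reads by default) in BOTH the sample and the reference:
#' \eqn{\Delta S = S_{sample} - S_{reference}}. Windows with
#' \eqn{\Delta S} strictly below `elocus_threshold` (default -60) are
#' flagged as eloci — epigenetic shift loci whose epiallele composition has
#' drifted markedly from the matched normal. \eqn{\Delta S = -60} exactly is
#' not an elocus.
#'
#' @param sample,reference [epiallele_table()] objects (e.g. lesion and
#'   matched normal from the same patient).
#' @param elocus_threshold eloci cutoff on the \eqn{\Delta S} scale.
#' @return data.frame of class `shift_records` with one row per shared
#'   window: coordinates, per-side totals, `S_sample`, `S_reference`,
#'   `delta_S`, `epipoly_sample`, `epipoly_reference`, `is_elocus`.
#' @export
entropy_shift <- function(sample, reference, elocus_threshold = -60) {
  ks <- window_key(sample$windows)
  kr <- window_key(reference$windows)
  shared <- intersect(ks, kr)
  if (length(shared) == 0L) {
    warning("no shared windows between '", sample$sample_id, "' and '",
            reference$sample_id, "'")
  }
  is_ <- match(shared, ks)
  ir <- match(shared, kr)
  w <- sample$windows[is_, c("chrom", "pos1", "pos2", "pos3", "pos4"),
                      drop = FALSE]
  rownames(w) <- NULL
  if (length(shared)) {
    Ss <- combinatorial_entropy(sample$counts[is_, , drop = FALSE])
    Sr <- combinatorial_entropy(reference$counts[ir, , drop = FALSE])
    Es <- epipolymorphism(sample$counts[is_, , drop = FALSE])
    Er <- epipolymorphism(reference$counts[ir, , drop = FALSE])
  } else {
    Ss <- Sr <- Es <- Er <- numeric(0)
  }
  out <- cbind(w, data.frame(
    total_sample = sample$windows$total[is_],
    total_reference = reference$windows$total[ir],
    S_sample = Ss, S_reference = Sr, delta_S = Ss - Sr,
    epipoly_sample = Es, epipoly_reference = Er,
    is_elocus = (Ss - Sr) < elocus_threshold))
  class(out) <- c("shift_records", "data.frame")
  attr(out, "sample_id") <- sample$sample_id
  attr(out, "elocus_threshold") <- elocus_threshold
  out
}

#' Per-sample eloci counts with cohort normalization
#'
#' Raw eloci counts are biased by per-sample coverage (more assessable loci,
#' more eloci), so each sample's count is normalized: the number of eloci is
#' divided by the number of assessed loci in that sample and multiplied by
#' the average number of assessed loci across all samples in the cohort.
#'
#' @param records named list of `shift_records` (one per sample, as from
#'   [entropy_shift()]).
#' @return data.frame with `sample_id`, `n_eloci`, `n_assessed`,
#'   `normalized_eloci`.
#' @export
summarize_eloci <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  ids <- vapply(seq_along(records), function(i) {
    nm <- names(records)[i]
    if (!is.null(nm) && !is.na(nm) && nzchar(nm)) nm
    else attr(records[[i]], "sample_id") %||% as.character(i)
  }, character(1))
  n_assessed <- vapply(records, nrow, integer(1))
  n_eloci <- vapply(records, function(r) sum(r$is_elocus), integer(1))
  keep <- n_assessed > 0L
  if (any(!keep)) {
    warning("excluding sample(s) with zero assessed loci: ",
            paste(ids[!keep], collapse = ", "))
  }
  mean_assessed <- mean(n_assessed[keep])
  data.frame(sample_id = ids[keep], n_eloci = n_eloci[keep],
             n_assessed = n_assessed[keep],
             normalized_eloci = n_eloci[keep] / n_assessed[keep] *
               mean_assessed,
             stringsAsFactors = FALSE)
}

#' Empirical cumulative distribution of shift values
#'
#' Right-continuous ECDF, evaluable at arbitrary points; used for the
#' cumulative distribution curves of \eqn{\Delta S} and epipolymorphism
#' across stages.
#'
#' @param values numeric vector (at least one value).
#' @return A step function as returned by [stats::ecdf()].
#' @export
shift_ecdf <- function(values) {
  if (length(values) == 0L) stop("ECDF of an empty value set is undefined")
  stats::ecdf(values)
}

#' Per-group empirical quantiles as pinball-loss minimizers
#'
#' For each group, returns the value minimizing the pinball (quantile
#' regression check) loss \eqn{\sum_i \rho_\tau(x_i - q)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u < 0\})}. With a group-indicator design
#' this is the per-group empirical \eqn{\tau}-quantile; when the minimizer is
#' an interval, the lower endpoint is returned (deterministic tie-break).
#' Used to compare \eqn{\Delta S} distributions at the 1st percentile and
#' epipolymorphism at the 50th percentile across stages.
#'
#' @param values numeric vector.
#' @param groups grouping vector, same length as `values`.
#' @param tau quantile level in (0, 1).
#' @return data.frame with `group`, `tau`, `estimate` (one row per group,
#'   in factor-level or first-appearance order).
#' @export
group_quantile <- function(values, groups, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must be a single value in (0, 1)")
  }
  stopifnot(length(values) == length(groups))
  levs <- if (is.factor(groups)) levels(groups)[levels(groups) %in% groups] else
    unique(groups)
  est <- vapply(levs, function(g) {
    x <- sort(values[groups == g])
    if (length(x) == 0L) stop("group '", g, "' is empty")
    loss <- vapply(x, function(q) {
      u <- x - q
      sum(u * (tau - (u < 0)))
    }, numeric(1))
    x[which(loss <= min(loss) + 1e-12 * max(1, abs(min(loss))))[1L]]
  }, numeric(1))
  data.frame(group = as.character(levs), tau = tau, estimate = est,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify shift records by genomic region class
#'
#' A window is assigned to a region class when its 4-CpG span (pos1..pos4)
#' overlaps any interval of that class by at least 1 bp; a window may belong
#' to several classes. For sets named in `partitions` (e.g. PMDs, repeats)
#' the complementary `outside_<name>` stratum is also produced, making those
#' strata a binary partition of the records. The unrestricted `"all"`
#' stratum is always first.
#'
#' @param records a `shift_records` data.frame (or any data.frame with
#'   `chrom`, `pos1`, `pos4`).
#' @param region_sets named list of [region_set()] objects.
#' @param partitions character vector of `region_sets` names for which the
#'   outside stratum should also be returned.
#' @return Named list of record subsets, one per stratum.
#' @export
stratify_shift_records <- function(records, region_sets,
                                   partitions = character(0)) {
  out <- list(all = records)
  for (nm in names(region_sets)) {
    hit <- overlaps_regions(records$chrom, records$pos1, records$pos4,
                            region_sets[[nm]])
    out[[nm]] <- records[hit, , drop = FALSE]
    if (nm %in% partitions) {
      out[[paste0("outside_", nm)]] <- records[!hit, , drop = FALSE]
    }
  }
  out
}
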