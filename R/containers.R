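#' The 16 epiallele patterns
#'
#' An epiallele is the binary methylation pattern of four consecutive CpG
#' sites observed on a single bisulfite sequencing read, so the pattern space
#' has exactly 2^4 = 16 states. Patterns are indexed in lexicographic
#' (binary-counting) order, `"0000"` to `"1111"`, where `1` marks a methylated
#' CpG; this fixed order is the column order of every epiallele count matrix
#' in the package.
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' epiallele_patterns()
epiallele_patterns <- function() {
  grid <- expand.grid(rep(list(0:1), 4))[, 4:1]
  apply(grid, 1L, paste, collapse = "")
}

#' Ordered histologic stages
#'
#' Stage labels of the assumed progression: normal lung, atypical adenomatous
#' hyperplasia (AAH), adenocarcinoma in situ (AIS), minimally invasive
#' adenocarcinoma (MIA), invasive adenocarcinoma (ADC). The ordering
#' NORMAL < AAH < AIS < MIA < ADC is total and used wherever stages are
#' compared.
#'
#' @return Ordered factor levels as a character vector.
#' @export
stage_levels <- function() c("NORMAL", "AAH", "AIS", "MIA", "ADC")

as_stage <- function(x) {
  x <- toupper(as.character(x))
  bad <- !x %in% stage_levels()
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = stage_levels(), ordered = TRUE)
}

#' Construct a per-sample CpG methylation profile
#'
#' A methylation profile holds one sample's CpG-level methylation calls:
#' for each covered CpG the number of methylated and total reads and the
#' methylation fraction beta = meth/total. Positions are 1-based cytosine
#' coordinates on the forward strand (reverse-strand calls are assumed to
#' have been collapsed onto the forward C before entry). Sites with zero
#' total reads are never stored.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `meth`, `total`.
#'   `beta` is always recomputed as `meth/total`.
#' @param sample_id,patient_id,lesion_id,stage,role sample metadata; `stage`
#'   one of [stage_levels()], `role` `"tumor"` or `"normal"`.
#' @return An object of class `meth_profile`.
#' @export
meth_profile <- function(sites, sample_id, patient_id = NA_character_,
                         lesion_id = NA_character_, stage = "NORMAL",
                         role = c("tumor", "normal")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "meth", "total") %in% names(sites)))
  sites <- sites[sites$total > 0L, , drop = FALSE]
  if (any(sites$meth > sites$total)) {
    stop("meth_profile: meth reads exceed total reads at some site")
  }
  if (any(sites$meth < 0L) || any(sites$total < 0L)) {
    stop("meth_profile: negative read counts")
  }
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("meth_profile: duplicate (chrom, pos) keys")
  sites$beta <- sites$meth / sites$total
  rownames(sites) <- NULL
  structure(
    list(sample_id = sample_id, patient_id = patient_id,
         lesion_id = lesion_id, stage = as_stage(stage), role = role,
         sites = sites[, c("chrom", "pos", "meth", "total", "beta")]),
    class = "meth_profile"
  )
}

#' @export
print.meth_profile <- function(x, ...) {
  cat(sprintf("<meth_profile> %s (%s, %s): %d CpG sites on %d chromosome(s)\n",
              x$sample_id, as.character(x$stage), x$role, nrow(x$sites),
              length(unique(x$sites$chrom))))
  if (nrow(x$sites)) {
    cat(sprintf("  mean beta %.3f, mean coverage %.1f\n",
                mean(x$sites$beta), mean(x$sites$total)))
  }
  invisible(x)
}

#' Construct a per-sample epiallele count table
#'
#' Holds, for each 4-CpG window, the read counts over the 16 epiallele
#' patterns. Windows are keyed by the exact tuple of their four CpG
#' positions; overlapping windows from staggered reads are distinct loci.
#'
#' @param windows data.frame with columns `chrom`, `pos1`..`pos4`
#'   (strictly increasing per row).
#' @param counts integer matrix, `nrow(windows)` x 16, columns in
#'   [epiallele_patterns()] order.
#' @param sample_id sample identifier.
#' @return An object of class `epiallele_table`.
#' @export
epiallele_table <- function(windows, counts, sample_id) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "pos1", "pos2", "pos3", "pos4") %in% names(windows)))
  counts <- as.matrix(counts)
  if (nrow(windows) != nrow(counts) || ncol(counts) != 16L) {
    stop("epiallele_table: counts must be nrow(windows) x 16")
  }
  if (any(counts < 0)) stop("epiallele_table: negative counts")
  mono <- windows$pos1 < windows$pos2 & windows$pos2 < windows$pos3 &
    windows$pos3 < windows$pos4
  if (nrow(windows) && !all(mono)) {
    stop("epiallele_table: CpG positions must be strictly increasing")
  }
  key <- window_key(windows)
  if (anyDuplicated(key)) stop("epiallele_table: duplicate window keys")
  o <- order(windows$chrom, windows$pos1, windows$pos2, windows$pos3,
             windows$pos4)
  windows <- windows[o, c("chrom", "pos1", "pos2", "pos3", "pos4"),
                     drop = FALSE]
  counts <- counts[o, , drop = FALSE]
  colnames(counts) <- epiallele_patterns()
  rownames(windows) <- NULL
  windows$total <- as.integer(rowSums(counts))
  structure(list(sample_id = sample_id, windows = windows, counts = counts),
            class = "epiallele_table")
}

#' @export
print.epiallele_table <- function(x, ...) {
  cat(sprintf("<epiallele_table> %s: %d 4-CpG windows (median depth %s)\n",
              x$sample_id, nrow(x$windows),
              if (nrow(x$windows)) stats::median(x$windows$total) else "NA"))
  invisible(x)
}

window_key <- function(w) {
  paste(w$chrom, w$pos1, w$pos2, w$pos3, w$pos4, sep = ":")
}

#' Construct a named genomic region set
#'
#' In-memory intervals are 1-based and closed on both ends; conversion from
#' the 0-based half-open BED convention happens only in [read_bed()] /
#' [write_bed()].
#'
#' @param chrom,start,end interval coordinates (1-based, closed, start <= end).
#' @param strand optional strand (`"+"`, `"-"` or `"*"`).
#' @param name region-set name (e.g. `"promoter"`, `"PMD"`, `"LINE1"`).
#' @return A data.frame of class `region_set` with attribute `name`.
#' @export
region_set <- function(chrom, start, end, strand = "*", name = "regions") {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (any(start > end)) stop("region_set: start > end")
  if (!nzchar(name)) stop("region_set: name must be nonempty")
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> '%s': %d intervals, %s bp total\n",
              attr(x, "name"), nrow(x),
              format(sum(x$end - x$start + 1), big.mark = ",")))
  invisible(x)
}

#' Construct a per-specimen somatic mutation profile
#'
#' Variants are stored as a set (duplicates removed) of `chrom:pos:ref:alt`
#' keys; the Hamming distance between two specimens is the size of the
#' symmetric difference of their variant sets.
#'
#' @param sample_id specimen identifier.
#' @param variants character vector of variant keys or a data.frame with
#'   columns `chrom`, `pos`, `ref`, `alt`.
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(sample_id, variants = character(0)) {
  if (is.data.frame(variants)) {
    variants <- variant_key(variants$chrom, variants$pos, variants$ref,
                            variants$alt)
  }
  structure(list(sample_id = sample_id,
                 variants = sort(unique(as.character(variants)))),
            class = "mutation_profile")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("<mutation_profile> %s: %d variants\n", x$sample_id,
              length(x$variants)))
  invisible(x)
}

## -- internal helpers ------------------------------------------------------

regions_to_gr <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start, end = rs$end)
  )
}

## logical: does interval i (1-based closed) overlap any interval of rs by
## >= 1 bp?
overlaps_regions <- function(chrom, start, end, rs) {
  if (length(chrom) == 0L) return(logical(0))
  if (nrow(rs) == 0L) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  IRanges::overlapsAny(q, regions_to_gr(rs))
}

## deterministic child seed, kept below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
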