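#' Read a Bismark-style coverage file
#'
#' Parses the tab-separated coverage dialect
#' `chrom, start(1-based), end(optional), methylation percent, count
#' methylated, count unmethylated`. The percent column is ignored: beta is
#' always recomputed from the integer counts, which avoids rounding drift.
#' Rows with zero total reads are skipped with a warning; sites below
#' `min_reads` total coverage are dropped.
#'
#' @param path coverage file path.
#' @param min_reads minimum total reads per CpG (default 10, the usual
#'   single-CpG coverage filter for RRBS analyses).
#' @param sample_id,patient_id,lesion_id,stage,role metadata attached to the
#'   returned profile; `sample_id` defaults to the file name.
#' @return A [meth_profile()].
#' @export
read_coverage <- function(path, min_reads = 10L,
                          sample_id = sub("\\.[^.]*$", "", basename(path)),
                          patient_id = NA_character_,
                          lesion_id = NA_character_,
                          stage = "NORMAL", role = "tumor") {
  stopifnot(min_reads >= 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(meth_profile(
      data.frame(chrom = character(0), pos = integer(0), meth = integer(0),
                 total = integer(0)),
      sample_id, patient_id, lesion_id, stage, role))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (!all(nf %in% c(5L, 6L))) {
    bad <- which(!nf %in% c(5L, 6L))[1L]
    stop(sprintf("malformed coverage line %d in '%s': expected 5 or 6 fields, got %d",
                 bad, path, nf[bad]))
  }
  m <- matrix(unlist(parts[nf == nf[1L]]), ncol = nf[1L], byrow = TRUE)
  if (length(unique(nf)) > 1L) {
    stop(sprintf("malformed coverage line %d in '%s': inconsistent field count",
                 which(nf != nf[1L])[1L], path))
  }
  k <- ncol(m)
  chrom <- m[, 1L]
  pos <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, k - 1L]))
  unmeth <- suppressWarnings(as.integer(m[, k]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad)) {
    stop(sprintf("malformed coverage line %d in '%s': non-numeric field",
                 bad[1L], path))
  }
  total <- meth + unmeth
  if (any(total == 0L)) {
    warning(sprintf("%d coverage row(s) with zero reads skipped in '%s'",
                    sum(total == 0L), path))
  }
  keep <- total >= min_reads & total > 0L
  meth_profile(
    data.frame(chrom = chrom[keep], pos = pos[keep], meth = meth[keep],
               total = total[keep], stringsAsFactors = FALSE),
    sample_id, patient_id, lesion_id, stage, role)
}

#' Write a methylation profile as a Bismark-style coverage file
#'
#' @param profile a [meth_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(profile, path) {
  s <- profile$sites
  txt <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", s$chrom, s$pos, s$pos,
                 format(100 * s$beta, trim = TRUE, digits = 10),
                 s$meth, s$total - s$meth)
  writeLines(txt, path)
  invisible(path)
}

#' Filter CpG sites by chromosome and an exclusion mask
#'
#' Removes sex-chromosome and mitochondrial CpGs (`chrX`/`chrY`/`chrM`, with
#' or without the `chr` prefix) when `autosomes_only` is set, and any site
#' listed in `exclude_sites` (e.g. a user-supplied SNP mask; no database is
#' bundled or downloaded).
#'
#' @param profile a [meth_profile()].
#' @param autosomes_only drop non-autosomal sites.
#' @param exclude_sites data.frame with columns `chrom`, `pos`, or `NULL`.
#' @return The filtered [meth_profile()].
#' @export
filter_sites <- function(profile, autosomes_only = TRUE,
                         exclude_sites = NULL) {
  s <- profile$sites
  keep <- rep(TRUE, nrow(s))
  if (autosomes_only) {
    keep <- keep & !sub("^chr", "", s$chrom) %in% c("X", "Y", "M", "MT")
  }
  if (!is.null(exclude_sites) && nrow(exclude_sites)) {
    mask <- paste(exclude_sites$chrom, exclude_sites$pos)
    keep <- keep & !paste(s$chrom, s$pos) %in% mask
  }
  profile$sites <- s[keep, , drop = FALSE]
  rownames(profile$sites) <- NULL
  profile
}

#' Read a per-read epiallele pattern file
#'
#' Parses the tab-separated dialect `sample_id, chrom, pos1, pos2, pos3,
#' pos4, pattern, read_count` where `pattern` is four characters over
#' `{0,1}` (1 = methylated CpG). Counts for duplicate (window, pattern) rows
#' are summed; windows whose total read count is below `min_total_reads`
#' are dropped (default 60 reads, the depth at which the epiallele
#' composition of a 4-CpG locus is considered assessable).
#'
#' @param path pattern TSV path.
#' @param min_total_reads minimum reads per window (default 60).
#' @return An [epiallele_table()]. The file must contain a single sample.
#' @export
read_patterns <- function(path, min_total_reads = 60L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "chrom", "pos1", "pos2",
                                        "pos3", "pos4", "pattern", "count"),
                          colClasses = c("character", "character", "integer",
                                         "integer", "integer", "integer",
                                         "character", "integer"))
  if (nrow(df) == 0L) {
    return(epiallele_table(
      data.frame(chrom = character(0), pos1 = integer(0), pos2 = integer(0),
                 pos3 = integer(0), pos4 = integer(0)),
      matrix(0L, 0L, 16L), sample_id = sub("\\.[^.]*$", "", basename(path))))
  }
  sid <- unique(df$sample_id)
  if (length(sid) != 1L) {
    stop("pattern file '", path, "' contains multiple sample ids: ",
         paste(sid, collapse = ", "))
  }
  bad <- !grepl("^[01]{4}$", df$pattern)
  if (any(bad)) {
    stop(sprintf("pattern parse error at line %d of '%s': '%s' is not a 4-character 0/1 pattern",
                 which(bad)[1L], path, df$pattern[which(bad)[1L]]))
  }
  mono <- df$pos1 < df$pos2 & df$pos2 < df$pos3 & df$pos3 < df$pos4
  if (!all(mono)) {
    stop(sprintf("pattern parse error at line %d of '%s': CpG positions not strictly increasing",
                 which(!mono)[1L], path))
  }
  key <- window_key(df)
  ukey <- unique(key)
  windows <- df[match(ukey, key), c("chrom", "pos1", "pos2", "pos3", "pos4")]
  counts <- matrix(0L, nrow = length(ukey), ncol = 16L,
                   dimnames = list(NULL, epiallele_patterns()))
  idx <- cbind(match(key, ukey), match(df$pattern, epiallele_patterns()))
  for (r in seq_len(nrow(df))) {
    counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] +
      df$count[r]
  }
  keep <- rowSums(counts) >= min_total_reads
  epiallele_table(windows[keep, , drop = FALSE],
                  counts[keep, , drop = FALSE], sid)
}

#' Write an epiallele table as a pattern TSV
#'
#' Only nonzero pattern counts are written; [read_patterns()] on the output
#' restores the table (for windows above its read threshold).
#'
#' @param tab an [epiallele_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(tab, path) {
  w <- tab$windows
  lines <- character(0)
  if (nrow(w)) {
    nz <- which(tab$counts > 0L, arr.ind = TRUE)
    nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
    lines <- sprintf("%s\t%s\t%d\t%d\t%d\t%d\t%s\t%d",
                     tab$sample_id, w$chrom[nz[, 1L]], w$pos1[nz[, 1L]],
                     w$pos2[nz[, 1L]], w$pos3[nz[, 1L]], w$pos4[nz[, 1L]],
                     epiallele_patterns()[nz[, 2L]],
                     tab$counts[nz])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a region set
#'
#' BED is 0-based half-open on disk; in-memory intervals are 1-based closed,
#' so a BED line `chr1 100 200` becomes the interval covering positions
#' 101-200.
#'
#' @param path BED3+ file path.
#' @param name region-set name (defaults to the file name).
#' @return A [region_set()].
#' @export
read_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file '", path, "' has fewer than 3 columns")
  start0 <- as.integer(df[[2L]])
  end0 <- as.integer(df[[3L]])
  if (any(start0 >= end0)) {
    stop(sprintf("BED parse error at line %d of '%s': start >= end",
                 which(start0 >= end0)[1L], path))
  }
  strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else "*"
  region_set(df[[1L]], start0 + 1L, end0, strand = strand, name = name)
}

#' Write a region set as a BED file
#'
#' @param rs a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  has_strand <- any(rs$strand %in% c("+", "-"))
  if (has_strand) {
    txt <- sprintf("%s\t%d\t%d\t%s\t0\t%s", rs$chrom, rs$start - 1L, rs$end,
                   attr(rs, "name"), rs$strand)
  } else {
    txt <- sprintf("%s\t%d\t%d", rs$chrom, rs$start - 1L, rs$end)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a mutation table
#'
#' Tab-separated with columns `sample, chrom, pos, ref, alt` (no header).
#' Duplicate variant rows collapse to one set element.
#'
#' @param path mutation TSV path.
#' @return Named list of [mutation_profile()], one per sample.
#' @export
read_mutations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "chrom", "pos", "ref", "alt"))
  sapply(unique(df$sample), function(s) {
    d <- df[df$sample == s, , drop = FALSE]
    mutation_profile(s, variant_key(d$chrom, d$pos, d$ref, d$alt))
  }, simplify = FALSE)
}

#' Write mutation profiles as a mutation TSV
#' @param profiles list of [mutation_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(profiles, path) {
  lines <- unlist(lapply(profiles, function(p) {
    if (!length(p$variants)) return(character(0))
    parts <- do.call(rbind, strsplit(p$variants, ":", fixed = TRUE))
    sprintf("%s\t%s\t%s\t%s\t%s", p$sample_id, parts[, 1L], parts[, 2L],
            parts[, 3L], parts[, 4L])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with header `sample_id, patient_id, lesion_id, stage, role`.
#'
#' @param path sample sheet path.
#' @return data.frame with stage as an ordered factor.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "lesion_id", "stage", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sample sheet '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$stage <- as_stage(df$stage)
  df
}

#' Write / read a phylogenetic tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so trees
#' round-trip with branch lengths.
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @return `write_newick` returns `path` invisibly; `read_newick` the tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
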