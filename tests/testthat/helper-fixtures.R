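# Small in-code fixture builders shared across test files.

# epiallele table with one window per element of `counts`; each element is a
# named vector of pattern -> count (missing patterns are zero)
make_epi <- function(counts, sample_id = "S") {
  nw <- length(counts)
  windows <- data.frame(chrom = "chr1",
                        pos1 = 100L * seq_len(nw),
                        pos2 = 100L * seq_len(nw) + 15L,
                        pos3 = 100L * seq_len(nw) + 30L,
                        pos4 = 100L * seq_len(nw) + 45L)
  mat <- matrix(0L, nw, 16L, dimnames = list(NULL, epiallele_patterns()))
  for (i in seq_len(nw)) {
    mat[i, names(counts[[i]])] <- as.integer(counts[[i]])
  }
  epiallele_table(windows, mat, sample_id = sample_id)
}

# methylation profile from parallel vectors
make_profile <- function(pos, meth, total, chrom = "chr1", sample_id = "S",
                         role = "tumor", stage = "ADC") {
  meth_profile(data.frame(chrom = chrom, pos = as.integer(pos),
                          meth = as.integer(meth), total = as.integer(total)),
               sample_id = sample_id, stage = stage, role = role)
}

# uniform and monoclonal 16-slot count vectors
uniform_counts <- function(per = 10L) {
  stats::setNames(rep(per, 16L), epiallele_patterns())
}
mono_counts <- function(pattern = "1111", n = 160L) {
  out <- stats::setNames(rep(0L, 16L), epiallele_patterns())
  out[pattern] <- as.integer(n)
  out
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
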