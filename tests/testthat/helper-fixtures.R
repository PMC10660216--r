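# Small generators used across test files.  Everything is built in code at
# test time; no stored fixtures.

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_reads <- function(n, len_range = c(30, 200), with_qual = FALSE,
                         n_rate = 0) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(
      c("A", "C", "G", "T", "N"), l,
      replace = TRUE,
      prob = c(rep((1 - n_rate) / 4, 4), n_rate)
    ), collapse = "")
  }, character(1))
  tibble::tibble(
    id = sprintf("read%04d", seq_len(n)),
    seq = seqs,
    qual = if (with_qual) strrep("I", lens) else NA_character_
  )
}

write_temp_lines <- function(lines, ext = ".txt", gz = FALSE) {
  path <- tempfile(fileext = if (gz) paste0(ext, ".gz") else ext)
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

empty_orfs_for_test <- function() {
  find_orfs(random_reads(0))
}

# FASTQ crossing read lengths {49, 50, 181} with N counts {0, 1, 2}: nine
# reads covering every combination of the two quality-filter axes.
length_by_n_fastq <- function() {
  lens <- rep(c(49L, 50L, 181L), each = 3)
  ns <- rep(0:2, times = 3)
  lines <- unlist(lapply(seq_along(lens), function(i) {
    seq <- strrep("A", lens[i])
    if (ns[i] > 0) {
      substr(seq, 1, ns[i]) <- strrep("N", ns[i])
    }
    c(sprintf("@len%d_n%d", lens[i], ns[i]), seq, "+", strrep("I", lens[i]))
  }))
  list(path = write_temp_lines(lines, ".fastq"), lens = lens, ns = ns)
}
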