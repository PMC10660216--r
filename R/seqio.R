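#' Read sequences from a FASTA or FASTQ file
#'
#' Reads nucleotide sequence records into a tibble with one row per read.
#' Gzip-compressed input is handled transparently (detected from the file
#' content, not the extension).  Record identifiers are the first
#' whitespace-delimited token of the header line.  Sequences are uppercased
#' and any IUPAC ambiguity code other than A, C, G or T is normalised to
#' `N`, so downstream filters deal in a single ambiguity currency.
#'
#' Multi-line FASTA sequences are concatenated; FASTQ records are expected
#' in four-line form and the `+` separator line may or may not repeat the
#' identifier.  Malformed records (quality length differing from sequence
#' length, truncated records, empty sequences) raise an error naming the
#' record index and line number.  An empty file yields an empty tibble.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @param format One of `"auto"` (default; sniffed from the first character,
#'   `>` for FASTA and `@` for FASTQ), `"fasta"` or `"fastq"`.
#'
#' @return A tibble with columns `id` (character), `seq` (character over
#'   A/C/G/T/N) and `qual` (character, `NA` for FASTA input).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 a hot-spring read", "ACGT", "ACGT"), tf)
#' read_sequences(tf)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path))
  }
  lines <- read_text_lines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) {
    return(empty_reads())
  }
  if (format == "auto") {
    first <- substr(lines[[1]], 1, 1)
    format <- switch(first,
      ">" = "fasta",
      "@" = "fastq",
      abort(paste0(
        "cannot sniff sequence format: first character is ",
        encodeString(first, quote = "'"), ", expected '>' or '@'"
      ))
    )
  }
  if (format == "fasta") parse_fasta(lines, dna = TRUE) else parse_fastq(lines)
}

# readLines through gzfile(), which reads both plain and gzip content by
# inspecting the magic bytes; carriage returns stripped for DOS files.
read_text_lines <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  sub("\r$", "", readLines(con, warn = FALSE))
}

empty_reads <- function() {
  tibble(id = character(), seq = character(), qual = character())
}

first_token <- function(x) {
  stringr::str_extract(x, "^\\S+")
}

# Uppercase and collapse every non-ACGT IUPAC letter to N; anything that is
# not a letter is malformed.
normalise_dna <- function(seq, record, line) {
  seq <- toupper(seq)
  bad <- stringr::str_detect(seq, "[^A-Z]")
  if (any(bad)) {
    i <- which(bad)[[1]]
    abort(sprintf(
      "malformed record %d (line %d): sequence contains non-letter characters",
      record[i], line[i]
    ))
  }
  stringi::stri_replace_all_regex(seq, "[^ACGTN]", "N")
}

parse_fasta <- function(lines, dna = TRUE) {
  lines <- lines[lines != ""]
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[[1]]) {
    abort("malformed record 1 (line 1): FASTA input does not start with '>'")
  }
  rec <- cumsum(is_hdr)
  ids <- first_token(sub("^>", "", lines[is_hdr]))
  if (anyNA(ids)) {
    i <- which(is.na(ids))[[1]]
    abort(sprintf(
      "malformed record %d (line %d): empty FASTA header",
      i, which(is_hdr)[i]
    ))
  }
  seq_lines <- lines[!is_hdr]
  seqs <- vapply(
    split(seq_lines, factor(rec[!is_hdr], levels = seq_along(ids))),
    paste0,
    character(1),
    collapse = ""
  )
  empty <- !nzchar(seqs)
  if (any(empty)) {
    i <- which(empty)[[1]]
    abort(sprintf(
      "malformed record %d (line %d): record has no sequence",
      i, which(is_hdr)[i]
    ))
  }
  if (dna) {
    seqs <- normalise_dna(seqs, seq_along(ids), which(is_hdr))
  } else {
    seqs <- toupper(seqs)
  }
  tibble(id = ids, seq = unname(seqs), qual = NA_character_)
}

parse_fastq <- function(lines) {
  n <- length(lines)
  if (n %% 4 != 0) {
    abort(sprintf(
      "malformed record %d (line %d): truncated FASTQ record",
      n %/% 4 + 1, n
    ))
  }
  hdr <- lines[seq(1, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]
  rec <- seq_along(hdr)
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) {
    i <- which(bad_hdr)[[1]]
    abort(sprintf(
      "malformed record %d (line %d): FASTQ header does not start with '@'",
      i, 4L * i - 3L
    ))
  }
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) {
    i <- which(bad_plus)[[1]]
    abort(sprintf(
      "malformed record %d (line %d): FASTQ separator does not start with '+'",
      i, 4L * i - 1L
    ))
  }
  bad_len <- nchar(qual) != nchar(seqs)
  if (any(bad_len)) {
    i <- which(bad_len)[[1]]
    abort(sprintf(
      paste0(
        "malformed record %d (line %d): quality length %d does not match ",
        "sequence length %d"
      ),
      i, 4L * i, nchar(qual[i]), nchar(seqs[i])
    ))
  }
  ids <- first_token(sub("^@", "", hdr))
  if (anyNA(ids) || any(!nzchar(seqs))) {
    i <- which(is.na(ids) | !nzchar(seqs))[[1]]
    abort(sprintf(
      "malformed record %d (line %d): empty FASTQ header or sequence",
      i, 4L * i - 3L
    ))
  }
  tibble(
    id = ids,
    seq = normalise_dna(seqs, rec, 4L * rec - 2L),
    qual = qual
  )
}

#' Write sequence records to FASTA or FASTQ
#'
#' Inverse of [read_sequences()]: writes a reads tibble back to disk.  With
#' `format = "auto"` the format follows the records: FASTQ when every record
#' carries a quality string, FASTA otherwise.  A `.gz` path suffix writes
#' gzip-compressed output.
#'
#' @param x A tibble with columns `id`, `seq` and optionally `qual`.
#' @param path Output file path; gzip-compressed when it ends in `.gz`.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  qual <- if ("qual" %in% names(x)) x$qual else rep(NA_character_, nrow(x))
  if (format == "auto") {
    format <- if (nrow(x) > 0 && !anyNA(qual)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    if (anyNA(qual)) {
      abort("cannot write FASTQ: some records have no quality string")
    }
    out <- rbind(paste0("@", x$id), x$seq, "+", qual)
  } else {
    out <- rbind(paste0(">", x$id), x$seq)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.character(out), con)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Like [read_sequences()] but for amino-acid FASTA: sequences are
#' uppercased and left untouched otherwise (no nucleotide normalisation).
#'
#' @param path Path to a protein FASTA file, optionally gzip-compressed.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path))
  }
  lines <- read_text_lines(path)
  if (length(lines) == 0 || all(lines == "")) {
    return(tibble(id = character(), seq = character()))
  }
  out <- parse_fasta(lines, dna = FALSE)
  out$qual <- NULL
  out
}

#' Apply read quality filters
#'
#' Retains reads at least `min_len` bases long with at most `max_n`
#' ambiguous (`N`) bases; both limits are inclusive.  The defaults are the
#' conventional short-read thresholds for composition work: 50 bp minimum
#' length and at most one N per read.  Tallies are attached as an attribute
#' and retrieved with [filter_stats()]; a read failing both filters is
#' counted once, under length, so the tallies partition the input.
#'
#' @param reads A reads tibble as returned by [read_sequences()].
#' @param min_len Minimum read length in bp (inclusive, default 50).
#' @param max_n Maximum number of N bases per read (inclusive, default 1).
#' @return The surviving rows of `reads`, in order, with a `filter_stats`
#'   attribute.
#' @examples
#' reads <- tibble::tibble(
#'   id = c("a", "b"), seq = c("ACGT", strrep("A", 60)), qual = NA
#' )
#' filter_stats(quality_filter(reads))
#' @export
quality_filter <- function(reads, min_len = 50, max_n = 1) {
  stopifnot(min_len >= 1, max_n >= 0)
  len <- nchar(reads$seq)
  n_amb <- stringr::str_count(reads$seq, stringr::fixed("N"))
  fail_len <- len < min_len
  fail_n <- !fail_len & n_amb > max_n
  keep <- !fail_len & !fail_n
  out <- reads[keep, , drop = FALSE]
  attr(out, "filter_stats") <- tibble(
    n_in = length(keep),
    n_pass = sum(keep),
    n_fail_len = sum(fail_len),
    n_fail_n = sum(fail_n)
  )
  out
}

#' Retrieve the tallies attached by [quality_filter()]
#'
#' @param x A tibble returned by [quality_filter()].
#' @return A one-row tibble with columns `n_in`, `n_pass`, `n_fail_len`,
#'   `n_fail_n`; the three outcome columns always sum to `n_in`.
#' @export
filter_stats <- function(x) {
  st <- attr(x, "filter_stats", exact = TRUE)
  if (is.null(st)) {
    abort("`x` carries no filter statistics; was it returned by quality_filter()?")
  }
  st
}

#' Drop reads whose identifier is on an exclusion list
#'
#' Identifier-based read removal: the counterpart of mapping reads to a
#' host or contaminant reference externally and keeping only the unmapped
#' ones.  The mapping itself is out of scope here; this consumes its output
#' as a set of read ids.
#'
#' @param reads A reads tibble.
#' @param excluded_ids Character vector of read identifiers to drop (or a
#'   path readable by [read_id_list()]).
#' @return The rows of `reads` whose `id` is not excluded, in order.
#' @export
exclude_by_id <- function(reads, excluded_ids) {
  reads[!(reads$id %in% excluded_ids), , drop = FALSE]
}

#' Read a plain-text identifier list
#'
#' One read identifier per line; blank lines ignored; gzip transparent.
#'
#' @param path Path to the identifier list.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path))
  }
  lines <- read_text_lines(path)
  lines[nzchar(lines)]
}
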