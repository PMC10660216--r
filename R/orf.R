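# Bacterial/archaeal genetic code (translation table 11).  Sense codons are
# identical to the standard code; the table-11 difference is the wider set
# of permitted initiation codons, handled in find_orfs(), not here.
GENETIC_CODE_11 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STANDARD_AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

IVYWREL <- c("I", "V", "Y", "W", "R", "E", "L")

DEFAULT_STARTS <- c("ATG", "GTG", "TTG")

#' Reverse-complement nucleotide sequences
#'
#' Vectorised over a character vector; `N` maps to `N`.
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

#' Translate in-frame nucleotide sequences
#'
#' Translation under genetic code table 11 (bacteria/archaea).  Any codon
#' containing an ambiguous base translates to `X` rather than being solved,
#' so no residue is fabricated from uncertain sequence; stop codons appear
#' as `*` in the raw translation (callers split or strip them).  No
#' start-codon remapping is applied here: `GTG` translates to `V` wherever
#' it occurs.  [find_orfs()] rewrites the initial residue to `M` when a
#' call begins at a start codon.
#'
#' @param x Character vector of nucleotide sequences, each with length a
#'   multiple of 3.
#' @return Character vector of protein strings over the 20 standard
#'   residues plus `X` and `*`.
#' @examples
#' translate_dna(c("ATGAAA", "ATGNNNAAA"))
#' @export
translate_dna <- function(x) {
  bad <- nchar(x) %% 3 != 0
  if (any(bad)) {
    abort(sprintf(
      "sequence %d has length %d, not a multiple of 3",
      which(bad)[[1]], nchar(x)[bad][[1]]
    ))
  }
  ncod <- nchar(x) %/% 3
  if (sum(ncod) == 0) {
    return(rep("", length(x)))
  }
  pos <- 3L * (sequence(ncod) - 1L) + 1L
  codon <- substring(rep(toupper(x), ncod), pos, pos + 2L)
  aa <- unname(GENETIC_CODE_11[codon])
  aa[is.na(aa)] <- "X"
  joined <- paste(aa, collapse = "")
  ends <- cumsum(ncod)
  out <- substring(joined, c(1L, head(ends, -1L) + 1L), ends)
  out[ncod == 0] <- ""
  out
}

#' Find open reading frames in short reads by six-frame scanning
#'
#' Scans every read in all six reading frames and reports maximal stop-free
#' in-frame stretches as candidate coding fragments.  This is a
#' deterministic stand-in for a trained gene caller, designed for short
#' shotgun reads (~181 bp) that rarely contain complete genes.
#'
#' In `fragment` mode (default) every maximal stretch between stop codons
#' (or read edges) with at least `min_aa` translated residues is emitted;
#' `has_start`/`has_stop` record whether the stretch begins at a start
#' codon and ends at a stop codon.  In `complete` mode only stretches with
#' both a start codon and a terminal stop are emitted.  Overlapping calls
#' across frames and strands are all reported; use [select_orfs()] to
#' resolve one coding frame per read before composition pooling.
#'
#' Coordinates `start`/`end` are 0-based half-open on the forward strand of
#' the read, and include the stop codon when `has_stop` is true (so
#' `end - start` is always a multiple of 3 and the protein has
#' `(end - start)/3 - has_stop` residues).  When a call begins at a start
#' codon its first residue is reported as `M`, following the bacterial
#' convention for alternative initiation codons.
#'
#' @param reads A reads tibble (columns `id`, `seq`) or a character vector
#'   of sequences (names used as ids when present).
#' @param min_aa Minimum number of translated residues per call (default 20).
#' @param mode `"fragment"` (default) or `"complete"`.
#' @param starts Permitted initiation codons (default `ATG`, `GTG`, `TTG`,
#'   the table-11 set).
#' @return A tibble with one row per call: `parent_id`, `strand` (`+`/`-`),
#'   `frame` (0..2, offset on the scanned strand), `start`, `end`,
#'   `protein`, `cds` (the stretch's codons on the scanned strand, stop
#'   excluded), `has_start`, `has_stop`, `length_aa`.  Calls are ordered by
#'   input read, then (start, strand, frame).
#' @examples
#' find_orfs(paste0("ATG", strrep("GCT", 60), "TAA"), mode = "complete")
#' @export
find_orfs <- function(reads, min_aa = 20, mode = c("fragment", "complete"),
                      starts = DEFAULT_STARTS) {
  mode <- match.arg(mode)
  stopifnot(min_aa >= 1)
  if (is.character(reads)) {
    ids <- names(reads) %||% paste0("seq", seq_along(reads))
    reads <- tibble(id = ids, seq = unname(reads))
  }
  if (nrow(reads) == 0) {
    return(empty_orfs())
  }
  if (any(!nzchar(reads$seq))) {
    abort("empty sequence in `reads`")
  }
  seqs <- toupper(reads$seq)
  len <- nchar(seqs)
  rc <- revcomp(seqs)
  pieces <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqs else rc
    for (f in 0:2) {
      pieces[[length(pieces) + 1L]] <-
        scan_frame(s, len, strand, f, min_aa, starts)
    }
  }
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    return(empty_orfs())
  }
  if (mode == "complete") {
    out <- out[out$has_start & out$has_stop, , drop = FALSE]
  }
  out$parent_id <- reads$id[out$.read]
  out <- out[order(out$.read, out$start, out$strand, out$frame), , drop = FALSE]
  out$.read <- NULL
  out[, c(
    "parent_id", "strand", "frame", "start", "end", "protein", "cds",
    "has_start", "has_stop", "length_aa"
  )]
}

empty_orfs <- function() {
  tibble(
    parent_id = character(), strand = character(), frame = integer(),
    start = integer(), end = integer(), protein = character(),
    cds = character(), has_start = logical(), has_stop = logical(),
    length_aa = integer()
  )
}

# One (strand, frame) pass over all reads at once.  Codons are cut with a
# single vectorised substring() call; maximal stop-free runs are found with
# run-boundary logic on the flattened codon vector, and per-run protein and
# cds strings are cut back out of one concatenated string.
scan_frame <- function(s, len, strand, f, min_aa, starts) {
  ncod <- pmax((len - f) %/% 3L, 0L)
  total <- sum(ncod)
  if (total == 0) {
    return(NULL)
  }
  read_of <- rep.int(seq_along(s), ncod)
  cidx <- sequence(ncod) # 1-based codon index within the frame
  pos <- f + 3L * (cidx - 1L) + 1L
  codon <- substring(s[read_of], pos, pos + 2L)
  aa <- unname(GENETIC_CODE_11[codon])
  aa[is.na(aa)] <- "X"
  is_stop <- aa == "*"
  valid <- !is_stop
  new_read <- c(TRUE, read_of[-1L] != read_of[-total])
  prev_valid <- c(FALSE, valid[-total]) & !new_read
  run_start <- valid & !prev_valid
  next_valid <- c(valid[-1L], FALSE) & c(!new_read[-1L], FALSE)
  run_end <- valid & !next_valid
  first <- which(run_start)
  last <- which(run_end)
  n_aa <- last - first + 1L
  keep <- n_aa >= min_aa
  if (!any(keep)) {
    return(NULL)
  }
  first <- first[keep]
  last <- last[keep]
  n_aa <- n_aa[keep]
  # a run not ending at the read's final codon is terminated by a stop
  # (guard against looking across a read boundary in the flattened vector)
  next_same_read <- c(read_of[-1L], 0L)[last] == read_of[last]
  has_stop <- last < total & next_same_read & c(is_stop[-1L], FALSE)[last]
  has_start <- codon[first] %in% starts
  aa_all <- paste(aa, collapse = "")
  cds_all <- paste(codon, collapse = "")
  protein <- substring(aa_all, first, last)
  protein[has_start] <- paste0("M", substring(protein[has_start], 2L))
  cds <- substring(cds_all, 3L * (first - 1L) + 1L, 3L * last)
  s0 <- f + 3L * (cidx[first] - 1L)
  e0 <- f + 3L * cidx[last] + ifelse(has_stop, 3L, 0L)
  rd <- read_of[first]
  if (strand == "+") {
    start <- s0
    end <- e0
  } else {
    start <- len[rd] - e0
    end <- len[rd] - s0
  }
  tibble(
    .read = rd, strand = strand, frame = f,
    start = as.integer(start), end = as.integer(end),
    protein = protein, cds = cds,
    has_start = has_start, has_stop = has_stop,
    length_aa = as.integer(n_aa)
  )
}

#' Resolve one coding frame per read among overlapping ORF calls
#'
#' Six-frame scanning emits every stop-free stretch, so a read typically
#' yields calls in several frames of which at most one is genuinely coding.
#' Pooling them all dilutes the amino-acid composition with wrong-frame
#' residues and attenuates the temperature signal badly, so the pipeline
#' resolves a single call per read before pooling.
#'
#' `method = "likelihood"` (default) is a two-pass codon-usage classifier
#' in the spirit of trained gene callers: pass one takes, for each read,
#' the unique longest call where one exists and estimates codon frequencies
#' from those unambiguous calls; then, per read, candidates within `slack`
#' residues of the longest call are rescored by mean per-codon
#' log-likelihood and the best is kept (iterated `iterations` times,
#' retraining on the winners).  `method = "longest"` keeps the longest call
#' per read (ties broken by call order); `method = "all"` is the identity.
#' All methods are deterministic.
#'
#' @param orfs An ORF tibble from [find_orfs()].
#' @param method `"likelihood"`, `"longest"` or `"all"`.
#' @param slack Length slack (in residues) defining near-longest candidate
#'   calls for likelihood rescoring; default 1, which covers the one-codon
#'   frame-capacity difference between reading frames of the same read.
#' @param iterations Number of rescoring passes (default 2).
#' @param pseudocount Additive smoothing for codon frequencies.
#' @return The selected rows of `orfs` (at most one per `parent_id` for
#'   `"likelihood"` and `"longest"`).
#' @export
select_orfs <- function(orfs, method = c("likelihood", "longest", "all"),
                        slack = 1, iterations = 2, pseudocount = 0.5) {
  method <- match.arg(method)
  if (method == "all" || nrow(orfs) == 0) {
    return(orfs)
  }
  grp <- match(orfs$parent_id, unique(orfs$parent_id))
  max_len <- stats::ave(orfs$length_aa, grp, FUN = max)
  if (method == "longest") {
    idx <- which(orfs$length_aa == max_len)
    idx <- idx[!duplicated(grp[idx])]
    return(orfs[sort(idx), , drop = FALSE])
  }
  # candidates: within slack of the per-read maximum
  cand <- which(orfs$length_aa >= max_len - slack)
  # pass 1 training set: unique strict longest per read
  at_max <- orfs$length_aa == max_len
  n_at_max <- stats::ave(as.integer(at_max), grp, FUN = sum)
  train_idx <- which(at_max & n_at_max == 1L)
  if (length(train_idx) == 0) {
    train_idx <- which(at_max) # fully ambiguous input: train on everything
  }
  codons_of <- function(idx) {
    nc <- nchar(orfs$cds[idx]) %/% 3L
    p <- 3L * (sequence(nc) - 1L) + 1L
    list(
      codon = substring(rep(orfs$cds[idx], nc), p, p + 2L),
      row = rep.int(idx, nc),
      ncod = nc
    )
  }
  cc <- codons_of(cand)
  sense <- names(GENETIC_CODE_11)[GENETIC_CODE_11 != "*"]
  counts_from <- function(rows) {
    tab <- table(factor(cc$codon[cc$row %in% rows], levels = sense))
    as.numeric(tab)
  }
  winners <- train_idx
  for (it in seq_len(iterations)) {
    cnt <- counts_from(winners)
    logq <- log((cnt + pseudocount) / (sum(cnt) + pseudocount * length(sense)))
    names(logq) <- sense
    ll <- logq[cc$codon]
    ll[is.na(ll)] <- log(pseudocount / (sum(cnt) + pseudocount * length(sense)))
    score_sum <- rowsum(ll, cc$row)
    srow <- as.integer(rownames(score_sum))
    ncod_by_row <- setNames(cc$ncod, cand)
    score <- as.numeric(score_sum) / ncod_by_row[as.character(srow)]
    # per read, pick candidate with max mean log-likelihood (ties: first)
    g <- grp[srow]
    ord <- order(g, -score, srow)
    winners <- srow[ord][!duplicated(g[ord])]
  }
  orfs[sort(winners), , drop = FALSE]
}

#' Write translated ORF calls as a protein FASTA file
#'
#' Headers encode the parent read, strand, frame, forward-strand
#' coordinates and completeness flags:
#' `parent|strand|frame|start-end|partial` or `|complete`.
#'
#' @param orfs An ORF tibble from [find_orfs()].
#' @param path Output FASTA path (gzip when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  flags <- ifelse(orfs$has_start & orfs$has_stop, "complete", "partial")
  hdr <- sprintf(
    "%s|%s|%d|%d-%d|%s",
    orfs$parent_id, orfs$strand, orfs$frame, orfs$start, orfs$end, flags
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.character(rbind(paste0(">", hdr), orfs$protein)), con)
  invisible(path)
}
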