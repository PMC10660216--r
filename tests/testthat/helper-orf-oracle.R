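# Brute-force ORF oracle, independent of the package's vectorised scanner:
# reverses/complements with its own code, takes the genetic code from
# Biostrings, and walks every frame codon by codon, emitting each maximal
# stop-free window per the definition.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_find_orfs <- function(seq, min_aa = 20,
                             mode = c("fragment", "complete"),
                             starts = c("ATG", "GTG", "TTG")) {
  mode <- match.arg(mode)
  gc11 <- Biostrings::getGeneticCode("11")
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else oracle_revcomp(toupper(seq))
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 1) next
      cods <- vapply(
        seq_len(ncod),
        function(i) substr(s, f + 3 * (i - 1) + 1, f + 3 * i),
        character(1)
      )
      aas <- unname(gc11[cods])
      aas[is.na(aas)] <- "X"
      i <- 1
      while (i <= ncod) {
        if (aas[i] == "*") {
          i <- i + 1
          next
        }
        j <- i
        while (j < ncod && aas[j + 1] != "*") j <- j + 1
        n_aa <- j - i + 1
        has_stop <- j < ncod
        has_start <- cods[i] %in% starts
        keep <- n_aa >= min_aa &&
          (mode == "fragment" || (has_start && has_stop))
        if (keep) {
          prot <- paste(aas[i:j], collapse = "")
          if (has_start) prot <- paste0("M", substr(prot, 2, n_aa))
          s0 <- f + 3 * (i - 1)
          e0 <- f + 3 * j + if (has_stop) 3 else 0
          rows[[length(rows) + 1]] <- tibble::tibble(
            strand = strand, frame = f,
            start = if (strand == "+") s0 else L - e0,
            end = if (strand == "+") e0 else L - s0,
            protein = prot, has_start = has_start, has_stop = has_stop
          )
        }
        i <- j + 2
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      strand = character(), frame = integer(), start = integer(),
      end = integer(), protein = character(), has_start = logical(),
      has_stop = logical()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), start, strand, frame)
}

orf_key_cols <- function(orfs) {
  out <- orfs[, c("strand", "frame", "start", "end", "protein", "has_start", "has_stop")]
  out <- dplyr::arrange(out, start, strand, frame)
  out$frame <- as.integer(out$frame)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  tibble::as_tibble(out)
}
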