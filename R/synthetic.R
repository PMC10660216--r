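# Synonymous codons per residue under table 11 (no stop codons), used by
# reverse_translate(); uniform choice among them, so in-frame internal
# stops are impossible by construction.
CODONS_BY_AA <- split(names(GENETIC_CODE_11), unname(GENETIC_CODE_11))[STANDARD_AA]

NON_IVYWREL <- setdiff(STANDARD_AA, IVYWREL)

#' Specify a synthetic microbial community
#'
#' Defines the ground truth for a synthetic metagenome: a community whose
#' pooled proteome has a prescribed IVYWREL fraction — equivalently a
#' prescribed temperature via the linear calibration \eqn{f = (T+335)/937}
#' — together with the gene, read-length, coverage and ambiguity settings
#' used to turn it into shotgun-like reads.  Exactly one of `target_temp`
#' and `target_f` must be given.  All downstream draws derive from `seed`,
#' so every generated object is bit-reproducible.
#'
#' Defaults emulate a modest metagenomic sample: 200 genes of 150 residues,
#' 181-bp reads (a typical post-trimming short-read average), 5x coverage
#' and no ambiguous bases.
#'
#' @param target_temp Target temperature in degrees Celsius (range -335 to
#'   602, the image of \[0, 1\] under the calibration); or `NULL`.
#' @param target_f Target pooled IVYWREL fraction in \[0, 1\]; or `NULL`.
#' @param n_genes Number of genes (default 200).
#' @param gene_len_aa Residues per gene (default 150).
#' @param read_len Read length in bp (default 181).
#' @param coverage Mean per-base sequencing depth (default 5).
#' @param n_rate Per-base probability of replacing a read base by `N`
#'   (default 0).
#' @param intergenic_fraction Fraction of generated read bases drawn from
#'   random non-coding sequence rather than genes (default 0); useful for
#'   stressing the ORF caller.
#' @param allow_short_reads Permit genes shorter than `read_len`, which are
#'   then emitted as single whole-gene reads (default `FALSE`).
#' @param seed Integer seed governing all randomness (default 1).
#' @return A `community_spec` object.
#' @examples
#' community_spec(target_temp = 50, n_genes = 10, gene_len_aa = 100)
#' @export
community_spec <- function(target_temp = NULL, target_f = NULL,
                           n_genes = 200, gene_len_aa = 150,
                           read_len = 181, coverage = 5, n_rate = 0,
                           intergenic_fraction = 0,
                           allow_short_reads = FALSE, seed = 1) {
  if (is.null(target_temp) == is.null(target_f)) {
    abort("give exactly one of `target_temp` and `target_f`")
  }
  if (is.null(target_f)) {
    target_f <- (target_temp + 335) / 937
  } else {
    target_temp <- 937 * target_f - 335
  }
  if (target_f < 0 || target_f > 1) {
    abort("`target_f` must lie in [0, 1] (temperatures -335 to 602 °C)")
  }
  stopifnot(
    n_genes >= 1, gene_len_aa >= 1, read_len >= 1, coverage > 0,
    n_rate >= 0, n_rate <= 1,
    intergenic_fraction >= 0, intergenic_fraction < 1
  )
  structure(
    list(
      target_temp = target_temp, target_f = target_f,
      n_genes = as.integer(n_genes), gene_len_aa = as.integer(gene_len_aa),
      read_len = as.integer(read_len), coverage = coverage,
      n_rate = n_rate, intergenic_fraction = intergenic_fraction,
      allow_short_reads = allow_short_reads, seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Synthetic community: target %.2f °C (f = %.5f)\n",
      "  %d genes x %d aa, reads %d bp at %.1fx coverage, ",
      "N rate %.3g, seed %d\n"
    ),
    x$target_temp, x$target_f, x$n_genes, x$gene_len_aa, x$read_len,
    x$coverage, x$n_rate, x$seed
  ))
  invisible(x)
}

#' Generate a proteome with a prescribed pooled IVYWREL fraction
#'
#' Draws `n_genes` proteins of `gene_len_aa` residues whose pooled IVYWREL
#' fraction equals the spec's target exactly when `target_f * total
#' residues` is an integer, and the nearest achievable fraction otherwise
#' (reported in the `achieved_f` attribute; the quantisation error is at
#' most `1/(n_genes * gene_len_aa)`).  IVYWREL positions are drawn
#' uniformly among the seven signal residues and the remaining positions
#' uniformly among the other thirteen.
#'
#' @param spec A [community_spec()].
#' @return Character vector of `n_genes` protein strings with attribute
#'   `achieved_f`.
#' @export
make_proteome <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  total <- spec$n_genes * spec$gene_len_aa
  k <- round(spec$target_f * total)
  withr::with_seed(spec$seed, {
    res <- character(total)
    hot <- rep(FALSE, total)
    hot[sample.int(total, k)] <- TRUE
    res[hot] <- sample(IVYWREL, k, replace = TRUE)
    res[!hot] <- sample(NON_IVYWREL, total - k, replace = TRUE)
    gene <- rep(seq_len(spec$n_genes), each = spec$gene_len_aa)
    proteome <- vapply(
      split(res, gene), paste0,
      character(1), collapse = ""
    )
  })
  structure(unname(proteome), achieved_f = k / total)
}

#' Reverse-translate proteins to coding sequences
#'
#' Maps each residue to a uniformly chosen synonymous codon of genetic code
#' table 11 and appends a terminal `TAA` stop.  Because only sense codons
#' are used, the coding frame contains no internal stop by construction and
#' `translate_dna()` on the result (stop removed) round-trips to the input
#' protein.
#'
#' @param protein Character vector of protein strings over the 20 standard
#'   residues.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Character vector of CDS strings (each `3*(nchar(protein)+1)`
#'   long).
#' @examples
#' reverse_translate("MK", seed = 7)
#' @export
reverse_translate <- function(protein, seed = 1) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  bad <- !(flat %in% STANDARD_AA)
  if (any(bad)) {
    abort(sprintf(
      "invalid residue '%s' in protein", flat[which(bad)[[1]]]
    ))
  }
  nsyn <- lengths(CODONS_BY_AA)[flat]
  withr::with_seed(seed, {
    pick <- ceiling(runif(length(flat)) * nsyn)
  })
  codon <- mapply(
    function(a, i) CODONS_BY_AA[[a]][i], flat, pick,
    USE.NAMES = FALSE
  )
  ends <- cumsum(lengths(chars))
  joined <- paste(codon, collapse = "")
  cds <- substring(joined, 3L * c(0L, head(ends, -1L)) + 1L, 3L * ends)
  paste0(cds, "TAA")
}

#' Shred coding sequences into shotgun-like reads
#'
#' Emulates shotgun sequencing of the community's coding sequences: each
#' gene yields a Poisson number of reads matching the target coverage,
#' positioned uniformly along the gene, drawn from either strand with
#' equal probability, and with each base independently replaced by `N`
#' with probability `n_rate`.  Read identifiers encode the source gene,
#' read number, 0-based offset and strand
#' (`g<gene>_r<read>_p<offset>_<strand>`), so every read is traceable to
#' its truth.  Deterministic given the spec's seed.
#'
#' @param cds_list Character vector of CDS strings (see
#'   [reverse_translate()]), or any nucleotide contigs.
#' @param spec A [community_spec()].
#' @return A reads tibble (`id`, `seq`, `qual = NA`) suitable for
#'   [predict_mpt()] or [write_sequences()].
#' @export
shred_to_reads <- function(cds_list, spec) {
  stopifnot(inherits(spec, "community_spec"))
  len <- nchar(cds_list)
  short <- len < spec$read_len
  if (any(short) && !spec$allow_short_reads) {
    abort(paste0(
      "sequence shorter than read_len; set allow_short_reads = TRUE ",
      "to emit whole-gene reads"
    ))
  }
  if (spec$intergenic_fraction > 0) {
    frac <- spec$intergenic_fraction
    ig_len <- max(spec$read_len, round(frac / (1 - frac) * sum(len)))
    cds_list <- c(cds_list, random_contig(ig_len, spec$seed + 3L))
    names(cds_list)[length(cds_list)] <- "intergenic"
    len <- nchar(cds_list)
    short <- len < spec$read_len
  }
  gene_label <- names(cds_list) %||% sprintf("g%04d", seq_along(cds_list))
  gene_label[gene_label == ""] <- sprintf("g%04d", which(gene_label == ""))
  withr::with_seed(spec$seed + 2L, {
    n_reads <- rpois(length(cds_list), spec$coverage * len / spec$read_len)
    gene <- rep(seq_along(cds_list), n_reads)
    span <- pmin(len[gene], spec$read_len)
    offset <- floor(runif(length(gene)) * (len[gene] - span + 1))
    seqs <- substring(cds_list[gene], offset + 1, offset + span)
    flip <- runif(length(gene)) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    if (spec$n_rate > 0 && length(seqs) > 0) {
      seqs <- inject_n(seqs, spec$n_rate)
    }
  })
  if (length(gene) == 0) {
    return(empty_reads())
  }
  idx <- sequence(n_reads)
  tibble(
    id = sprintf(
      "%s_r%03d_p%d_%s", gene_label[gene], idx, offset,
      ifelse(flip, "rev", "fwd")
    ),
    seq = unname(seqs),
    qual = NA_character_
  )
}

# Per-base N replacement at rate `rate`, vectorised across reads.
inject_n <- function(seqs, rate) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  hit <- runif(length(flat)) < rate
  flat[hit] <- "N"
  ends <- cumsum(lengths(chars))
  joined <- paste(flat, collapse = "")
  substring(joined, c(1L, head(ends, -1L) + 1L), ends)
}

random_contig <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

#' Simulate a complete synthetic metagenome
#'
#' Convenience wrapper chaining [make_proteome()], [reverse_translate()]
#' and [shred_to_reads()] for one [community_spec()].  Sub-seeds are
#' derived from the spec's seed (seed for the proteome, seed+1 for the
#' codon draw, seed+2 for the shredding), so the whole object is
#' bit-reproducible.
#'
#' @param spec A [community_spec()].
#' @return A `community_sim` list: `reads` (tibble), `proteome`, `cds`,
#'   `achieved_f`, `spec`.
#' @examples
#' sim <- simulate_community(
#'   community_spec(target_temp = 50, n_genes = 20, gene_len_aa = 80, seed = 3)
#' )
#' nrow(sim$reads)
#' @export
simulate_community <- function(spec) {
  proteome <- make_proteome(spec)
  cds <- reverse_translate(proteome, seed = spec$seed + 1L)
  names(cds) <- sprintf("g%04d", seq_along(cds))
  reads <- shred_to_reads(cds, spec)
  structure(
    list(
      reads = reads, proteome = proteome, cds = cds,
      achieved_f = attr(proteome, "achieved_f"), spec = spec
    ),
    class = "community_sim"
  )
}

#' Write a simulated community and its manifest to disk
#'
#' Writes the reads (FASTA), the truth proteome (FASTA) and a JSON
#' manifest recording the spec and the achieved pooled IVYWREL fraction,
#' for use as fixtures by external tools.
#'
#' @param sim A `community_sim` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sequences(sim$reads, file.path(dir, "reads.fasta"))
  writeLines(
    as.character(rbind(
      paste0(">", names(sim$cds) %||% sprintf("g%04d", seq_along(sim$cds))),
      sim$proteome
    )),
    file.path(dir, "proteome.faa")
  )
  manifest <- c(
    unclass(sim$spec),
    list(achieved_f = sim$achieved_f, n_reads = nrow(sim$reads))
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
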