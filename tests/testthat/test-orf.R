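test_that("translation follows table 11 with ambiguity mapped to X", {
  expect_equal(translate_dna("ATGAAA"), "MK")
  expect_equal(translate_dna("ATGNNNAAA"), "MXK")
  expect_equal(translate_dna("GTGAAA"), "VK") # no start remapping here
  expect_equal(translate_dna("TAATAGTGA"), "***")
  expect_equal(translate_dna(""), "")
  expect_error(translate_dna("ACGTA"), "multiple of 3")
})

test_that("translation agrees with Biostrings on random clean sequences", {
  set.seed(31)
  seqs <- vapply(1:100, function(i) random_dna(3 * sample(1:60, 1)), character(1))
  ref <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seqs),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE
  ))
  expect_equal(translate_dna(seqs), unname(ref))
})

test_that("a constructed complete gene is called once with full coordinates", {
  gene <- paste0("ATG", strrep("GCT", 60), "TAA")
  calls <- find_orfs(gene, mode = "complete")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$protein, paste0("M", strrep("A", 60)))
  expect_true(calls$has_start && calls$has_stop)
  expect_equal(calls$start, 0L)
  expect_equal(calls$end, 186L)

  rc_calls <- find_orfs(revcomp(gene), mode = "complete")
  expect_equal(rc_calls$strand, "-")
  expect_equal(rc_calls$protein, calls$protein)
  expect_equal(rc_calls$start, 0L)
  expect_equal(rc_calls$end, 186L)
})

test_that("fragment mode emits edge-truncated stretches without start/stop", {
  # frame 0 of 100 bp with no stop anywhere: built from AAA codons
  calls <- find_orfs(strrep("AAA", 33), min_aa = 20)
  f0 <- calls[calls$strand == "+" & calls$frame == 0, ]
  expect_equal(nrow(f0), 1)
  expect_false(f0$has_start)
  expect_false(f0$has_stop)
  expect_equal(f0$protein, strrep("K", 33))
})

test_that("alternative start codons translate to M only at a call start", {
  seq <- paste0("GTG", strrep("AAA", 25), "TAA")
  call <- find_orfs(seq, mode = "complete")
  expect_equal(substr(call$protein[call$frame == 0 & call$strand == "+"], 1, 1), "M")
  # GTG mid-stretch stays V: no stop before it, so it is not a call start
  seq2 <- paste0("AAA", "GTG", strrep("AAA", 24))
  frag <- find_orfs(seq2, min_aa = 20)
  f0 <- frag[frag$strand == "+" & frag$frame == 0, ]
  expect_equal(substr(f0$protein, 1, 2), "KV")
})

test_that("six-frame calls match the brute-force oracle on random sequences", {
  set.seed(4004)
  for (i in 1:200) {
    seq <- random_dna(
      sample(30:300, 1),
      alphabet = if (i %% 5 == 0) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    )
    min_aa <- sample(c(5, 10, 20), 1)
    for (mode in c("fragment", "complete")) {
      got <- orf_key_cols(find_orfs(seq, min_aa = min_aa, mode = mode))
      want <- orf_key_cols(oracle_find_orfs(seq, min_aa = min_aa, mode = mode))
      expect_equal(got, want, info = sprintf("seq %d, mode %s", i, mode))
    }
  }
})

test_that("calls are strand-symmetric under reverse complement", {
  set.seed(55)
  for (i in 1:25) {
    seq <- random_dna(sample(60:250, 1))
    fwd <- orf_key_cols(find_orfs(seq, min_aa = 10))
    rev <- orf_key_cols(find_orfs(revcomp(seq), min_aa = 10))
    flipped <- rev
    flipped$strand <- ifelse(rev$strand == "+", "-", "+")
    flipped$start <- nchar(seq) - rev$end
    flipped$end <- nchar(seq) - rev$start
    flipped <- dplyr::arrange(flipped, start, strand, frame)
    # frames renumber under reflection; compare everything else
    cols <- c("strand", "start", "end", "protein", "has_start", "has_stop")
    expect_equal(flipped[, cols], fwd[, cols])
  }
})

test_that("no call is shorter than min_aa or contains a stop character", {
  set.seed(66)
  for (i in 1:20) {
    calls <- find_orfs(random_dna(200), min_aa = 8)
    expect_true(all(calls$length_aa >= 8))
    expect_false(any(grepl("*", calls$protein, fixed = TRUE)))
    expect_true(all((calls$end - calls$start) %% 3 == 0))
    expect_equal(
      nchar(calls$protein),
      (calls$end - calls$start) / 3 - as.integer(calls$has_stop)
    )
  }
})

test_that("complete-mode output is a subset of fragment-mode output", {
  set.seed(99)
  for (i in 1:20) {
    seq <- random_dna(sample(100:300, 1))
    frag <- orf_key_cols(find_orfs(seq, min_aa = 5, mode = "fragment"))
    comp <- orf_key_cols(find_orfs(seq, min_aa = 5, mode = "complete"))
    expect_equal(nrow(dplyr::anti_join(comp, frag, by = names(comp))), 0)
  }
})

test_that("frame resolution keeps at most one call per read and is deterministic", {
  set.seed(123)
  reads <- random_reads(80, len_range = c(150, 181))
  orfs <- find_orfs(reads, min_aa = 15)
  for (method in c("longest", "likelihood")) {
    sel <- select_orfs(orfs, method = method)
    expect_lte(max(table(sel$parent_id)), 1)
    expect_equal(sel, select_orfs(orfs, method = method))
  }
  expect_equal(select_orfs(orfs, method = "all"), orfs)
  expect_equal(nrow(select_orfs(empty_orfs_for_test(), method = "likelihood")), 0)
})

test_that("likelihood resolution recovers the true frame of coding reads", {
  # reads cut from a genuine CDS: the winning call should be the full-read
  # coding stretch in nearly all reads
  spec <- community_spec(
    target_temp = 37, n_genes = 40, gene_len_aa = 150, seed = 8
  )
  sim <- simulate_community(spec)
  orfs <- find_orfs(sim$reads)
  sel <- select_orfs(orfs)
  # the true coding stretch spans the read: 59 or 60 residues at 181 bp
  expect_gt(mean(sel$length_aa >= 59), 0.9)
})

test_that("ORF FASTA export writes one header per call with coordinates", {
  calls <- find_orfs(paste0("ATG", strrep("GCT", 60), "TAA"), mode = "complete")
  path <- tempfile(fileext = ".faa")
  write_orf_fasta(calls, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">seq1|+|0|0-186|complete")
  expect_equal(lines[2], calls$protein)
})
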