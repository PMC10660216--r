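test_that("a community spec needs exactly one of temperature and fraction", {
  expect_error(community_spec(), "exactly one")
  expect_error(community_spec(target_temp = 50, target_f = 0.4), "exactly one")
  expect_error(community_spec(target_temp = 700), "\\[0, 1\\]")
  sp <- community_spec(target_temp = 60)
  expect_equal(sp$target_f, (60 + 335) / 937)
  sp2 <- community_spec(target_f = 0.5)
  expect_equal(sp2$target_temp, 133.5)
})

test_that("generated proteomes hit integer-achievable fractions exactly", {
  all_hot <- make_proteome(community_spec(target_f = 1, n_genes = 2, gene_len_aa = 10))
  residues <- strsplit(paste(all_hot, collapse = ""), "")[[1]]
  expect_true(all(residues %in% c("I", "V", "Y", "W", "R", "E", "L")))
  expect_equal(pool_composition(all_hot)$f_ivywrel, 1)

  half <- make_proteome(community_spec(target_f = 0.5, n_genes = 1, gene_len_aa = 100))
  expect_equal(pool_composition(half)$f_ivywrel, 0.5)
  expect_equal(attr(half, "achieved_f"), 0.5)

  none <- make_proteome(community_spec(target_f = 0, n_genes = 3, gene_len_aa = 10))
  expect_equal(pool_composition(none)$f_ivywrel, 0)
})

test_that("quantisation error is bounded by one residue in the pool", {
  spec <- community_spec(target_temp = 60, n_genes = 7, gene_len_aa = 131)
  prot <- make_proteome(spec)
  total <- 7 * 131
  achieved <- pool_composition(prot)$f_ivywrel
  expect_equal(achieved, attr(prot, "achieved_f"))
  expect_lte(abs(achieved - (60 + 335) / 937), 1 / total)
})

test_that("proteome generation is bit-reproducible under a fixed seed", {
  spec <- community_spec(target_temp = 50, n_genes = 10, gene_len_aa = 50, seed = 99)
  expect_identical(make_proteome(spec), make_proteome(spec))
  other <- community_spec(target_temp = 50, n_genes = 10, gene_len_aa = 50, seed = 100)
  expect_false(identical(make_proteome(spec), make_proteome(other)))
})

test_that("reverse translation round-trips through translation", {
  cds <- reverse_translate("MK", seed = 3)
  expect_true(substr(cds, 1, 3) == "ATG")
  expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) == "TAA")
  expect_equal(translate_dna(substr(cds, 1, nchar(cds) - 3)), "MK")
  expect_identical(reverse_translate("MK", seed = 3), reverse_translate("MK", seed = 3))
  expect_error(reverse_translate("MJ"), "invalid residue")
})

test_that("reverse translation round-trips for many random proteins", {
  set.seed(14)
  prots <- vapply(1:1000, function(i) {
    paste(sample(metathermo:::STANDARD_AA, sample(5:80, 1), replace = TRUE),
      collapse = ""
    )
  }, character(1))
  cds <- reverse_translate(prots, seed = 77)
  stripped <- substr(cds, 1, nchar(cds) - 3)
  expect_equal(translate_dna(stripped), prots)
  # sense codons only: the coding frame never contains an internal stop
  expect_false(any(grepl("*", translate_dna(stripped), fixed = TRUE)))
})

test_that("shredding is reproducible and respects the N-rate", {
  spec <- community_spec(target_temp = 40, n_genes = 20, gene_len_aa = 100, seed = 6)
  cds <- reverse_translate(make_proteome(spec), seed = 7)
  reads1 <- shred_to_reads(cds, spec)
  reads2 <- shred_to_reads(cds, spec)
  expect_identical(reads1, reads2)
  expect_false(any(grepl("N", reads1$seq, fixed = TRUE)))
  expect_true(all(nchar(reads1$seq) == 181))
  # with no Ns and 181-bp reads, the standard QC keeps everything
  expect_equal(filter_stats(quality_filter(reads1))$n_pass, nrow(reads1))
})

test_that("read counts track coverage through the Poisson draw", {
  spec <- community_spec(
    target_temp = 40, n_genes = 100, gene_len_aa = 150,
    coverage = 5, seed = 11
  )
  cds <- reverse_translate(make_proteome(spec), seed = 12)
  reads <- shred_to_reads(cds, spec)
  expected <- 5 * sum(nchar(cds)) / 181
  expect_lt(abs(nrow(reads) - expected) / expected, 0.1)
})

test_that("a high N-rate fails the ambiguity filter as the binomial predicts", {
  spec <- community_spec(
    target_temp = 40, n_genes = 200, gene_len_aa = 120,
    read_len = 100, n_rate = 0.05, coverage = 14, seed = 13
  )
  cds <- reverse_translate(make_proteome(spec), seed = 2)
  reads <- shred_to_reads(cds, spec)
  expect_gt(nrow(reads), 5000)
  n_per_base <- sum(stringr::str_count(reads$seq, "N")) / sum(nchar(reads$seq))
  expect_lt(abs(n_per_base - 0.05), 0.005)
  # P(<= 1 N in 100 bases at 5%) is about 0.037: nearly all reads fail
  pass_frac <- filter_stats(quality_filter(reads))$n_pass / nrow(reads)
  expect_lt(pass_frac, 0.1)
})

test_that("the intergenic knob adds traceable non-coding reads", {
  spec <- community_spec(
    target_temp = 40, n_genes = 20, gene_len_aa = 100,
    intergenic_fraction = 0.3, seed = 9
  )
  cds <- reverse_translate(make_proteome(spec), seed = 10)
  names(cds) <- sprintf("g%04d", seq_along(cds))
  reads <- shred_to_reads(cds, spec)
  expect_gt(sum(grepl("^intergenic", reads$id)), 0)
})

test_that("whole simulations are reproducible and traceable", {
  spec <- community_spec(target_temp = 55, n_genes = 15, gene_len_aa = 90, seed = 31)
  sim1 <- simulate_community(spec)
  sim2 <- simulate_community(spec)
  expect_identical(sim1$reads, sim2$reads)
  expect_match(sim1$reads$id[1], "^g\\d+_r\\d+_p\\d+_(fwd|rev)$")
  dir <- tempfile()
  write_community(sim1, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$achieved_f, sim1$achieved_f)
  expect_equal(
    nrow(read_sequences(file.path(dir, "reads.fasta"))),
    nrow(sim1$reads)
  )
})
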