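test_that("genetic code partitions the 64 triplets in fixed TCAG order", {
  gc <- genetic_code()
  expect_length(gc$codons, 64)
  expect_setequal(c(gc$sense_codons, gc$stop_codons), gc$codons)
  expect_identical(gc$stop_codons, c("TAA", "TAG", "TGA"))
  expect_identical(gc$sense_codons[1:2], c("TTT", "TTC"))
  expect_identical(unname(gc$sense_index["TTT"]), 1L)
  # neighbour pairs: every pair differs at exactly one position
  p <- gc$pairs
  a <- strsplit(gc$sense_codons[p$i], "")
  b <- strsplit(gc$sense_codons[p$j], "")
  ndiff <- mapply(function(x, y) sum(x != y), a, b)
  expect_true(all(ndiff == 1))
})

test_that("FASTA loading converts triplets to states, gaps/N to missing", {
  aln <- h_aln_from_strings(c(A = "ATGAAA", B = "ATGAAG"))
  expect_equal(aln$n_codons, 2)
  gc <- genetic_code()
  expect_equal(aln$states["A", ], unname(gc$sense_index[c("ATG", "AAA")]))
  expect_equal(aln$states["B", ], unname(gc$sense_index[c("ATG", "AAG")]))

  aln2 <- h_aln_from_strings(c(A = "ATGAT-", B = "ATGNTA"))
  expect_true(is.na(aln2$states["A", 2]))
  expect_true(is.na(aln2$states["B", 2]))
  expect_false(anyNA(aln2$states[, 1]))
})

test_that("in-frame stops error in strict mode and mask under mask_stops", {
  expect_error(h_aln_from_strings(c(A = "ATGTAA", B = "ATGAAA")),
               "stop codon")
  aln <- h_aln_from_strings(c(A = "ATGTAA", B = "ATGAAA"), mask_stops = TRUE)
  expect_true(is.na(aln$states["A", 2]))
  expect_identical(attr(aln, "masked_stops"), 1L)
})

test_that("FASTA reader rejects ragged, off-frame and duplicate inputs", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "ATGAAA", ">B", "ATG"), f)
  expect_error(read_codon_alignment(f), "ragged")
  writeLines(c(">A", "ATGA", ">B", "ATGA"), f)
  expect_error(read_codon_alignment(f), "multiple of 3")
  writeLines(c(">A", "ATGAAA", ">A", "ATGAAA"), f)
  expect_error(read_codon_alignment(f), "duplicate")
})

test_that("FASTA round trip preserves states and missing placement", {
  aln <- h_random_aln(c("a", "b", "c", "d"), 30, seed = 5, miss_prob = 0.15)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, f)
  back <- read_codon_alignment(f)
  expect_identical(back$states, aln$states)
  expect_identical(back$taxa, aln$taxa)
})

test_that("gc3 counts third-position G/C over non-missing codons", {
  aln <- h_aln_from_strings(c(A = "GGGAAA", B = "GGCGCG"))
  expect_equal(gc3(aln, "A"), 0.5)
  expect_equal(gc3(aln, "B"), 1.0)
  expect_error(gc3(aln, "zebra"), "not in alignment")

  # column-order invariance
  aln3 <- h_random_aln(c("x", "y"), 40, seed = 2, miss_prob = 0.1)
  perm <- sample(40)
  aln3p <- codon_alignment(aln3$states[, perm], gene = "perm")
  expect_equal(gc3(aln3), gc3(aln3p))

  # fully-missing taxon is undefined, not 0
  st <- aln3$states
  st["x", ] <- NA_integer_
  expect_true(is.na(gc3(codon_alignment(st), "x")))
})

test_that("gc3 on random sequences matches a direct string-scan oracle", {
  set.seed(31)
  for (rep in 1:5) {
    nucs <- sample(c("A", "C", "G", "T", "N", "-"), 3000, replace = TRUE,
                   prob = c(rep(0.23, 4), 0.04, 0.04))
    mat <- rbind(A = nucs, B = sample(c("A", "C", "G", "T"), 3000, TRUE))
    aln <- omegascan:::codon_alignment_from_chars(mat, mask_stops = TRUE)
    expect_equal(gc3(aln, "A"), oracle_gc3_from_chars(nucs))
  }
})

test_that("delta_gc3 is the foreground-background mean difference", {
  aln <- h_aln_from_strings(c(f1 = "AAGGGG", f2 = "TTGCCC",
                              b1 = "AAAGGA", b2 = "TTTCCA"))
  expect_equal(delta_gc3(aln, c("f1", "f2")), 1)
  expect_equal(delta_gc3(aln, c("f1", "b1")),
               -delta_gc3(aln, c("f2", "b2")))
  # matches recomputation from per-taxon gc3
  aln2 <- h_random_aln(letters[1:6], 50, seed = 9, miss_prob = 0.05)
  g <- gc3(aln2)
  fg <- c("a", "c")
  expect_equal(delta_gc3(aln2, fg),
               mean(g[fg]) - mean(g[setdiff(letters[1:6], fg)]))
  # swap property
  expect_equal(delta_gc3(aln2, fg),
               -delta_gc3(aln2, setdiff(letters[1:6], fg)))
  expect_error(delta_gc3(aln2, letters[1:6]), "proper subset")
  expect_error(delta_gc3(aln2, character(0)), "nonempty")
})
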