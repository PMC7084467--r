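test_that("identical sequences align gap-free at 100% identity", {
  s <- strrep("MACDEFGHIK", 10)
  aln <- global_align(s, s)
  expect_equal(aln$identity, 100)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
})

test_that("ten substitutions in a 100-residue pair give identity 90", {
  set.seed(5)
  a <- paste(sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X"),
                    100, replace = TRUE), collapse = "")
  bv <- strsplit(a, "")[[1]]
  pos <- sample(100, 10)
  for (p in pos) {
    bv[p] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], bv[p]), 1)
  }
  b <- paste(bv, collapse = "")
  aln <- global_align(a, b)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
  expect_false(grepl("-", aln$aligned_b, fixed = TRUE))
  expect_equal(aln$identity, 90)
})

test_that("terminal gap counts against identity (ACDE vs ACD)", {
  aln <- global_align("ACDE", "ACD")
  expect_equal(nchar(aln$aligned_a), 4)
  expect_equal(aln$identity, 75)
})

test_that("empty or invalid sequences are rejected", {
  expect_error(global_align("", "MACDE"), "empty")
  expect_error(global_align("MAC1E", "MACDE"), "non-amino-acid")
  expect_error(global_align("MACZE", "MACDE"), "non-amino-acid")
})

test_that("alignment score matches exhaustive recursion on short pairs", {
  set.seed(11)
  sc <- alignment_scoring()
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (rep in 1:40) {
    na <- sample(1:8, 1)
    nb <- sample(1:8, 1)
    a <- paste(sample(aas, na, replace = TRUE), collapse = "")
    b <- paste(sample(aas, nb, replace = TRUE), collapse = "")
    got <- global_align(a, b, sc)$score
    want <- oracle_align_score(a, b, sc$sub, sc$gap_open, sc$gap_ext)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("alignment score agrees with Biostrings on longer pairs", {
  set.seed(12)
  sc <- alignment_scoring()
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aas, 45, replace = TRUE), collapse = "")
    b <- mutate_protein(a, 12)
    got <- global_align(a, b, sc)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sc$sub, gapOpening = sc$gap_open,
      gapExtension = sc$gap_ext, type = "global")
    expect_equal(got, Biostrings::score(ref))
  }
})

test_that("percent identity is symmetric", {
  set.seed(13)
  for (rep in 1:20) {
    a <- random_test_protein(40)
    b <- mutate_protein(a, sample(5:20, 1))
    expect_equal(global_align(a, b)$identity, global_align(b, a)$identity)
  }
})

test_that("two-sequence progressive alignment equals pairwise alignment", {
  set.seed(14)
  a <- random_test_protein(60)
  b <- mutate_protein(a, 15)
  pa <- global_align(a, b)
  ma <- msa_progressive(c(x = a, y = b))
  expect_equal(unname(ma[["x"]]), pa$aligned_a)
  expect_equal(unname(ma[["y"]]), pa$aligned_b)
})

test_that("progressive alignment of identical sequences is gap-free", {
  s <- random_test_protein(50)
  ma <- msa_progressive(c(a = s, b = s, c = s, d = s))
  expect_true(all(!grepl("-", ma, fixed = TRUE)))
  expect_equal(length(unique(ma)), 1L)
})

test_that("ungapping progressive alignment rows recovers the inputs", {
  set.seed(15)
  base <- random_test_protein(70)
  seqs <- c(a = base,
            b = mutate_protein(base, 20),
            c = substring(mutate_protein(base, 10), 1, 60),
            d = paste0(mutate_protein(base, 5), "WWHKL"),
            e = random_test_protein(55))
  ma <- msa_progressive(seqs)
  expect_equal(length(unique(nchar(ma))), 1L)
  for (nm in names(seqs)) {
    expect_equal(gsub("-", "", ma[[nm]], fixed = TRUE), unname(seqs[[nm]]))
  }
  expect_error(msa_progressive(seqs[1]), "at least 2")
})

test_that("poisson distance follows the closed form under pairwise deletion", {
  m <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAC")
  r <- poisson_distance(m, "x", "y")
  expect_equal(r$p, 0.1)
  expect_equal(r$d, -log(0.9), tolerance = 1e-10)

  same <- poisson_distance(c(a = "MKLV", b = "MKLV"), "a", "b")
  expect_equal(same$p, 0)
  expect_equal(same$d, 0)

  r2 <- poisson_distance(c(x = "A-CD", y = "A-CE"), "x", "y")
  expect_equal(r2$n_sites, 3)
  expect_equal(r2$p, 1 / 3)
  expect_equal(r2$d, -log(2 / 3), tolerance = 1e-10)

  expect_error(poisson_distance(c(x = "A-", y = "-A"), "x", "y"),
               "no ungapped column")
})

test_that("poisson correction is strictly increasing and matrix symmetric", {
  ps <- seq(0.05, 0.9, by = 0.05)
  ds <- -log(1 - ps)
  expect_true(all(diff(ds) > 0))
  expect_lt(-log(1 - 1e-9), 1e-8)

  set.seed(16)
  seqs <- c(a = random_test_protein(40), b = random_test_protein(40),
            c = random_test_protein(40))
  dm <- poisson_distance_matrix(msa_progressive(seqs))
  expect_equal(dm$d, t(dm$d))
  expect_equal(dm$identity, t(dm$identity))
  expect_equal(unname(diag(dm$d)), rep(0, 3))
})

test_that("codon back-translation follows the protein alignment", {
  out <- codon_backtranslate(c(g = "M-A"), c(g = "ATGGCT"))
  expect_equal(unname(out[["g"]]), "ATG---GCT")

  out2 <- codon_backtranslate(c(g = "MA"), c(g = "ATGGCTTAA"))
  expect_equal(unname(out2[["g"]]), "ATGGCT")

  expect_error(codon_backtranslate(c(g = "MKA"), c(g = "ATGTAAGCT")),
               "stop codon")
  expect_error(codon_backtranslate(c(g = "MA"), c(g = "ATGGC")),
               "multiple of 3")
  expect_error(codon_backtranslate(c(g = "MK"), c(g = "ATGGCT")),
               "residue 2")
  expect_error(codon_backtranslate(c(g = "MA"), c(h = "ATGGCT")), "no CDS")
})
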