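# Tandem/segmental rule boundaries, NG86 against the enumeration oracle,
# and divergence dating.

pair_fixture <- function(gap_a_b) {
  # two family genes on chr1 separated by `gap_a_b` filler genes, plus an
  # unrelated pair on different chromosomes
  pt <- data.frame(pol_id = c("D01", "D01", "E01", "E01"),
                   gene_id = c("fam1", "fam2", "fam3", "fam4"),
                   species = "Mt", group = c("D", "D", "E", "E"))
  class(pt) <- c("pol_table", "data.frame")
  n_fill <- gap_a_b
  ord <- data.frame(
    gene_id = c("fam1", sprintf("fill%02d", seq_len(n_fill)), "fam2",
                "fam3", "fam4"),
    chrom = c(rep("chr1", n_fill + 2), "chr2", "chr3"),
    start = c(seq_len(n_fill + 2) * 1000, 500, 500))
  list(pols = pt, ord = ord)
}

test_that("four intervening genes is tandem, five is segmental", {
  f4 <- pair_fixture(4)
  p4 <- find_duplicate_pairs(f4$pols, f4$ord)
  expect_equal(p4$intervening[p4$gene_a == "fam1"], 4L)
  expect_equal(p4$mode[p4$gene_a == "fam1"], "tandem")

  f5 <- pair_fixture(5)
  p5 <- find_duplicate_pairs(f5$pols, f5$ord)
  expect_equal(p5$intervening[p5$gene_a == "fam1"], 5L)
  expect_equal(p5$mode[p5$gene_a == "fam1"], "segmental")

  f0 <- pair_fixture(0)
  p0 <- find_duplicate_pairs(f0$pols, f0$ord)
  expect_equal(p0$intervening[p0$gene_a == "fam1"], 0L)
  expect_equal(p0$mode[p0$gene_a == "fam1"], "tandem")

  # different chromosomes can never be tandem
  expect_equal(p4$mode[p4$gene_a == "fam3"], "segmental")
  expect_true(is.na(p4$intervening[p4$gene_a == "fam3"]))
})

test_that("scaffold placements and missing coordinates are never tandem", {
  pt <- data.frame(pol_id = c("D01", "D01"), gene_id = c("s1", "s2"),
                   species = "Mt", group = "D")
  class(pt) <- c("pol_table", "data.frame")
  ord <- data.frame(gene_id = c("s1", "s2"),
                    chrom = "scaffold_17", start = c(100, 200))
  p <- find_duplicate_pairs(pt, ord)
  expect_equal(p$mode, "segmental")

  ord2 <- data.frame(gene_id = "s1", chrom = "chr1", start = 100)
  expect_warning(p2 <- find_duplicate_pairs(pt, ord2), "missing")
  expect_equal(p2$mode, "segmental")
  expect_true(p2$coord_missing)
})

test_that("gene labels use tandem-over-segmental precedence", {
  pt <- data.frame(pol_id = rep("D01", 4),
                   gene_id = c("t1", "t2", "t3", "far"),
                   species = "Mt", group = "D")
  class(pt) <- c("pol_table", "data.frame")
  # t1-t2-t3 adjacent on chr1; far sits on chr2; lone gene in another POL
  pt2 <- rbind(pt, data.frame(pol_id = "E01", gene_id = "solo",
                              species = "Mt", group = "E"))
  class(pt2) <- c("pol_table", "data.frame")
  ord <- data.frame(gene_id = c("t1", "t2", "t3", "far", "solo"),
                    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                    start = c(1000, 2000, 3000, 100, 100))
  pairs <- find_duplicate_pairs(pt2, ord)
  lab <- gene_duplication_labels(pairs, pt2)
  expect_equal(unname(lab[c("t1", "t2", "t3")]), rep("tandem", 3))
  expect_equal(unname(lab[["far"]]), "segmental")  # has only cross-chr pairs
  expect_equal(unname(lab[["solo"]]), "none")
})

test_that("NG86 handles the single-synonymous-difference worked example", {
  a <- strrep("TTT", 9)
  b <- paste0(strrep("TTT", 8), "TTC")
  r <- ng86(a, b)
  expect_equal(r$S, 3)
  expect_equal(r$N, 24)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 1 / 3)
  expect_equal(r$dS, -0.75 * log(1 - 4 / 9), tolerance = 1e-9)
  expect_true(r$valid)

  same <- ng86(a, a)
  expect_equal(same$Sd, 0)
  expect_equal(same$dS, 0)
  expect_equal(same$dN, 0)
})

test_that("NG86 validates its input", {
  expect_error(ng86("ATGAA", "ATGAA"), "multiple of 3")
  expect_error(ng86("ATGTAA", "ATGAAA"), "stop")
  expect_error(ng86("ATG---", "ATGAAA"), "gapped")
  expect_error(ng86("ATGAAA", "ATG"), "length")
})

test_that("NG86 is symmetric and conserves sites and differences", {
  set.seed(61)
  for (rep in 1:25) {
    a <- random_test_cds(20)
    b <- mutate_cds(a, sample(1:6, 1))
    ra <- ng86(a, b)
    rb <- ng86(b, a)
    expect_equal(ra$S, rb$S)
    expect_equal(ra$Sd, rb$Sd)
    expect_equal(ra$dS, rb$dS)
    expect_equal(ra$S + ra$N, 3 * ra$n_codons)
    # Sd + Nd equals the pathway-averaged total difference count
    ca <- famtrace:::split_codons(a)
    cb <- famtrace:::split_codons(b)
    ndiff <- sum(mapply(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, ca, cb))
    expect_equal(ra$Sd + ra$Nd, ndiff)
  }
})

test_that("NG86 agrees with the enumeration oracle on random pairs", {
  set.seed(62)
  for (rep in 1:50) {
    a <- random_test_cds(sample(5:30, 1))
    b <- mutate_cds(a, sample(0:8, 1))
    got <- ng86(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$dS, want$dS, tolerance = 1e-12)
    expect_equal(got$dN, want$dN, tolerance = 1e-12)
  }
})

test_that("divergence dating follows T = dS/(2 lambda) * 1e-6", {
  expect_equal(divergence_time(0, 1e-8), 0)
  expect_equal(divergence_time(1.2528, 1.08e-8), 58, tolerance = 1e-12)
  expect_equal(divergence_time(0.1521, 5.85e-9), 13, tolerance = 1e-12)
  expect_true(is.na(divergence_time(NA, 1e-8)))
  expect_error(divergence_time(0.5, 0), "lambda")
})

test_that("date_duplications aligns, backtranslates and dates pairs", {
  set.seed(63)
  cds1 <- random_test_cds(60)
  cds2 <- mutate_cds(cds1, 12)
  genes <- data.frame(
    gene_id = c("a", "b"),
    protein = c(famtrace:::translate_cds(cds1), famtrace:::translate_cds(cds2)),
    cds = c(cds1, cds2))
  pairs <- data.frame(pol_id = "D01", species = "Mt", gene_a = "a",
                      gene_b = "b", chrom_a = "chr1", chrom_b = "chr1",
                      intervening = 0L, mode = "tandem",
                      coord_missing = FALSE)
  out <- date_duplications(pairs, genes, c(Mt = 1.08e-8))
  expect_true(out$valid)
  expect_equal(out$T_my, out$dS / (2 * 1.08e-8) * 1e-6)
  oracle <- oracle_ng86(cds1, cds2)
  expect_equal(out$dS, oracle$dS, tolerance = 1e-12)
})
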