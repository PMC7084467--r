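# Handcrafted trees and identity matrices for the POL clustering gates.

make_identity <- function(ids, fill) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  m
}

test_that("two well-separated clades become two POLs", {
  tr <- ape::read.tree(text = paste0(
    "(((a1:.1,a2:.1):.1,(a3:.1,(a4:.1,a5:.1):.1):.1):1,",
    "((b1:.1,b2:.1):.1,(b3:.1,(b4:.1,b5:.1):.1):.1):1,out:3);"))
  ids <- c(paste0("a", 1:5), paste0("b", 1:5))
  idm <- make_identity(c(ids, "out"), 40)
  idm[paste0("a", 1:5), paste0("a", 1:5)] <- 88
  idm[paste0("b", 1:5), paste0("b", 1:5)] <- 90
  diag(idm) <- 100
  groups <- setNames(rep("D", 10), ids)
  cl <- assign_pols(tr, idm, groups)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[cl$gene_id %in% paste0("a", 1:5)])), 1L)
  expect_equal(length(unique(cl$cluster[cl$gene_id %in% paste0("b", 1:5)])), 1L)
})

test_that("identical genes form one POL per group", {
  tr <- ape::read.tree(text = "((x1:.1,x2:.1):.1,(y1:.1,y2:.1):.1,out:1);")
  ids <- c("x1", "x2", "y1", "y2")
  idm <- make_identity(c(ids, "out"), 100)
  groups <- setNames(c("A", "A", "E", "E"), ids)
  cl <- assign_pols(tr, idm, groups)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[cl$group == "A"])), 1L)
})

test_that("a gene below the identity gates stays a singleton POL", {
  tr <- ape::read.tree(text = "((a1:.1,a2:.1):.1,lone:2,out:2);")
  idm <- make_identity(c("a1", "a2", "lone", "out"), 30)
  idm["a1", "a2"] <- idm["a2", "a1"] <- 85
  groups <- setNames(rep("D", 3), c("a1", "a2", "lone"))
  cl <- assign_pols(tr, idm, groups)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_false(cl$cluster[cl$gene_id == "lone"] %in%
                 cl$cluster[cl$gene_id != "lone"])
})

test_that("the bootstrap gate blocks merges across weak edges", {
  tr <- ape::read.tree(
    text = "(((a1:.1,a2:.1):.5,(a3:.1,a4:.1):.5):.5,out1:2,out2:2);")
  ids <- paste0("a", 1:4)
  idm <- make_identity(c(ids, "out1", "out2"), 80)
  groups <- setNames(rep("D", 4), ids)
  # cherries well supported; the four-gene clade's own edge is weak
  ref <- sort(tr$tip.label)[1]
  sup <- c(90, 90, 10)
  names(sup) <- c(famtrace:::split_key(c("a1", "a2"), tr$tip.label, ref),
                  famtrace:::split_key(c("a3", "a4"), tr$tip.label, ref),
                  famtrace:::split_key(ids, tr$tip.label, ref))
  attr(tr, "split_support") <- sup
  cl <- assign_pols(tr, idm, groups, pol_config(min_support = 50))
  expect_equal(length(unique(cl$cluster)), 2L)
  # dropping the gate lets the full clade survive as one POL
  cl2 <- assign_pols(tr, idm, groups, pol_config(min_support = 0))
  expect_equal(length(unique(cl2$cluster)), 1L)
})

test_that("raising theta_min never decreases the number of POLs", {
  set.seed(41)
  tr <- ape::read.tree(text = paste0(
    "(((a1:.1,a2:.1):.1,(a3:.1,a4:.1):.1):1,out:2);"))
  ids <- paste0("a", 1:4)
  idm <- make_identity(c(ids, "out"), 0)
  idm[ids, ids] <- 62
  idm["a1", "a2"] <- idm["a2", "a1"] <- 90
  idm["a3", "a4"] <- idm["a4", "a3"] <- 90
  diag(idm) <- 100
  groups <- setNames(rep("D", 4), ids)
  n_pols <- vapply(c(0, 55, 70, 95), function(th) {
    cl <- assign_pols(tr, idm, groups,
                      pol_config(theta_min = th, theta_mean = max(th, 60)))
    length(unique(cl$cluster))
  }, integer(1))
  expect_true(all(diff(n_pols) >= 0))
})

test_that("POL assignment partitions the genes and is deterministic", {
  tr <- ape::read.tree(text = paste0(
    "(((a1:.1,a2:.1):.1,(a3:.1,a4:.1):.1):1,(b1:.1,b2:.1):1,out:2);"))
  ids <- c(paste0("a", 1:4), "b1", "b2")
  idm <- make_identity(c(ids, "out"), 70)
  groups <- setNames(c(rep("D", 4), "E", "E"), ids)
  cl1 <- assign_pols(tr, idm, groups)
  cl2 <- assign_pols(tr, idm, groups)
  expect_identical(cl1, cl2)
  expect_setequal(cl1$gene_id, ids)
  expect_equal(nrow(cl1), length(ids))
  expect_error(assign_pols(tr, idm[1:3, 1:3], groups), "missing from")
})

test_that("POLs are named by the priority species' coordinates", {
  clusters <- data.frame(
    gene_id = c("m1", "m2", "m3", "g1", "g2"),
    group = "D",
    cluster = c("c1", "c2", "c3", "c1", "c3"))
  genes <- data.frame(
    gene_id = c("m1", "m2", "m3", "g1", "g2"),
    species = c("Mt", "Mt", "Mt", "Gm", "Gm"),
    chrom = c("Ch1", "Ch1", "Ch2", "Ch9", "Ch9"),
    start = c(900, 100, 50, 1, 2))
  pt <- name_pols(clusters, genes, c("Mt", "Gm"))
  pol_of <- setNames(pt$pol_id, pt$gene_id)
  # order: m2 (Ch1:100) < m1 (Ch1:900) < m3 (Ch2:50)
  expect_equal(unname(pol_of[c("m2", "m1", "m3")]), c("D01", "D02", "D03"))
  expect_equal(unname(pol_of[["g1"]]), "D02")  # rides with m1 via c1

  # a POL without priority-species members falls back to the next species
  clusters2 <- data.frame(gene_id = c("g9", "m9"), group = "L",
                          cluster = c("cA", "cB"))
  genes2 <- data.frame(gene_id = c("g9", "m9"), species = c("Gm", "Mt"),
                       chrom = c("Ch1", "Ch5"), start = c(10, 99))
  pt2 <- name_pols(clusters2, genes2, c("Mt", "Gm"))
  expect_equal(pt2$pol_id[pt2$gene_id == "m9"], "L01")
  expect_equal(pt2$pol_id[pt2$gene_id == "g9"], "L02")

  # single POL in a group gets index 01
  one <- name_pols(data.frame(gene_id = "z", group = "R", cluster = "c"),
                   data.frame(gene_id = "z", species = "Mt", chrom = "Ch1",
                              start = 5), "Mt")
  expect_equal(one$pol_id, "R01")
})

test_that("copy-number classes follow the count", {
  pt <- data.frame(
    pol_id = c("D01", "D01", "D01", "D01", "D02", "D02", "D02"),
    gene_id = sprintf("g%d", 1:7),
    species = c("Mt", "Mt", "Mt", "Gm", "Mt", "Gm", "Gm"),
    group = "D")
  class(pt) <- c("pol_table", "data.frame")
  cn <- copy_number_classes(pt, species = c("Mt", "Gm", "Lj"))
  lk <- function(p, s) cn$class[cn$pol_id == p & cn$species == s]
  expect_equal(lk("D01", "Mt"), "multi")
  expect_equal(lk("D01", "Gm"), "single")
  expect_equal(lk("D01", "Lj"), "absent")
  expect_equal(lk("D02", "Gm"), "double")
})

test_that("simulated POLs recover the true loci (ARI >= 0.9)", {
  res <- run_all(sim_config(n_ancestral_loci = 12, seed = 55,
                            filler_genes_per_chromosome = 10),
                 out_dir = NULL, seed = 55, n_boot = 40)
  ari <- res$metrics$value[res$metrics$metric == "pol_ari"]
  expect_gte(ari, 0.9)
})
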