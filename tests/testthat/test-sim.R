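# Simulator limits, ground-truth consistency and calibration.

three_sp <- function(...) {
  sim_config(species_tree = "((A:10,B:10):5,C:15);",
             lambda_per_species = c(A = 1e-8, B = 1e-8, C = 1e-8),
             n_ancestral_loci = 10, chromosomes_per_species = 3,
             filler_genes_per_chromosome = 10,
             tandem_rate = 0, segmental_rate = 0, loss_rate = 0,
             intron_gain_rate = 0, intron_loss_rate = 0,
             wgd_branches = list(), seed = 7, ...)
}

test_that("with all event rates zero every species carries one gene per locus", {
  sim <- simulate_family(three_sp())
  expect_equal(as.integer(table(sim$genes$species)), rep(10L, 3))
  tg <- sim$truth$genes
  locus_of <- setNames(tg$locus, tg$gene_id)
  per <- table(sim$genes$species, locus_of[sim$genes$gene_id])
  expect_true(all(per == 1))
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("lambda zero freezes all sequences within a locus", {
  cfg <- three_sp()
  cfg$lambda_per_species[] <- 0
  sim <- simulate_family(cfg)
  locus_of <- setNames(sim$truth$genes$locus, sim$truth$genes$gene_id)
  by_locus <- split(sim$genes$protein, locus_of[sim$genes$gene_id])
  expect_true(all(vapply(by_locus, function(x) length(unique(x)) == 1,
                         logical(1))))
  # and cross-species identity within a locus is exactly 100
  one <- by_locus[[1]]
  expect_equal(global_align(one[1], one[2])$identity, 100)
})

test_that("a terminal-branch WGD doubles the gene count relative to the sister", {
  cfg <- three_sp()
  cfg$wgd_branches <- list(list(branch = "A", time = 5))
  sim <- simulate_family(cfg)
  counts <- table(sim$genes$species)
  expect_equal(unname(counts[["A"]]), 2 * unname(counts[["B"]]))
  expect_equal(sum(sim$truth$events$event == "wgd_dup"), 10)
})

test_that("outputs are byte-identical for the same seed", {
  cfg <- sim_config(n_ancestral_loci = 6, seed = 19,
                    filler_genes_per_chromosome = 5)
  d1 <- file.path(tempdir(), "sim_rep1")
  d2 <- file.path(tempdir(), "sim_rep2")
  s1 <- simulate_family(cfg)
  write_simulation(s1, d1, make_decoys(cfg, s1$genes))
  s2 <- simulate_family(cfg)
  write_simulation(s2, d2, make_decoys(cfg, s2$genes))
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("invalid species trees are rejected", {
  cfg <- three_sp()
  cfg$species_tree <- "((A:10,B:9):5,C:15);"
  expect_error(simulate_family(cfg), "ultrametric")
  cfg$species_tree <- "();"
  expect_error(simulate_family(cfg), "")
  cfg2 <- three_sp()
  cfg2$lambda_per_species <- c(A = 1e-8, B = 1e-8)
  expect_error(simulate_family(cfg2), "lambda")
})

test_that("event log counts match the gene-to-locus map", {
  cfg <- sim_config(n_ancestral_loci = 10, seed = 23,
                    tandem_rate = 0.02, segmental_rate = 0.01,
                    loss_rate = 0.005, filler_genes_per_chromosome = 8)
  sim <- simulate_family(cfg)
  tg <- sim$truth$genes
  locus_of <- setNames(tg$locus, tg$gene_id)
  # every emitted gene maps to exactly one known locus
  expect_true(all(sim$genes$gene_id %in% tg$gene_id))
  expect_false(any(is.na(locus_of[sim$genes$gene_id])))
  # genes per species per locus implied by the event log: births along the
  # lineage minus losses; cross-check the no-duplication loci
  ev <- sim$truth$events
  dup_loci <- unique(locus_of[ev$new_gene[grepl("_dup$", ev$event)]])
  lost <- ev$gene[ev$event == "loss"]
  quiet <- setdiff(sim$truth$loci$locus_id, dup_loci)
  per <- table(factor(locus_of[sim$genes$gene_id],
                      levels = sim$truth$loci$locus_id),
               sim$genes$species)
  for (L in quiet) {
    expect_true(all(per[L, ] <= 1))
  }
  # a species count above one requires at least one duplication in that locus
  over <- rownames(per)[apply(per, 1, max) > 1]
  expect_true(all(over %in% dup_loci))
})

test_that("tandem placements sit within four intervening genes", {
  cfg <- sim_config(n_ancestral_loci = 10, seed = 29, tandem_rate = 0.03,
                    segmental_rate = 0, loss_rate = 0,
                    filler_genes_per_chromosome = 10)
  sim <- simulate_family(cfg)
  ord <- rbind(sim$genes[, c("gene_id", "species", "chrom", "start")],
               sim$fillers[, c("gene_id", "species", "chrom", "start")])
  ord$key <- paste(ord$species, ord$chrom)
  rank <- unlist(lapply(split(seq_len(nrow(ord)), ord$key), function(ix) {
    setNames(rank(ord$start[ix]), ord$gene_id[ix])
  }))
  names(rank) <- unlist(lapply(split(ord$gene_id, ord$key), identity))
  chrom_of <- setNames(paste(ord$species, ord$chrom), ord$gene_id)
  ev <- sim$truth$events
  checked <- 0
  for (i in which(ev$event == "tandem_dup")) {
    a <- ev$gene[i]
    b <- ev$new_gene[i]
    if (!(a %in% sim$genes$gene_id && b %in% sim$genes$gene_id)) next
    expect_equal(unname(chrom_of[a]), unname(chrom_of[b]))
    expect_lte(abs(rank[[a]] - rank[[b]]) - 1, 4)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("realized dS matches 2 * lambda * dT within Monte-Carlo error", {
  # two species, high tandem rate, no other events: planted pair ages are
  # known and dS should average 2 * lambda * age * 1e6
  cfg <- sim_config(species_tree = "(A:30,B:30);",
                    lambda_per_species = c(A = 1e-8, B = 1e-8),
                    n_ancestral_loci = 50, chromosomes_per_species = 3,
                    filler_genes_per_chromosome = 5,
                    tandem_rate = 0.03, segmental_rate = 0, loss_rate = 0,
                    intron_gain_rate = 0, intron_loss_rate = 0,
                    wgd_branches = list(), seed = 31)
  sim <- simulate_family(cfg)
  ev <- sim$truth$events
  ratios <- c()
  genes <- setNames(seq_len(nrow(sim$genes)), sim$genes$gene_id)
  for (i in which(ev$event == "tandem_dup")) {
    a <- ev$gene[i]
    b <- ev$new_gene[i]
    if (!(a %in% names(genes) && b %in% names(genes))) next
    info <- truth_pair_event(sim$truth, a, b)
    if (is.null(info) || info$n_dups_below != 1 || info$time_mya < 3) next
    cds_a <- sub("TAA$", "", sim$genes$cds[genes[[a]]])
    cds_b <- sub("TAA$", "", sim$genes$cds[genes[[b]]])
    r <- ng86(cds_a, cds_b)
    if (!r$valid) next
    ratios <- c(ratios, r$dS / (2 * 1e-8 * info$time_mya * 1e6))
  }
  expect_gte(length(ratios), 50)
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("decoys each violate exactly their planted rule", {
  cfg <- sim_config(n_ancestral_loci = 5, seed = 37,
                    filler_genes_per_chromosome = 5,
                    decoy_counts = c(short = 3, long = 2, non_met_start = 3,
                                     incomplete_motif = 2,
                                     duplicate_identical = 1))
  sim <- simulate_family(cfg)
  dec <- make_decoys(cfg, sim$genes)
  expect_equal(sum(dec$decoy_class == "non_met_start"), 3)
  expect_true(all(substring(dec$protein[dec$decoy_class == "non_met_start"],
                            1, 1) != "M"))
  expect_true(all(nchar(dec$protein[dec$decoy_class == "short"]) <= 349))
  expect_true(all(nchar(dec$protein[dec$decoy_class == "long"]) >= 601))
  dupd <- dec[dec$decoy_class == "duplicate_identical", ]
  src <- sim$genes[sim$genes$species == dupd$species, ]
  expect_true(dupd$protein %in% src$protein)
  expect_true(all(dupd$gene_id > src$gene_id[src$protein == dupd$protein]))
  for (cls in c("short", "long", "duplicate_identical")) {
    sub <- dec[dec$decoy_class == cls, ]
    for (k in seq_len(nrow(sub))) {
      expect_true(motif_scan(sub$protein[k], cfg$motif)$pass ||
                    nchar(sub$protein[k]) < 88, info = cls)
    }
  }
  expect_false(any(vapply(dec$protein[dec$decoy_class == "incomplete_motif"],
                          function(p) motif_scan(p, cfg$motif)$pass,
                          logical(1))))
})
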