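# End-to-end orchestration: simulate -> screen -> align -> tree -> groups
# -> POLs -> introns -> duplications -> summaries -> recovery metrics, with
# one config and one seed, writing deterministic TSV/FASTA/Newick outputs.

#' Run the full pipeline on a simulated family
#'
#' Executes every stage with a single seed and writes all inputs and
#' results under `out_dir`. Outputs are byte-identical across runs with
#' the same config and seed.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created; pass `NULL` to skip writing)
#' @param seed integer; overrides `config$seed` and drives the bootstrap
#' @param n_boot bootstrap replicates for the gene tree (default 100 for
#'   desk-scale runs; the conventional full analysis uses 1000)
#' @param pol_cfg a [pol_config()]
#' @param screen_cfg a [screen_config()]; defaults to the simulator motif
#' @return invisible list with all intermediate and final objects:
#'   `sim`, `decoys`, `screen`, `msa`, `dist`, `tree`, `groups`, `pols`,
#'   `copy_number`, `introns`, `pairs`, `dup_labels`, `summary`, `metrics`
#' @export
run_all <- function(config = sim_config(), out_dir = NULL, seed = config$seed,
                    n_boot = 100, pol_cfg = pol_config(),
                    screen_cfg = NULL) {
  t_start <- proc.time()[["elapsed"]]
  stage <- function(msg) {
    message(sprintf("[famtrace %7.1fs] %s",
                    proc.time()[["elapsed"]] - t_start, msg))
  }
  config$seed <- seed
  if (is.null(screen_cfg)) {
    screen_cfg <- screen_config(motif_consensus = config$motif)
  }

  stage("simulating family")
  sim <- simulate_family(config)
  decoys <- make_decoys(config, sim$genes)
  if (!is.null(out_dir)) write_simulation(sim, out_dir, decoys)

  stage(sprintf("screening %d candidates",
                nrow(sim$genes) + nrow(decoys)))
  candidates <- rbind(sim$genes[, c("gene_id", "species", "protein")],
                      decoys[, c("gene_id", "species", "protein")])
  screen <- screen_candidates(candidates, screen_cfg)
  kept <- sim$genes[sim$genes$gene_id %in% screen$kept$gene_id, ]

  stage(sprintf("aligning %d kept genes + %d anchors",
                nrow(kept), nrow(sim$anchors)))
  seqs <- c(setNames(kept$protein, kept$gene_id),
            setNames(sim$anchors$protein, sim$anchors$anchor_id))
  msa <- msa_progressive(seqs)
  dmat <- poisson_distance_matrix(msa)

  stage(sprintf("NJ tree with %d bootstrap replicates", n_boot))
  boot_seed <- (as.integer(seed) %% 1000000000L) + 1L
  tree <- bootstrap_supports(msa, n_reps = n_boot, seed = boot_seed)

  stage("assigning groups and POLs")
  groups <- assign_groups(tree, sim$anchors, dmat$identity)
  clusters <- assign_pols(tree, dmat$identity, groups, pol_cfg)
  priority <- pol_cfg$species_priority %||% names(config$lambda_per_species)
  pols <- name_pols(clusters, kept, priority)
  cn <- copy_number_classes(pols, species = sim$species_tree$tip.label)

  introns <- intron_calls(pols, setNames(kept$introns, kept$gene_id))

  stage("duplication analysis")
  gene_order <- rbind(kept[, c("gene_id", "chrom", "start")],
                      sim$fillers[, c("gene_id", "chrom", "start")])
  gene_order$chrom <- paste(c(kept$species, sim$fillers$species),
                            gene_order$chrom, sep = "_")
  pairs <- find_duplicate_pairs(pols, gene_order)
  labels <- gene_duplication_labels(pairs, pols)
  dated <- date_duplications(pairs, kept, config$lambda_per_species)

  tables <- summarize_family(pols, introns, labels,
                             gene_order[gene_order$gene_id %in% pols$gene_id, ])
  metrics <- recovery_metrics(pols, dated, introns, sim$truth)
  stage("done")

  if (!is.null(out_dir)) {
    aln <- Biostrings::AAStringSet(msa)
    Biostrings::writeXStringSet(aln, file.path(out_dir, "alignment.afa"))
    ape::write.tree(tree, file.path(out_dir, "gene_tree.nwk"))
    write_tsv(screen$exclusions, file.path(out_dir, "exclusions.tsv"))
    write_tsv(data.frame(gene_id = names(groups), group = unname(groups)),
              file.path(out_dir, "groups.tsv"))
    write_tsv(as.data.frame(pols), file.path(out_dir, "pols.tsv"))
    write_tsv(cn, file.path(out_dir, "pol_copy_number.tsv"))
    write_tsv(introns, file.path(out_dir, "intron_calls.tsv"))
    write_tsv(dated, file.path(out_dir, "dup_events.tsv"))
    write_tsv(data.frame(gene_id = names(labels), label = unname(labels)),
              file.path(out_dir, "dup_labels.tsv"))
    write_summary(tables, out_dir)
    write_tsv(metrics, file.path(out_dir, "recovery_metrics.tsv"))
  }

  invisible(list(sim = sim, decoys = decoys, screen = screen, msa = msa,
                 dist = dmat, tree = tree, groups = groups, pols = pols,
                 copy_number = cn, introns = introns, pairs = dated,
                 dup_labels = labels, summary = tables, metrics = metrics))
}
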