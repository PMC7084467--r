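# Summary tables in the shape conventional for gene-family surveys
# (group-by-species POL counts with member counts in brackets, intron and
# duplication statistics with percentages), and recovery metrics against
# simulator ground truth.

#' Summary tables for a family analysis
#'
#' Percentages are rounded half-up to one decimal and always equal their
#' printed numerator/denominator. Inputs must cover exactly the same gene
#' universe; a mismatch is an error listing the symmetric difference.
#'
#' @param pols a `pol_table` from [name_pols()]
#' @param introns intron call table from [intron_calls()]
#' @param dup_labels named vector from [gene_duplication_labels()]
#' @param gene_coords data.frame `gene_id`, `chrom` (for the per-chromosome
#'   tally; may cover more genes than the family)
#' @return list of class `fam_summary` with data.frames `pol_counts`,
#'   `intron_stats`, `dup_stats`, `chrom_tally`
#' @export
summarize_family <- function(pols, introns, dup_labels, gene_coords = NULL) {
  universe <- sort(pols$gene_id)
  for (other in list(sort(introns$gene_id), sort(names(dup_labels)))) {
    if (!identical(universe, other)) {
      diffs <- c(setdiff(universe, other), setdiff(other, universe))
      stop("inconsistent gene universes across inputs: ",
           paste(head(diffs, 10), collapse = ", "))
    }
  }
  species <- sort(unique(pols$species))

  # group x species POL counts, members in brackets
  groups <- sort(unique(pols$group))
  pol_counts <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (sp in species) {
    cell <- vapply(groups, function(g) {
      sub <- pols[pols$group == g & pols$species == sp, ]
      if (nrow(sub) == 0) return("-")
      sprintf("%02d (%02d)", length(unique(sub$pol_id)), nrow(sub))
    }, character(1))
    pol_counts[[sp]] <- cell
  }
  pol_counts$total_pols <- vapply(groups, function(g) {
    length(unique(pols$pol_id[pols$group == g]))
  }, integer(1))
  total_row <- data.frame(group = "Total", stringsAsFactors = FALSE)
  for (sp in species) {
    sub <- pols[pols$species == sp, ]
    total_row[[sp] ] <- sprintf("%02d (%02d)", length(unique(sub$pol_id)),
                                nrow(sub))
  }
  total_row$total_pols <- length(unique(pols$pol_id))
  pol_counts <- rbind(pol_counts, total_row)

  intron_stats <- do.call(rbind, lapply(species, function(sp) {
    sub <- introns[introns$species == sp, ]
    n <- nrow(sub)
    n0 <- sum(sub$introns == 0)
    nwith <- n - n0
    n1 <- sum(sub$introns == 1)
    ngain <- sum(sub$event == "gained")
    nlost <- sum(sub$event == "lost")
    data.frame(species = sp, n_genes = n,
               n_no_intron = n0,
               pct_no_intron = round_half_up(100 * n0 / max(n, 1)),
               n_with_intron = nwith,
               n_one_intron = n1,
               pct_one_among_with = round_half_up(100 * n1 / max(nwith, 1)),
               n_gained = ngain, n_lost = nlost,
               stringsAsFactors = FALSE)
  }))

  sp_of <- setNames(pols$species, pols$gene_id)
  dup_stats <- do.call(rbind, lapply(species, function(sp) {
    lab <- dup_labels[names(dup_labels)[sp_of[names(dup_labels)] == sp]]
    n <- length(lab)
    nt <- sum(lab == "tandem")
    ns <- sum(lab == "segmental")
    data.frame(species = sp, n_genes = n,
               n_tandem = nt,
               pct_tandem = round_half_up(100 * nt / max(n, 1)),
               n_segmental = ns,
               pct_segmental = round_half_up(100 * ns / max(n, 1)),
               n_none = n - nt - ns,
               pct_none = round_half_up(100 * (n - nt - ns) / max(n, 1)),
               stringsAsFactors = FALSE)
  }))

  chrom_tally <- NULL
  if (!is.null(gene_coords)) {
    fam <- gene_coords[gene_coords$gene_id %in% universe, ]
    fam$species <- sp_of[fam$gene_id]
    tab <- as.data.frame(table(species = fam$species, chrom = fam$chrom),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n_genes"
    chrom_tally <- tab[tab$n_genes > 0, ]
    chrom_tally <- chrom_tally[order(chrom_tally$species, chrom_tally$chrom), ]
    rownames(chrom_tally) <- NULL
  }
  structure(list(pol_counts = pol_counts, intron_stats = intron_stats,
                 dup_stats = dup_stats, chrom_tally = chrom_tally),
            class = "fam_summary")
}

#' Write summary tables to TSV
#'
#' @param x a `fam_summary`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_summary <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(x$pol_counts, file.path(dir, "summary_pol_counts.tsv"))
  write_tsv(x$intron_stats, file.path(dir, "summary_intron_stats.tsv"))
  write_tsv(x$dup_stats, file.path(dir, "summary_dup_stats.tsv"))
  if (!is.null(x$chrom_tally)) {
    write_tsv(x$chrom_tally, file.path(dir, "summary_chrom_tally.tsv"))
  }
  invisible(dir)
}

#' Locate the duplication event separating two same-species genes
#'
#' Walks the truth genealogy of both genes to their most recent common
#' ancestral gene; the lineages separate at the older of the two birth
#' events immediately below it that is a duplication. Returns its mode and
#' age.
#'
#' @param truth a `sim_truth`
#' @param a,b gene ids
#' @return list with `mode` (`tandem`, `segmental` or `wgd`), `time_mya`
#'   and `n_dups_below` (duplication events on the two lineages below the
#'   common ancestor; 1 means the pair directly witnesses one planted
#'   event), or `NULL` if the genes never diverged by duplication
#' @export
truth_pair_event <- function(truth, a, b) {
  tg <- truth$genes
  parent <- setNames(tg$parent_gene, tg$gene_id)
  event <- setNames(tg$birth_event, tg$gene_id)
  btime <- setNames(tg$birth_time_mya, tg$gene_id)
  chain <- function(g) {
    out <- g
    while (!is.na(parent[[g]])) {
      g <- parent[[g]]
      out <- c(out, g)
    }
    out
  }
  ca <- chain(a)
  cb <- chain(b)
  common <- ca[ca %in% cb][1]
  if (is.na(common)) return(NULL)
  below_a <- ca[seq_len(match(common, ca) - 1)]
  below_b <- cb[seq_len(match(common, cb) - 1)]
  xa <- if (common == a) NULL else ca[match(common, ca) - 1]
  xb <- if (common == b) NULL else cb[match(common, cb) - 1]
  cand <- c(xa, xb)
  if (length(cand) == 0) return(NULL)
  is_dup <- grepl("_dup$", event[cand])
  cand <- cand[is_dup]
  if (length(cand) == 0) return(NULL)
  pick <- cand[which.max(btime[cand])]
  n_dups <- sum(grepl("_dup$", event[c(below_a, below_b)]))
  list(mode = sub("_dup$", "", event[[pick]]), time_mya = btime[[pick]],
       n_dups_below = n_dups)
}

#' Recovery metrics against simulator ground truth
#'
#' Compares an inferred analysis with the planted history: Adjusted Rand
#' Index (ARI) between the POL partition and the true-locus partition;
#' accuracy of tandem/segmental pair classification (true WGD copies count
#' as segmental, since a whole-genome duplicate lands on another
#' chromosome); recall of planted intron gains in ancestrally intron-free
#' loci; and the median relative error of estimated duplication times for
#' pairs with valid dS <= `max_ds`.
#'
#' @param pols a `pol_table`
#' @param dated_pairs output of [date_duplications()]
#' @param introns intron call table from [intron_calls()]
#' @param truth a `sim_truth` from [simulate_family()]
#' @param max_ds dS ceiling for the dating-error metric (default 0.5)
#' @return data.frame `metric`, `value`, `n`
#' @export
recovery_metrics <- function(pols, dated_pairs, introns, truth,
                             max_ds = 0.5) {
  locus_of <- setNames(truth$genes$locus, truth$genes$gene_id)
  common <- intersect(pols$gene_id, names(locus_of))
  if (length(common) == 0) stop("gene universes of inference and truth are disjoint")
  ari <- mclust::adjustedRandIndex(
    pols$pol_id[match(common, pols$gene_id)], locus_of[common])

  mode_ok <- logical(0)
  rel_err <- numeric(0)
  for (i in seq_len(nrow(dated_pairs))) {
    ev <- truth_pair_event(truth, dated_pairs$gene_a[i], dated_pairs$gene_b[i])
    if (is.null(ev)) next
    if (ev$n_dups_below == 1) {
      # only pairs directly witnessing one planted event carry its label;
      # composite pairs (several duplications below the split) have no
      # single planted mode
      true_mode <- if (ev$mode == "wgd") "segmental" else ev$mode
      mode_ok <- c(mode_ok, dated_pairs$mode[i] == true_mode)
    }
    if (isTRUE(dated_pairs$valid[i]) && !is.na(dated_pairs$dS[i]) &&
        dated_pairs$dS[i] <= max_ds && ev$time_mya > 0) {
      rel_err <- c(rel_err,
                   abs(dated_pairs$T_my[i] - ev$time_mya) / ev$time_mya)
    }
  }

  # detectable planted gains: genes carrying introns inside an ancestrally
  # intron-free locus that is still majority intron-free (a gain fixed in
  # most of a locus redefines the locus type and is undetectable by the
  # deviant-member rule, by design)
  anc0 <- truth$loci$locus_id[truth$loci$anc_introns == 0]
  il <- introns
  il$true_locus <- locus_of[il$gene_id]
  planted <- character(0)
  for (L in intersect(anc0, unique(il$true_locus))) {
    sub <- il[il$true_locus == L, ]
    if (classify_pol_intron_type(sub) == "no_intron") {
      planted <- c(planted, sub$gene_id[sub$introns > 0])
    }
  }
  recall <- if (length(planted)) {
    mean(introns$event[match(planted, introns$gene_id)] == "gained")
  } else NA_real_

  data.frame(
    metric = c("pol_ari", "dup_mode_accuracy", "intron_gain_recall",
               "t_median_rel_error"),
    value = c(ari,
              if (length(mode_ok)) mean(mode_ok) else NA_real_,
              recall,
              if (length(rel_err)) median(rel_err) else NA_real_),
    n = c(length(common), length(mode_ok), length(planted), length(rel_err)),
    stringsAsFactors = FALSE)
}
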