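# Fixture reproducing a published-style survey table from printed
# per-species counts: intron distribution, intron-gain counts and
# duplication labels for one focal species, with helper genes from four
# other species fixing each POL's intron type.

printed_counts_fixture <- function(species, n_total, intron_counts,
                                   n_one_intron_gained,
                                   n_tandem, n_segmental) {
  counts <- rep(as.integer(names(intron_counts)), intron_counts)
  stopifnot(length(counts) == n_total)
  gene_id <- sprintf("%s.%03d", species, seq_len(n_total))
  helpers <- c("H1", "H2", "H3", "H4")

  ord <- order(counts)  # zeros first, then ones, then multi
  counts <- counts[ord]
  n_one <- sum(counts == 1)
  # the first n_one_intron_gained one-intron genes go to no-intron POLs
  one_idx <- which(counts == 1)
  in_no_intron_pol <- rep(FALSE, n_total)
  in_no_intron_pol[counts == 0] <- TRUE
  in_no_intron_pol[one_idx[seq_len(n_one_intron_gained)]] <- TRUE

  pol_rows <- list()
  intron_vec <- c()
  for (i in seq_len(n_total)) {
    pol <- sprintf("D%03d", i)
    helper_introns <- if (in_no_intron_pol[i]) 0L else 1L
    ids <- c(gene_id[i], paste0(pol, ".", helpers))
    pol_rows[[i]] <- data.frame(
      pol_id = pol, gene_id = ids,
      species = c(species, helpers), group = "D",
      stringsAsFactors = FALSE)
    intron_vec <- c(intron_vec,
                    setNames(c(counts[i], rep(helper_introns, 4)), ids))
  }
  pols <- do.call(rbind, pol_rows)
  class(pols) <- c("pol_table", "data.frame")

  labels <- setNames(rep("none", nrow(pols)), pols$gene_id)
  focal <- pols$gene_id[pols$species == species]
  labels[focal[seq_len(n_tandem)]] <- "tandem"
  labels[focal[n_tandem + seq_len(n_segmental)]] <- "segmental"

  list(pols = pols, introns = intron_calls(pols, intron_vec),
       labels = labels)
}
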