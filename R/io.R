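# File-format edges of the pipeline: FASTA via Biostrings, GFF3 via
# rtracklayer, Newick via ape, tables as TSV. Coordinates are 1-based and
# inclusive throughout; a gene's intron count is its exon count minus one.

#' Write protein or nucleotide sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param type `"AA"` or `"DNA"`
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file
#' @param type `"AA"` or `"DNA"`
#' @return named character vector
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write gene models to GFF3
#'
#' One `gene` feature per record plus `exon` sub-features; a gene with n
#' introns gets n + 1 exons (introns are fixed-width spacers between them,
#' a deliberate simplification: only the exon count carries information).
#' Non-family filler genes are written as single-exon genes.
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `introns`
#' @param path output file
#' @param fillers optional data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `strand`
#' @return the path, invisibly
#' @export
write_gff3 <- function(genes, path, fillers = NULL) {
  if (!is.null(fillers) && nrow(fillers) > 0) {
    fillers$introns <- 0L
    genes <- rbind(genes[, c("gene_id", "chrom", "start", "end", "strand",
                             "introns")],
                   fillers[, c("gene_id", "chrom", "start", "end", "strand",
                               "introns")])
  }
  genes <- genes[order(genes$chrom, genes$start), ]
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    feats[[length(feats) + 1]] <- data.frame(
      chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
      type = "gene", ID = g$gene_id, Parent = NA_character_)
    n_ex <- g$introns + 1
    # exons: equal-ish slices separated by 100-bp spacer introns
    width <- g$end - g$start + 1
    ex_w <- max(1, floor((width - 100 * g$introns) / n_ex))
    s <- g$start
    for (e in seq_len(n_ex)) {
      en <- if (e == n_ex) g$end else s + ex_w - 1
      feats[[length(feats) + 1]] <- data.frame(
        chrom = g$chrom, start = s, end = en, strand = g$strand,
        type = "exon", ID = sprintf("%s.exon%d", g$gene_id, e),
        Parent = g$gene_id)
      s <- en + 101
    }
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  par <- as.list(df$Parent)
  par[is.na(df$Parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- methods::as(par, "CharacterList")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene coordinates and intron counts from GFF3
#'
#' @param path GFF3 file with `gene` and `exon` features (exons linked by
#'   `Parent`)
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `introns`
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  parent <- unlist(lapply(exons$Parent, `[`, 1))
  n_ex <- table(parent)
  ids <- genes$ID
  introns <- as.integer(n_ex[ids]) - 1L
  introns[is.na(introns)] <- 0L
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(genes)),
             start = GenomicRanges::start(genes),
             end = GenomicRanges::end(genes),
             strand = as.character(GenomicRanges::strand(genes)),
             introns = introns,
             stringsAsFactors = FALSE)
}

#' Write all simulator outputs to a directory
#'
#' Per species: `<sp>_proteins.faa`, `<sp>_cds.fna` (family genes plus any
#' decoys assigned to that species) and `<sp>_genes.gff3` (family genes
#' plus fillers). Plus `anchors.faa` (headers carry `group=` tags),
#' `species_tree.nwk`, `truth_loci.tsv`, `truth_genes.tsv` and
#' `truth_events.tsv`.
#'
#' @param sim a `fam_sim` from [simulate_family()]
#' @param dir output directory (created if needed)
#' @param decoys optional decoy records from [make_decoys()]
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir, decoys = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in sim$species_tree$tip.label) {
    fam <- sim$genes[sim$genes$species == sp, ]
    dec <- if (is.null(decoys)) fam[0, ] else
      decoys[decoys$species == sp, names(decoys) != "decoy_class"]
    prots <- c(setNames(fam$protein, fam$gene_id),
               setNames(dec$protein, dec$gene_id))
    cds <- c(setNames(fam$cds, fam$gene_id),
             setNames(dec$cds, dec$gene_id))
    write_fasta(prots, file.path(dir, paste0(sp, "_proteins.faa")), "AA")
    write_fasta(cds, file.path(dir, paste0(sp, "_cds.fna")), "DNA")
    write_gff3(fam, file.path(dir, paste0(sp, "_genes.gff3")),
               fillers = sim$fillers[sim$fillers$species == sp, ])
  }
  anchor_seqs <- setNames(sim$anchors$protein,
                          sprintf("%s group=%s", sim$anchors$anchor_id,
                                  sim$anchors$group))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(anchor_seqs),
                              file.path(dir, "anchors.faa"))
  ape::write.tree(sim$species_tree, file.path(dir, "species_tree.nwk"))
  write_tsv(sim$truth$loci, file.path(dir, "truth_loci.tsv"))
  write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(sim$truth$events, file.path(dir, "truth_events.tsv"))
  if (!is.null(decoys)) {
    write_tsv(decoys[, c("gene_id", "species", "decoy_class")],
              file.path(dir, "truth_decoys.tsv"))
  }
  invisible(dir)
}

#' Read an anchor FASTA with group labels
#'
#' Headers must carry a `group=<letter>` tag after the anchor id.
#'
#' @param path FASTA file
#' @return data.frame `anchor_id`, `group`, `protein`
#' @export
read_anchors <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  grp <- sub(".*group=(\\S+).*", "\\1", full)
  if (any(grp == full)) stop("anchor headers must carry group= tags")
  data.frame(anchor_id = ids, group = grp, protein = as.character(x),
             stringsAsFactors = FALSE)
}
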