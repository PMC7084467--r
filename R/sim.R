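# Gene-family evolution simulator. Ancestral loci (grouped into
# anchor-defined phylogenetic groups) evolve along a dated, ultrametric
# species tree under codon-level substitution with tandem, segmental and
# whole-genome duplications, losses and intron count gain/loss, on
# chromosomes padded with motif-less filler genes so that "intervening
# genes" is meaningful. Every emitted gene carries a known ancestral locus
# and a full event genealogy (SimTruth).

DEFAULT_SPECIES_TREE <-
  "(((Mt:23,Tp:23):17,Lj:40):8,(Gm:19,Pv:19):29);"

DEFAULT_LAMBDA <- c(Mt = 1.08e-8, Gm = 5.85e-9, Pv = 8.46e-9,
                    Lj = 6.05e-9, Tp = 8.12e-9)

#' Simulation configuration
#'
#' Defaults emulate a five-species papilionoid legume study system: an
#' ultrametric species tree with the two deepest splits at 48 and 40
#' million years (MY), species-specific synonymous substitution rates
#' lambda of order 1e-8 per site per year, a whole-genome duplication on
#' the Gm terminal branch 13 million years ago, and a 44-residue C-terminal
#' diagnostic motif in every authentic family member.
#'
#' @param species_tree Newick string (branch lengths in MY, ultrametric)
#' @param lambda_per_species named vector, synonymous substitutions per
#'   synonymous site per year, one entry per tip
#' @param n_ancestral_loci ancestral family loci at the root
#' @param chromosomes_per_species chromosomes in the ancestral genome
#' @param filler_genes_per_chromosome motif-less non-family genes per
#'   chromosome (annotation context for the tandem rule)
#' @param tandem_rate,segmental_rate,loss_rate events per gene per MY
#' @param wgd_branches list of `list(branch=, time=)`: whole-genome
#'   duplications, each on the branch above the named node/tip at the given
#'   age in MY
#' @param intron_gain_rate,intron_loss_rate events per gene per MY
#' @param omega acceptance probability for nonsynonymous substitutions
#'   (dN/dS of the accepted process)
#' @param protein_length_range codon range for ancestral proteins
#' @param motif 44-residue consensus embedded near each C terminus
#' @param n_groups number of phylogenetic groups (anchor clades)
#' @param locus_divergence fraction of non-motif residues replaced when an
#'   ancestral locus is derived from its group ancestor
#' @param anchor_divergence same, for the group anchor sequence
#' @param p_ancestral_intron probability an ancestral locus has one intron
#'   (otherwise zero)
#' @param decoy_counts named counts per screening-violation class for
#'   [make_decoys()]
#' @param seed integer seed; all outputs are deterministic given it
#' @return list of class `sim_config`
#' @export
sim_config <- function(species_tree = DEFAULT_SPECIES_TREE,
                       lambda_per_species = DEFAULT_LAMBDA,
                       n_ancestral_loci = 30,
                       chromosomes_per_species = 5,
                       filler_genes_per_chromosome = 40,
                       tandem_rate = 0.012,
                       segmental_rate = 0.004,
                       loss_rate = 0.002,
                       wgd_branches = list(list(branch = "Gm", time = 13)),
                       intron_gain_rate = 0.001,
                       intron_loss_rate = 0.0005,
                       omega = 0.2,
                       protein_length_range = c(350, 600),
                       motif = default_motif(),
                       n_groups = 6,
                       locus_divergence = 0.35,
                       anchor_divergence = 0.08,
                       p_ancestral_intron = 0.4,
                       decoy_counts = c(short = 2, long = 2,
                                        non_met_start = 2,
                                        incomplete_motif = 2,
                                        duplicate_identical = 2),
                       seed = 1) {
  rates <- c(tandem_rate, segmental_rate, loss_rate, intron_gain_rate,
             intron_loss_rate)
  stopifnot(all(rates >= 0), omega >= 0, omega <= 1,
            n_ancestral_loci >= 1, chromosomes_per_species >= 1,
            filler_genes_per_chromosome >= 0,
            length(protein_length_range) == 2,
            protein_length_range[1] >= 100,
            protein_length_range[1] <= protein_length_range[2],
            nchar(motif) == 44, n_groups >= 1,
            locus_divergence >= 0, locus_divergence <= 1,
            all(lambda_per_species >= 0))
  structure(list(species_tree = species_tree,
                 lambda_per_species = lambda_per_species,
                 n_ancestral_loci = n_ancestral_loci,
                 chromosomes_per_species = chromosomes_per_species,
                 filler_genes_per_chromosome = filler_genes_per_chromosome,
                 tandem_rate = tandem_rate,
                 segmental_rate = segmental_rate,
                 loss_rate = loss_rate,
                 wgd_branches = wgd_branches,
                 intron_gain_rate = intron_gain_rate,
                 intron_loss_rate = intron_loss_rate,
                 omega = omega,
                 protein_length_range = protein_length_range,
                 motif = motif,
                 n_groups = n_groups,
                 locus_divergence = locus_divergence,
                 anchor_divergence = anchor_divergence,
                 p_ancestral_intron = p_ancestral_intron,
                 decoy_counts = decoy_counts,
                 seed = seed),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Fields mirror the arguments of [sim_config()]; absent fields keep their
#' defaults.
#'
#' @param path YAML file
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(vals$lambda_per_species)) {
    vals$lambda_per_species <- unlist(vals$lambda_per_species)
  }
  if (!is.null(vals$decoy_counts)) vals$decoy_counts <- unlist(vals$decoy_counts)
  do.call(sim_config, vals)
}

# --- sequence machinery ----------------------------------------------------

random_cds <- function(protein_len, motif, motif_at = NULL) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  aa_of <- gc[sense]
  codons_for <- split(sense, aa_of)
  if (is.null(motif_at)) motif_at <- protein_len - 44 - 9  # near C terminus
  aa <- c("M", sample(setdiff(names(codons_for), "M"), protein_len - 1,
                      replace = TRUE))
  aa[motif_at:(motif_at + 43)] <- strsplit(motif, "")[[1]]
  cds <- vapply(aa, function(x) {
    opts <- codons_for[[x]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  list(cds = paste(cds, collapse = ""), motif_at = motif_at)
}

# replace a fraction of non-motif, non-start codons with codons for a
# different amino acid (used to derive locus ancestors and group anchors)
diverge_cds <- function(cds, fraction, motif_at) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  codons <- split_codons(cds)
  protected <- c(1, motif_at:(motif_at + 43))
  candidates <- setdiff(seq_along(codons), protected)
  n_mut <- round(fraction * length(candidates))
  if (n_mut == 0) return(cds)
  hit <- sample(candidates, n_mut)
  for (i in hit) {
    cur_aa <- gc[[codons[i]]]
    opts <- sense[gc[sense] != cur_aa]
    codons[i] <- opts[sample.int(length(opts), 1)]
  }
  paste(codons, collapse = "")
}

# Neutral-with-selection substitution process: single-nucleotide proposals
# arrive at rate lambda per site; synonymous proposals are always accepted,
# nonsynonymous with probability omega, and proposals creating a stop codon
# or touching the start codon are rejected. Because the synonymous fraction
# of neighbor changes defines the NG86 synonymous site count, the realized
# synonymous substitution rate per synonymous site per year equals lambda.
evolve_cds <- function(cds, lambda, dt_my, omega) {
  if (dt_my <= 0 || lambda <= 0) return(cds)
  nts <- strsplit(cds, "")[[1]]
  L <- length(nts)
  n_prop <- rpois(1, L * lambda * dt_my * 1e6)
  if (n_prop == 0) return(cds)
  gc <- genetic_code()
  for (k in seq_len(n_prop)) {
    pos <- sample.int(L, 1)
    ci <- (pos - 1) %/% 3
    if (ci == 0) next  # start codon is immutable
    cur <- nts[pos]
    alt <- sample(setdiff(NUCS, cur), 1)
    cod <- nts[(ci * 3 + 1):(ci * 3 + 3)]
    old_aa <- gc[[paste(cod, collapse = "")]]
    cod[pos - ci * 3] <- alt
    new_aa <- gc[[paste(cod, collapse = "")]]
    if (new_aa == "*") next
    if (new_aa == old_aa || runif(1) < omega) nts[pos] <- alt
  }
  paste(nts, collapse = "")
}

# one guaranteed nonsynonymous change (applied to every fresh duplicate so
# that no two genes are ever byte-identical; dS is untouched)
force_nonsyn <- function(cds) {
  nts <- strsplit(cds, "")[[1]]
  gc <- genetic_code()
  repeat {
    pos <- sample(4:length(nts), 1)
    ci <- (pos - 1) %/% 3
    cur <- nts[pos]
    alt <- sample(setdiff(NUCS, cur), 1)
    cod <- nts[(ci * 3 + 1):(ci * 3 + 3)]
    old_aa <- gc[[paste(cod, collapse = "")]]
    cod[pos - ci * 3] <- alt
    new_aa <- gc[[paste(cod, collapse = "")]]
    if (new_aa != "*" && new_aa != old_aa) {
      nts[pos] <- alt
      return(paste(nts, collapse = ""))
    }
  }
}

# --- simulation ------------------------------------------------------------

#' Simulate a multi-species gene family with known history
#'
#' Evolves `n_ancestral_loci` family loci (plus filler genes) along the
#' configured species tree. All randomness flows from `config$seed`, so
#' outputs are fully reproducible. See the package vignette for the model
#' and its deliberate simplifications.
#'
#' @param config a [sim_config()]
#' @return list of class `fam_sim` with elements `genes` (per-species gene
#'   records: `gene_id`, `species`, `chrom`, `start`, `end`, `strand`,
#'   `introns`, `protein`, `cds`), `fillers` (annotation-only non-family
#'   genes), `anchors` (group anchor records), `truth` (a `sim_truth`:
#'   `loci`, `genes` genealogy, `events` log), `species_tree` (`phylo`) and
#'   `config`
#' @export
simulate_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- ape::read.tree(text = config$species_tree)
  if (is.null(tree) || length(tree$tip.label) == 0) {
    stop("empty species tree")
  }
  if (length(tree$tip.label) >= 2 &&
      !ape::is.ultrametric(tree, tol = 1e-6)) {
    stop("species tree must be ultrametric (branch lengths in MY)")
  }
  missing_l <- setdiff(tree$tip.label, names(config$lambda_per_species))
  if (length(missing_l)) {
    stop("no lambda for species: ", paste(missing_l, collapse = ", "))
  }
  set.seed(config$seed)

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  node_name <- c(tree$tip.label, sprintf("node%d", seq_len(nnode)))
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth            # MYA per node
  root <- ntip + 1
  kids <- split(tree$edge[, 2], tree$edge[, 1])

  # per-branch lambda: terminal branches use the species rate, internal
  # branches the mean rate of their descendant species
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  branch_lambda <- vapply(seq_len(ntip + nnode), function(v) {
    mean(config$lambda_per_species[tips_under(v)])
  }, numeric(1))

  # bookkeeping environment
  trk <- new.env(parent = emptyenv())
  trk$counters <- list()
  trk$truth_genes <- list()
  trk$events <- list()
  trk$filler_n <- 0L
  new_id <- function(branch) {
    n <- (trk$counters[[branch]] %||% 0L) + 1L
    trk$counters[[branch]] <- n
    sprintf("%s.%04d", branch, n)
  }
  new_filler <- function() {
    trk$filler_n <- trk$filler_n + 1L
    sprintf("flr%05d", trk$filler_n)
  }
  note_gene <- function(id, branch, locus, parent, event, time) {
    trk$truth_genes[[length(trk$truth_genes) + 1]] <-
      data.frame(gene_id = id, branch = branch, locus = locus,
                 parent_gene = parent, birth_event = event,
                 birth_time_mya = time, stringsAsFactors = FALSE)
  }
  note_event <- function(event, branch, time, gene, new_gene = NA, mode = NA) {
    trk$events[[length(trk$events) + 1]] <-
      data.frame(event = event, branch = branch, time_mya = time,
                 gene = gene, new_gene = new_gene, mode = mode,
                 stringsAsFactors = FALSE)
  }

  # ancestral groups, loci and genome
  groups <- LETTERS[seq_len(config$n_groups)]
  grp_anc <- lapply(groups, function(g) {
    len <- sample(config$protein_length_range[1]:config$protein_length_range[2], 1)
    random_cds(len, config$motif)
  })
  names(grp_anc) <- groups
  locus_group <- sample(rep(groups, length.out = config$n_ancestral_loci))
  locus_ids <- sprintf("L%02d", seq_len(config$n_ancestral_loci))
  anc_introns <- rbinom(config$n_ancestral_loci, 1, config$p_ancestral_intron)
  loci_df <- data.frame(locus_id = locus_ids, group = locus_group,
                        anc_introns = anc_introns,
                        length_aa = vapply(grp_anc[locus_group], function(x)
                          nchar(x$cds) / 3, numeric(1)),
                        stringsAsFactors = FALSE)

  genome <- lapply(seq_len(config$chromosomes_per_species), function(i) {
    vapply(seq_len(config$filler_genes_per_chromosome),
           function(j) new_filler(), character(1))
  })
  names(genome) <- sprintf("chr%d", seq_len(config$chromosomes_per_species))

  root_age <- ages[root]
  genes <- list()
  for (i in seq_len(config$n_ancestral_loci)) {
    g <- locus_group[i]
    cds <- diverge_cds(grp_anc[[g]]$cds, config$locus_divergence,
                       grp_anc[[g]]$motif_at)
    id <- new_id("root")
    genes[[id]] <- list(id = id, locus = locus_ids[i], cds = cds,
                        introns = anc_introns[i], last_age = root_age)
    ch <- sample(names(genome), 1)
    pos <- sample(0:length(genome[[ch]]), 1)
    genome[[ch]] <- append(genome[[ch]], id, after = pos)
    note_gene(id, "root", locus_ids[i], NA_character_, "root", root_age)
  }

  anchors <- data.frame(
    anchor_id = sprintf("anchor_%s", groups), group = groups,
    protein = vapply(groups, function(g) {
      translate_cds(diverge_cds(grp_anc[[g]]$cds, config$anchor_divergence,
                                grp_anc[[g]]$motif_at))
    }, character(1)),
    stringsAsFactors = FALSE)

  wgd_by_branch <- list()
  for (w in config$wgd_branches) {
    wgd_by_branch[[w$branch]] <- c(wgd_by_branch[[w$branch]], w$time)
  }

  tip_records <- list()
  filler_records <- list()

  emit_tip <- function(species, genes, genome) {
    recs <- list()
    flls <- list()
    for (ch in names(genome)) {
      ids <- genome[[ch]]
      for (i in seq_along(ids)) {
        id <- ids[i]
        start <- (i - 1) * 10000 + 1
        if (startsWith(id, "flr")) {
          flls[[length(flls) + 1]] <- data.frame(
            gene_id = sprintf("%s.%s", species, id), species = species,
            chrom = ch, start = start, end = start + 999,
            strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
        } else {
          gn <- genes[[id]]
          span <- nchar(gn$cds) + 3 + 200 * gn$introns
          recs[[length(recs) + 1]] <- data.frame(
            gene_id = id, species = species, chrom = ch,
            start = start, end = start + span - 1,
            strand = sample(c("+", "-"), 1),
            introns = gn$introns,
            protein = translate_cds(gn$cds, id),
            cds = paste0(gn$cds, "TAA"), stringsAsFactors = FALSE)
        }
      }
    }
    tip_records[[species]] <<- do.call(rbind, recs)
    filler_records[[species]] <<- do.call(rbind, flls)
  }

  # process the branch ending at `node` (from age t0 down to the node's
  # age), then recurse into the node's children
  descend_branch <- function(node, genes, genome, t0) {
    branch <- node_name[node]
    t1 <- ages[node]
    lam <- branch_lambda[node]
    dt <- t0 - t1

    if (dt > 0 && length(genes) > 0) {
      # event queue for genes present at branch start
      q <- list()
      add <- function(type, gene, time) {
        q[[length(q) + 1]] <<- list(type = type, gene = gene, time = time)
      }
      for (id in names(genes)) {
        for (type in c("tandem", "segmental", "loss", "intron_gain",
                       "intron_loss")) {
          rate <- switch(type, tandem = config$tandem_rate,
                         segmental = config$segmental_rate,
                         loss = config$loss_rate,
                         intron_gain = config$intron_gain_rate,
                         intron_loss = config$intron_loss_rate)
          n <- rpois(1, rate * dt)
          if (n > 0) for (tm in runif(n, t1, t0)) add(type, id, tm)
        }
      }
      for (tm in wgd_by_branch[[branch]]) {
        if (tm <= t0 && tm > t1) add("wgd", NA, tm)
      }
      if (length(q)) {
        times <- vapply(q, `[[`, numeric(1), "time")
        q <- q[order(-times)]
      }
      for (ev in q) {
        if (ev$type == "wgd") {
          for (id in names(genes)) {
            genes[[id]]$cds <- evolve_cds(genes[[id]]$cds, lam,
                                          genes[[id]]$last_age - ev$time,
                                          config$omega)
            genes[[id]]$last_age <- ev$time
          }
          for (ch in names(genome)) {
            new_ch <- paste0(ch, "w")
            while (new_ch %in% names(genome)) new_ch <- paste0(new_ch, "w")
            new_vec <- character(length(genome[[ch]]))
            for (i in seq_along(genome[[ch]])) {
              id <- genome[[ch]][i]
              if (startsWith(id, "flr")) {
                new_vec[i] <- new_filler()
              } else {
                nid <- new_id(branch)
                genes[[nid]] <- list(id = nid, locus = genes[[id]]$locus,
                                     cds = force_nonsyn(genes[[id]]$cds),
                                     introns = genes[[id]]$introns,
                                     last_age = ev$time)
                note_gene(nid, branch, genes[[id]]$locus, id, "wgd_dup",
                          ev$time)
                note_event("wgd_dup", branch, ev$time, id, nid, "wgd")
                new_vec[i] <- nid
              }
            }
            genome[[new_ch]] <- new_vec
          }
          next
        }
        id <- ev$gene
        if (is.null(genes[[id]])) next  # lost before this event
        genes[[id]]$cds <- evolve_cds(genes[[id]]$cds, lam,
                                      genes[[id]]$last_age - ev$time,
                                      config$omega)
        genes[[id]]$last_age <- ev$time
        if (ev$type == "loss") {
          note_event("loss", branch, ev$time, id)
          for (ch in names(genome)) genome[[ch]] <- setdiff(genome[[ch]], id)
          genes[[id]] <- NULL
        } else if (ev$type == "intron_gain") {
          genes[[id]]$introns <- genes[[id]]$introns + 1L
          note_event("intron_gain", branch, ev$time, id)
        } else if (ev$type == "intron_loss") {
          if (genes[[id]]$introns > 0) {
            genes[[id]]$introns <- genes[[id]]$introns - 1L
            note_event("intron_loss", branch, ev$time, id)
          }
        } else {
          nid <- new_id(branch)
          genes[[nid]] <- list(id = nid, locus = genes[[id]]$locus,
                               cds = force_nonsyn(genes[[id]]$cds),
                               introns = genes[[id]]$introns,
                               last_age = ev$time)
          mode <- ev$type
          note_gene(nid, branch, genes[[id]]$locus, id,
                    paste0(mode, "_dup"), ev$time)
          note_event(paste0(mode, "_dup"), branch, ev$time, id, nid, mode)
          home <- NULL
          for (ch in names(genome)) {
            if (id %in% genome[[ch]]) { home <- ch; break }
          }
          if (mode == "tandem") {
            # unequal crossover places the copy adjacent to its source;
            # separation only arises from later insertions
            pos <- match(id, genome[[home]])
            genome[[home]] <- append(genome[[home]], nid, after = pos)
          } else {
            others <- setdiff(names(genome), home)
            tgt <- if (length(others)) sample(others, 1) else home
            genome[[tgt]] <- append(genome[[tgt]], nid,
                                    after = sample(0:length(genome[[tgt]]), 1))
          }
        }
      }
      for (id in names(genes)) {
        genes[[id]]$cds <- evolve_cds(genes[[id]]$cds, lam,
                                      genes[[id]]$last_age - t1, config$omega)
        genes[[id]]$last_age <- t1
      }
    }

    if (node <= ntip) {
      emit_tip(node_name[node], genes, genome)
      return(invisible(NULL))
    }
    for (child in kids[[as.character(node)]]) {
      cbranch <- node_name[child]
      cgenes <- list()
      cgenome <- genome
      remap <- character(0)
      for (id in names(genes)) {
        nid <- new_id(cbranch)
        g <- genes[[id]]
        g$id <- nid
        cgenes[[nid]] <- g
        remap[id] <- nid
        note_gene(nid, cbranch, g$locus, id, "speciation", t1)
      }
      for (ch in names(cgenome)) {
        fam <- cgenome[[ch]] %in% names(remap)
        cgenome[[ch]][fam] <- remap[cgenome[[ch]][fam]]
      }
      descend_branch(child, cgenes, cgenome, t1)
    }
    invisible(NULL)
  }

  descend_branch(root, genes, genome, root_age)

  gene_df <- do.call(rbind, tip_records[tree$tip.label])
  rownames(gene_df) <- NULL
  filler_df <- do.call(rbind, filler_records[tree$tip.label])
  rownames(filler_df) <- NULL
  truth <- structure(
    list(loci = loci_df,
         genes = do.call(rbind, trk$truth_genes),
         events = if (length(trk$events)) do.call(rbind, trk$events) else
           data.frame(event = character(), branch = character(),
                      time_mya = numeric(), gene = character(),
                      new_gene = character(), mode = character()),
         lambda = config$lambda_per_species),
    class = "sim_truth")
  structure(list(genes = gene_df, fillers = filler_df, anchors = anchors,
                 truth = truth, species_tree = tree, config = config),
            class = "fam_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate decoy genes violating the screening rules
#'
#' Each decoy violates exactly one screening rule: `short` (< 350
#' residues, motif intact), `long` (> 600), `non_met_start`,
#' `incomplete_motif` (motif region randomized) or `duplicate_identical`
#' (an exact copy of a kept family gene of the same species, with a gene
#' id sorting after the original so the original is the one kept).
#' Decoys are sequence-only records (no coordinates); their class is the
#' truth label.
#'
#' @param config a [sim_config()] (supplies `decoy_counts` and the motif)
#' @param genes family gene records from [simulate_family()]
#' @return data.frame like `genes` but with `chrom`/`start`/`end` `NA` and
#'   an extra `decoy_class` column
#' @export
make_decoys <- function(config, genes) {
  counts <- config$decoy_counts
  species <- unique(genes$species)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  codons_for <- split(sense, gc[sense])

  rows <- list()
  mk <- function(cls, i, sp) {
    if (cls == "duplicate_identical") {
      pool <- genes[genes$species == sp, ]
      src <- pool[sample.int(nrow(pool), 1), ]
      prot <- src$protein
      cds <- src$cds
      detail <- src$gene_id
    } else {
      len <- switch(cls,
                    short = sample(150:349, 1),
                    long = sample(601:700, 1),
                    sample(config$protein_length_range[1]:
                             config$protein_length_range[2], 1))
      r <- random_cds(len, config$motif)
      cds <- r$cds
      if (cls == "non_met_start") {
        first <- sample(setdiff(names(codons_for), "M"), 1)
        opts <- codons_for[[first]]
        cds <- paste0(opts[sample.int(length(opts), 1)],
                      substring(cds, 4))
      } else if (cls == "incomplete_motif") {
        cod <- split_codons(cds)
        for (j in r$motif_at:(r$motif_at + 43)) {
          cur <- gc[[cod[j]]]
          opts <- sense[gc[sense] != cur]
          cod[j] <- opts[sample.int(length(opts), 1)]
        }
        cds <- paste(cod, collapse = "")
      }
      prot <- translate_cds(cds)
      cds <- paste0(cds, "TAA")
      detail <- NA_character_
    }
    data.frame(gene_id = sprintf("%s.zdecoy_%s_%02d", sp, cls, i),
               species = sp, chrom = NA_character_, start = NA_real_,
               end = NA_real_, strand = NA_character_,
               introns = 0L, protein = prot, cds = cds,
               decoy_class = cls, stringsAsFactors = FALSE)
  }
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      sp <- species[(i - 1) %% length(species) + 1]
      rows[[length(rows) + 1]] <- mk(cls, i, sp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
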