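# Putative ortholog locus (POL) assignment: bottom-up agglomeration over
# the gene tree within each phylogenetic group, gated by bootstrap support
# and full-length percent identity; positional POL naming; copy-number
# classes.

#' POL clustering configuration
#'
#' Gates for [assign_pols()]. A merge of sister clades is accepted only
#' when the supporting edge has bootstrap support at least `min_support`,
#' the minimum pairwise identity within the merged gene set is at least
#' `theta_min` and the mean pairwise identity at least `theta_mean`. The
#' identity defaults reflect the within-POL conservation typically seen in
#' large plant families (roughly 54-99% between co-members).
#'
#' @param min_support bootstrap percentage gate (default 50)
#' @param theta_min minimum pairwise identity within a POL (default 55)
#' @param theta_mean minimum mean pairwise identity (default 60)
#' @param species_priority ordered species vector used by [name_pols()]
#' @return list of class `pol_config`
#' @export
pol_config <- function(min_support = 50, theta_min = 55, theta_mean = 60,
                       species_priority = NULL) {
  stopifnot(min_support >= 0, min_support <= 100,
            theta_min >= 0, theta_min <= 100,
            theta_mean >= 0, theta_mean <= 100,
            theta_min <= theta_mean)
  structure(list(min_support = min_support, theta_min = theta_min,
                 theta_mean = theta_mean,
                 species_priority = species_priority),
            class = "pol_config")
}

#' Cluster genes into putative ortholog loci
#'
#' Within each phylogenetic group the gene tree is rooted outside the group
#' and searched for maximal surviving clades: a clade survives when it
#' contains only this group's genes, its subtending edge passes the
#' bootstrap support gate, and its gene set passes both identity gates
#' (see [pol_config()]). Each maximal surviving clade becomes a POL, so
#' poorly supported edges nested inside a supported POL clade do not
#' fragment it; genes under no surviving clade remain singleton POLs, and
#' clades containing genes of another group are never merged across.
#' Cluster ids are provisional; [name_pols()] turns them into positional
#' POL names.
#'
#' @param tree `phylo` tree containing all genes (typically from
#'   [bootstrap_supports()]; without a `split_support` attribute all edges
#'   pass the support gate)
#' @param identity square percent-identity matrix covering all genes
#' @param groups named character vector gene -> group (from
#'   [assign_groups()])
#' @param config a [pol_config()]
#' @return data.frame with columns `gene_id`, `group`, `cluster`
#' @export
assign_pols <- function(tree, identity, groups, config = pol_config()) {
  genes <- names(groups)
  miss <- setdiff(genes, rownames(identity))
  if (length(miss)) {
    stop("genes missing from the identity matrix: ",
         paste(head(miss, 5), collapse = ", "))
  }
  support <- attr(tree, "split_support")
  tips <- tree$tip.label
  ref <- sort(tips)[1]

  res <- data.frame(gene_id = character(), group = character(),
                    cluster = character(), stringsAsFactors = FALSE)
  counter <- 0L
  for (g in sort(unique(groups))) {
    members <- genes[groups == g]
    if (length(members) == 1) {
      counter <- counter + 1L
      res <- rbind(res, data.frame(gene_id = members, group = g,
                                   cluster = sprintf("c%04d", counter)))
      next
    }
    out_tip <- setdiff(tips, members)[1]
    rt <- if (is.na(out_tip)) {
      ape::root(tree, outgroup = tips[1], resolve.root = TRUE)
    } else {
      ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
    }
    cl <- cluster_group(rt, members, identity, support, config, tips, ref)
    cl_ids <- sprintf("c%04d", counter + as.integer(factor(cl, levels = unique(cl))))
    counter <- counter + length(unique(cl))
    res <- rbind(res, data.frame(gene_id = names(cl), group = g,
                                 cluster = cl_ids, stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}

# Maximal surviving clades for one group's genes: a clade survives when it
# contains only this group's genes, its own subtending edge passes the
# bootstrap gate, and the identity gates hold over all its gene pairs.
# Each gene joins the largest surviving clade containing it (low-support
# edges nested inside a well-supported POL clade do not fragment it);
# genes under no surviving clade remain singletons.
cluster_group <- function(rt, members, identity, support, config,
                          orig_tips, ref) {
  ntip <- length(rt$tip.label)
  kids <- split(rt$edge[, 2], rt$edge[, 1])
  root <- setdiff(rt$edge[, 1], rt$edge[, 2])[1]
  cluster <- setNames(rep(NA_character_, length(members)), members)
  nxt <- 0L
  new_id <- function() {
    nxt <<- nxt + 1L
    sprintf("k%d", nxt)
  }

  edge_support <- function(side) {
    if (is.null(support)) return(100)
    if (length(side) <= 1 || length(side) >= length(orig_tips) - 1) return(100)
    k <- split_key(side, orig_tips, ref)
    if (k %in% names(support)) unname(support[[k]]) else 100
  }

  gates_pass <- function(set) {
    if (length(set) < 2) return(TRUE)
    sub <- identity[set, set]
    pij <- sub[upper.tri(sub)]
    min(pij) >= config$theta_min && mean(pij) >= config$theta_mean
  }

  tips_below <- function(node) {
    if (node <= ntip) return(rt$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_below), use.names = FALSE)
  }

  # top-down: stop at the first (largest) passing clade on each path
  assign_down <- function(node) {
    tb <- tips_below(node)
    genes <- intersect(tb, members)
    if (length(genes) == 0) return(invisible(NULL))
    pure <- length(genes) == length(tb)
    sup <- if (node == root || node <= ntip) 100 else edge_support(tb)
    if (pure && sup >= config$min_support && gates_pass(genes)) {
      cluster[genes] <<- new_id()
      return(invisible(NULL))
    }
    if (node <= ntip) {
      cluster[tb] <<- new_id()  # lone gene under no surviving clade
      return(invisible(NULL))
    }
    for (child in kids[[as.character(node)]]) assign_down(child)
    invisible(NULL)
  }
  assign_down(root)
  cluster
}

#' Name POLs positionally within each group
#'
#' Within a group, POLs are ranked by the chromosome and start coordinate
#' of the earliest member from the highest-priority species present (the
#' next species in priority order is used when the first has no members),
#' and labelled group letter + zero-padded rank (`D01`, `D02`, ...). POLs
#' with no positioned member sort last, by smallest gene id.
#'
#' @param clusters data.frame from [assign_pols()] (`gene_id`, `group`,
#'   `cluster`)
#' @param genes data.frame with `gene_id`, `species`, `chrom`, `start`
#' @param species_priority ordered character vector of species
#' @return data.frame of class `pol_table`: `pol_id`, `gene_id`, `species`,
#'   `group`
#' @export
name_pols <- function(clusters, genes, species_priority) {
  meta <- genes[match(clusters$gene_id, genes$gene_id), ]
  clusters$species <- meta$species
  clusters$chrom <- as.character(meta$chrom)
  clusters$start <- meta$start

  rank_key <- function(df) {
    for (sp in species_priority) {
      rows <- df[df$species == sp & !is.na(df$start), , drop = FALSE]
      if (nrow(rows)) {
        best <- rows[order(rows$chrom, rows$start, rows$gene_id)[1], ]
        return(list(pos = TRUE, sp = match(sp, species_priority),
                    chrom = best$chrom, start = best$start,
                    gene = best$gene_id))
      }
    }
    list(pos = FALSE, sp = length(species_priority) + 1L, chrom = "",
         start = Inf, gene = min(df$gene_id))
  }

  out <- NULL
  for (g in sort(unique(clusters$group))) {
    sub <- clusters[clusters$group == g, , drop = FALSE]
    ids <- unique(sub$cluster)
    keys <- lapply(ids, function(cl) rank_key(sub[sub$cluster == cl, ]))
    ord <- order(!vapply(keys, `[[`, logical(1), "pos"),
                 vapply(keys, `[[`, integer(1), "sp"),
                 vapply(keys, `[[`, character(1), "chrom"),
                 vapply(keys, `[[`, numeric(1), "start"),
                 vapply(keys, `[[`, character(1), "gene"))
    pol_of <- setNames(sprintf("%s%02d", g, seq_along(ids)), ids[ord])
    sub$pol_id <- unname(pol_of[sub$cluster])
    out <- rbind(out, sub[, c("pol_id", "gene_id", "species", "group")])
  }
  out <- out[order(out$pol_id, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("pol_table", "data.frame")
  out
}

#' Per-species copy-number class of each POL
#'
#' Counts members per species within each POL and classifies the count:
#' 0 = absent, 1 = single, 2 = double, >= 3 = multi.
#'
#' @param pols a `pol_table` from [name_pols()]
#' @param species character vector of the species universe (defaults to the
#'   species present in the table)
#' @return data.frame `pol_id`, `species`, `n`, `class`
#' @export
copy_number_classes <- function(pols, species = sort(unique(pols$species))) {
  grid <- expand.grid(pol_id = sort(unique(pols$pol_id)), species = species,
                      stringsAsFactors = FALSE)
  n <- mapply(function(p, s) sum(pols$pol_id == p & pols$species == s),
              grid$pol_id, grid$species)
  grid$n <- as.integer(n)
  grid$class <- cut(grid$n, breaks = c(-1, 0, 1, 2, Inf),
                    labels = c("absent", "single", "double", "multi"))
  grid$class <- as.character(grid$class)
  grid[order(grid$pol_id, grid$species), ]
}
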