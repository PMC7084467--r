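# Neighbor-joining trees, bootstrap supports on unrooted bipartitions, and
# phylogenetic-group assignment from labelled anchor sequences.

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via \pkg{ape}) on a distance matrix; negative
#' branch-length estimates are clamped to zero.
#'
#' @param D square symmetric distance matrix with taxon dimnames (or a
#'   `dist`)
#' @return unrooted `phylo` tree
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(D))) stop("distance matrix contains non-finite entries")
  tr <- ape::nj(D)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# Non-trivial bipartitions of an unrooted tree as canonical keys. Each
# internal edge splits the leaves in two; the key is the sorted,
# ';'-joined side that does not contain the alphabetically first leaf.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  ref <- sort(tips)[1]
  below <- clade_tips(tree)
  keys <- character(0)
  for (node in names(below)) {
    side <- below[[node]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    keys <- c(keys, split_key(side, tips, ref))
  }
  unique(keys)
}

split_key <- function(side, all_tips, ref = sort(all_tips)[1]) {
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ";")
}

# tip labels below each internal node (list named by node number)
clade_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  acc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (!is.null(below[[node]])) return(below[[node]])
    res <- unlist(lapply(kids[[as.character(node)]], acc), use.names = FALSE)
    below[[node]] <<- res
    res
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  acc(root)
  out <- below[(ntip + 1):(ntip + nnode)]
  names(out) <- as.character((ntip + 1):(ntip + nnode))
  out
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds a
#' replicate tree each time, and records for every internal bipartition of
#' the full-data tree the percentage of replicates containing it. Supports
#' are attached as `node.label` and as a named vector in
#' `attr(tree, "split_support")`. Replicate distances that are infinite
#' (a resample can leave a pair with no shared sites or all-different
#' sites) are capped at twice the largest finite replicate distance.
#'
#' @param msa named character vector of >= 3 aligned sequences
#' @param n_reps number of bootstrap replicates (>= 1; the conventional
#'   choice is 1000, reducible for desk-scale runs)
#' @param seed integer seed driving the column resampling
#' @return the full-data `phylo` tree with supports
#' @export
bootstrap_supports <- function(msa, n_reps = 1000, seed = 1) {
  if (length(msa) < 3) stop("bootstrap needs at least 3 sequences")
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- encode_msa(msa)
  if (ncol(m) < 1) stop("alignment has no columns")
  full_d <- matrix_from_coded(m, names(msa))
  tree <- nj_tree(full_d)
  keys <- tree_splits(tree)
  counts <- setNames(numeric(length(keys)), keys)

  set.seed(seed)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(m), replace = TRUE)
    d <- matrix_from_coded(m[, idx, drop = FALSE], names(msa))
    if (any(!is.finite(d))) {
      cap <- 2 * max(d[is.finite(d)], 1e-8)
      d[!is.finite(d)] <- cap
    }
    rep_keys <- tree_splits(nj_tree(d))
    hit <- intersect(rep_keys, keys)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps

  # node labels: support of the split below each internal node
  below <- clade_tips(tree)
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  labs <- vapply(below, function(side) {
    if (length(side) <= 1 || length(side) >= length(tips) - 1) return("")
    k <- split_key(side, tips, ref)
    if (k %in% names(support)) sprintf("%d", round(support[[k]])) else ""
  }, character(1))
  tree$node.label <- unname(labs)
  attr(tree, "split_support") <- support
  tree
}

matrix_from_coded <- function(m, nm) {
  st <- msa_pair_stats(m, X_CODE)
  p <- st$ndiff / pmax(st$ncomp, 1)
  p[st$ncomp == 0] <- NA_real_
  d <- ifelse(is.na(p), Inf, ifelse(p < 1, -log(1 - p), Inf))
  diag(d) <- 0
  dimnames(d) <- list(nm, nm)
  d
}

#' Assign genes to phylogenetic groups via labelled anchors
#'
#' Each gene receives the group of the anchors in the smallest clade (over
#' both sides of every edge of the unrooted tree) containing the gene and
#' at least one anchor. If the minimal clade contains anchors of more than
#' one group, the gene falls back to the group of its highest-identity
#' anchor.
#'
#' @param tree `phylo` tree whose tips include all anchors
#' @param anchors data.frame with columns `anchor_id`, `group`
#' @param identity square percent-identity matrix covering genes and
#'   anchors (used only for the mixed-clade fallback)
#' @return named character vector: gene id -> group
#' @export
assign_groups <- function(tree, anchors, identity = NULL) {
  stopifnot(all(c("anchor_id", "group") %in% names(anchors)))
  tips <- tree$tip.label
  anchor_ids <- anchors$anchor_id
  if (!any(anchor_ids %in% tips)) stop("tree contains no anchors")
  anchor_ids <- intersect(anchor_ids, tips)
  genes <- setdiff(tips, anchor_ids)
  if (length(genes) == 0) return(setNames(character(0), character(0)))
  grp_of_anchor <- setNames(anchors$group, anchors$anchor_id)

  below <- clade_tips(tree)
  sides <- c(below, lapply(below, function(s) setdiff(tips, s)))
  # plus single-tip sides so a gene sister to nothing still resolves
  sides <- c(sides, as.list(tips))
  sizes <- vapply(sides, length, integer(1))
  keep <- sizes >= 1 & sizes < length(tips)
  sides <- sides[keep]
  sizes <- sizes[keep]
  memb <- vapply(sides, function(s) tips %in% s, logical(length(tips)))
  rownames(memb) <- tips
  has_anchor <- vapply(sides, function(s) any(anchor_ids %in% s), logical(1))

  out <- setNames(rep(NA_character_, length(genes)), genes)
  for (g in genes) {
    cand <- which(has_anchor & memb[g, ])
    found <- if (length(cand) == 0) {
      anchor_ids  # no split separates g from the anchors (e.g. a star)
    } else {
      best <- cand[sizes[cand] == min(sizes[cand])]
      unique(unlist(lapply(sides[best], intersect, x = anchor_ids)))
    }
    groups_found <- unique(grp_of_anchor[found])
    if (length(groups_found) == 1) {
      out[g] <- groups_found
    } else {
      if (is.null(identity)) {
        stop("mixed anchor clade for gene ", g,
             " and no identity matrix supplied for the fallback")
      }
      ids <- identity[g, anchor_ids]
      out[g] <- unname(grp_of_anchor[anchor_ids[which.max(ids)]])
    }
  }
  out
}
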