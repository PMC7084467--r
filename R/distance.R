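# Poisson-corrected distances and percent identities from a multiple
# alignment, under pairwise deletion (for every sequence pair, columns
# gapped in either row are excluded from the distance; columns gapped in
# both are additionally excluded from the identity denominator).

#' Poisson distance between two alignment rows
#'
#' Under pairwise deletion, `p` is the proportion of differing residues
#' among columns ungapped in both rows and the Poisson-corrected distance
#' is `d = -ln(1 - p)`. `p = 1` has no finite correction and is flagged by
#' an infinite `d`.
#'
#' @param msa named character vector of aligned sequences
#' @param i,j row names or indices
#' @return list with `p`, `d` and `n_sites` (compared columns)
#' @export
poisson_distance <- function(msa, i, j) {
  m <- encode_msa(msa)
  if (is.character(i)) i <- match(i, rownames(m))
  if (is.character(j)) j <- match(j, rownames(m))
  a <- m[i, ]
  b <- m[j, ]
  keep <- a > 0 & b > 0
  n <- sum(keep)
  if (n == 0) stop("rows share no ungapped column")
  p <- sum(a[keep] != b[keep] | a[keep] == X_CODE) / n
  list(p = p, d = if (p < 1) -log(1 - p) else Inf, n_sites = n)
}

#' Pairwise distance and identity matrices from a multiple alignment
#'
#' Computes, for every pair of rows: the proportion of differing sites `p`
#' and Poisson distance `d = -ln(1 - p)` under pairwise deletion, the number
#' of compared sites, and the full-length percent identity (identical
#' residues over all columns where at least one row has a residue, so gaps
#' count against identity and X never matches).
#'
#' @param msa named character vector of aligned sequences
#' @return list of square matrices `p`, `d`, `n_sites`, `identity`
#' @export
poisson_distance_matrix <- function(msa) {
  m <- encode_msa(msa)
  st <- msa_pair_stats(m, X_CODE)
  p <- st$ndiff / pmax(st$ncomp, 1)
  p[st$ncomp == 0] <- NA_real_
  d <- ifelse(is.na(p), Inf, ifelse(p < 1, -log(1 - p), Inf))
  identity <- 100 * st$nid / pmax(st$ncov, 1)
  diag(p) <- 0
  diag(d) <- 0
  diag(identity) <- 100
  nm <- names(msa)
  dimnames(p) <- dimnames(d) <- dimnames(identity) <- list(nm, nm)
  ns <- st$ncomp
  dimnames(ns) <- list(nm, nm)
  list(p = p, d = d, n_sites = ns, identity = identity)
}
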