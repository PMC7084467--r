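# Pairwise and progressive protein alignment, and protein-guided codon
# alignment. The dynamic-programming core (Gotoh three-state affine
# alignment on a precomputed column-score matrix) lives in src/kernels.cpp
# and is shared between pairwise and profile-profile alignment, so the
# two-sequence progressive case reduces exactly to global_align().

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties.
#' Percent identity is the number of identically aligned residues divided by
#' the full alignment length (so gap columns count against identity, and the
#' ambiguity character X never matches). Tie-breaking among co-optimal
#' alignments is deterministic: aligned columns are preferred over gaps, and
#' a gap in `a` over a gap in `b`.
#'
#' @param a,b amino-acid sequences (single strings, no gaps)
#' @param scoring scoring scheme from [alignment_scoring()]
#' @return object of class `pair_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `identity` (0-100) and
#'   `score`
#' @examples
#' aln <- global_align("MACDE", "MACE")
#' aln$identity
#' @export
global_align <- function(a, b, scoring = alignment_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  ca <- encode_aa(a, "a", allow_gap = FALSE)
  cb <- encode_aa(b, "b", allow_gap = FALSE)
  cell <- scoring$sub[ca, cb, drop = FALSE]
  path <- gotoh_align(cell, scoring$gap_open, scoring$gap_ext)
  aa <- ifelse(path$a > 0, strsplit(a, "")[[1]][pmax(path$a, 1)], "-")
  bb <- ifelse(path$b > 0, strsplit(b, "")[[1]][pmax(path$b, 1)], "-")
  out <- list(aligned_a = paste(aa, collapse = ""),
              aligned_b = paste(bb, collapse = ""),
              identity = pair_identity(aa, bb),
              score = path$score)
  class(out) <- "pair_alignment"
  out
}

pair_identity <- function(chars_a, chars_b) {
  len <- length(chars_a)
  id <- sum(chars_a == chars_b & chars_a != "-" & chars_a != "X")
  100 * id / len
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("identity: %.1f%%  score: %.1f\n", x$identity, x$score))
  invisible(x)
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment: sequences are clustered by shared
#' 3-mer fraction (UPGMA), then profiles are merged bottom-up with the same
#' affine-gap dynamic program used by [global_align()]; profile columns are
#' scored by the frequency-weighted average substitution score. The result
#' is deterministic given the input order, every row ungaps back to its
#' input, and for exactly two sequences the alignment equals
#' [global_align()].
#'
#' @param seqs named character vector of >= 2 amino-acid sequences
#' @param scoring scoring scheme from [alignment_scoring()]
#' @return named character vector of equal-length aligned (gapped) sequences
#' @export
msa_progressive <- function(seqs, scoring = alignment_scoring()) {
  if (length(seqs) < 2) stop("progressive alignment needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  if (any(!nzchar(seqs))) stop("cannot align an empty sequence")
  coded <- lapply(seq_along(seqs), function(i) {
    encode_aa(seqs[[i]], names(seqs)[i], allow_gap = FALSE)
  })

  n <- length(seqs)
  merges <- if (n == 2) {
    matrix(c(-1L, -2L), nrow = 1)
  } else {
    stats::hclust(kmer_distance(seqs), method = "average")$merge
  }

  # each alignment is an integer matrix, rows named
  alns <- vector("list", nrow(merges))
  single <- function(i) {
    m <- matrix(coded[[i]], nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  }
  fetch <- function(k) if (k < 0) single(-k) else alns[[k]]
  for (r in seq_len(nrow(merges))) {
    alns[[r]] <- merge_profiles(fetch(merges[r, 1]), fetch(merges[r, 2]),
                                scoring)
  }
  final <- alns[[nrow(merges)]]
  final <- final[names(seqs), , drop = FALSE]
  out <- vapply(seq_len(nrow(final)), function(i) decode_aa(final[i, ]),
                character(1))
  names(out) <- rownames(final)
  out
}

# fraction of shared 3-mers (relative to the shorter sequence)
kmer_distance <- function(seqs, k = 3) {
  words <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  all_words <- unique(unlist(words))
  inc <- matrix(0L, length(seqs), length(all_words))
  for (i in seq_along(seqs)) inc[i, match(words[[i]], all_words)] <- 1L
  shared <- tcrossprod(inc)
  sizes <- vapply(words, length, integer(1))
  denom <- outer(sizes, sizes, pmin)
  d <- 1 - shared / pmax(denom, 1)
  dimnames(d) <- list(names(seqs), names(seqs))
  stats::as.dist(d)
}

merge_profiles <- function(A, B, scoring) {
  fa <- profile_freq(A)
  fb <- profile_freq(B)
  cell <- crossprod(scoring$sub %*% fa, fb)   # WA x WB column scores
  path <- gotoh_align(cell, scoring$gap_open, scoring$gap_ext)
  w <- length(path$a)
  out <- matrix(0L, nrow(A) + nrow(B), w)
  out[seq_len(nrow(A)), path$a > 0] <- A[, path$a[path$a > 0], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), path$b > 0] <- B[, path$b[path$b > 0], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

# residue frequencies per column (gaps contribute nothing; denominator is
# the number of sequences, so gappy columns score low against everything)
profile_freq <- function(A) {
  w <- ncol(A)
  f <- matrix(0, length(AA_LETTERS), w)
  for (j in seq_len(w)) {
    tab <- tabulate(A[, j], nbins = length(AA_LETTERS))
    f[, j] <- tab / nrow(A)
  }
  f
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue is replaced by its codon from the corresponding
#' coding sequence and each gap by `---`. A terminal stop codon on a CDS is
#' permitted and trimmed; any other disagreement between a CDS and its
#' protein row is an error naming the offending position.
#'
#' @param protein_msa named character vector of aligned protein sequences
#' @param cds_by_gene named character vector of coding sequences (names must
#'   cover the alignment rows)
#' @return named character vector of aligned codon sequences, each 3x the
#'   protein alignment length
#' @export
codon_backtranslate <- function(protein_msa, cds_by_gene) {
  missing <- setdiff(names(protein_msa), names(cds_by_gene))
  if (length(missing)) {
    stop("no CDS supplied for: ", paste(missing, collapse = ", "))
  }
  out <- vapply(names(protein_msa), function(g) {
    row <- protein_msa[[g]]
    cds <- trim_stop(cds_by_gene[[g]], g)
    prot <- gsub("-", "", row, fixed = TRUE)
    if (nchar(cds) != 3 * nchar(prot)) {
      stop(sprintf("CDS of %s has %d nt but its protein row has %d residues",
                   g, nchar(cds), nchar(prot)))
    }
    tr <- translate_cds(cds, g)
    mism <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])
    if (length(mism)) {
      stop(sprintf("CDS of %s does not translate to its protein row at residue %d",
                   g, mism[1]))
    }
    codons <- split_codons(cds)
    chars <- strsplit(row, "")[[1]]
    cells <- rep("---", length(chars))
    cells[chars != "-"] <- codons
    paste(cells, collapse = "")
  }, character(1))
  names(out) <- names(protein_msa)
  out
}

trim_stop <- function(cds, name) {
  n <- nchar(cds)
  if (n %% 3 != 0) {
    stop(sprintf("CDS length of %s (%d) is not a multiple of 3", name, n))
  }
  last <- substring(cds, n - 2, n)
  if (!is.na(genetic_code()[last]) && genetic_code()[last] == "*") {
    cds <- substring(cds, 1, n - 3)
  }
  cds
}
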