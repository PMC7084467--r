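# Within-species duplicate pairs: tandem/segmental classification from
# annotated gene order, Nei-Gojobori (1986) dN/dS, and divergence dating
# via T = dS / (2 * lambda).

#' Enumerate within-species duplicate pairs of each POL
#'
#' Members of a POL within one species are paralogs; every unordered pair
#' is emitted. For same-chromosome pairs the number of intervening genes is
#' counted over the full annotation (all annotated genes, any strand, in
#' start-coordinate order - not only family members), and a pair separated
#' by four or fewer genes is a tandem duplicate; everything else (five or
#' more intervening genes, different chromosomes, scaffold placements, or
#' missing coordinates) is segmental. Pairs on unplaced scaffolds are never
#' tandem; pairs with missing coordinates carry a warning flag.
#'
#' @param pols a `pol_table` from [name_pols()]
#' @param gene_order data.frame with `gene_id`, `chrom`, `start` covering
#'   the full annotation (family and non-family genes)
#' @param scaffold_regex chromosome names matching this pattern are treated
#'   as unplaced scaffolds
#' @return data.frame: `pol_id`, `species`, `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `intervening`, `mode`, `coord_missing`
#' @export
find_duplicate_pairs <- function(pols, gene_order,
                                 scaffold_regex = "^(scaffold|sc[_0-9])") {
  ord <- gene_order[!is.na(gene_order$start), ]
  rank <- setNames(rep(NA_integer_, nrow(ord)), ord$gene_id)
  for (ix in split(seq_len(nrow(ord)), as.character(ord$chrom))) {
    rank[ord$gene_id[ix]] <- rank(ord$start[ix], ties.method = "first")
  }
  chrom_of <- setNames(as.character(ord$chrom), ord$gene_id)

  rows <- list()
  for (key in unique(paste(pols$pol_id, pols$species, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- pols[pols$pol_id == parts[1] & pols$species == parts[2], ]
    if (nrow(sub) < 2) next
    prs <- combn(sort(sub$gene_id), 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]
      b <- prs[2, k]
      ca <- chrom_of[a]
      cb <- chrom_of[b]
      missing <- is.na(ca) || is.na(cb)
      if (missing) {
        inter <- NA_integer_
        mode <- "segmental"
      } else if (ca != cb) {
        inter <- NA_integer_
        mode <- "segmental"
      } else {
        inter <- abs(rank[[a]] - rank[[b]]) - 1L
        scafpair <- grepl(scaffold_regex, ca, ignore.case = TRUE)
        mode <- if (!scafpair && inter <= 4) "tandem" else "segmental"
      }
      rows[[length(rows) + 1]] <-
        data.frame(pol_id = parts[1], species = parts[2],
                   gene_a = a, gene_b = b,
                   chrom_a = ifelse(missing, NA, ca),
                   chrom_b = ifelse(missing, NA, cb),
                   intervening = inter, mode = mode,
                   coord_missing = missing, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pol_id = character(), species = character(),
                      gene_a = character(), gene_b = character(),
                      chrom_a = character(), chrom_b = character(),
                      intervening = integer(), mode = character(),
                      coord_missing = logical()))
  }
  out <- do.call(rbind, rows)
  if (any(out$coord_missing)) {
    warning(sum(out$coord_missing), " pair(s) with missing coordinates ",
            "classified segmental")
  }
  rownames(out) <- NULL
  out
}

#' Per-gene duplication labels
#'
#' A gene is `tandem` if at least one of its within-POL same-species pairs
#' is tandem, else `segmental` if it has any pair, else `none` (the gene is
#' its species' only copy in its POL).
#'
#' @param pairs data.frame from [find_duplicate_pairs()]
#' @param pols a `pol_table` (supplies the gene universe)
#' @return named character vector gene id -> label
#' @export
gene_duplication_labels <- function(pairs, pols) {
  lab <- setNames(rep("none", nrow(pols)), pols$gene_id)
  for (i in seq_len(nrow(pairs))) {
    for (g in c(pairs$gene_a[i], pairs$gene_b[i])) {
      if (pairs$mode[i] == "tandem") {
        lab[g] <- "tandem"
      } else if (lab[g] == "none") {
        lab[g] <- "segmental"
      }
    }
  }
  lab
}

# --- Nei-Gojobori (1986) ---------------------------------------------------

# per-codon synonymous-site fractions: for each position the fraction of
# the three single-nucleotide neighbors that preserve the amino acid
# (changes to stop codons are non-synonymous), so S + N = 3 per codon
ng86_tables <- function() {
  if (!is.null(.famtrace_env$ng86)) return(.famtrace_env$ng86)
  gc <- genetic_code()
  codons <- names(gc)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, ch[pos])) {
        alt <- ch
        alt[pos] <- nt
        altc <- paste(alt, collapse = "")
        if (gc[[altc]] != "*" && gc[[altc]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    syn[cd] <- s
  }
  .famtrace_env$ng86 <- list(syn = syn, gc = gc)
  .famtrace_env$ng86
}

# average synonymous/nonsynonymous step counts over all orderings of the
# single-nucleotide steps from codon a to codon b, excluding paths through
# stop codons (if every ordering passes through a stop, all orderings
# count)
codon_path_counts <- function(a, b) {
  key <- paste(a, b)
  cache <- .famtrace_env$path_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .famtrace_env$path_cache <- cache
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diff_pos <- which(ca != cb)
  paths <- perms(diff_pos)
  tally <- matrix(0, nrow = length(paths), ncol = 2,
                  dimnames = list(NULL, c("syn", "nonsyn")))
  valid <- logical(length(paths))
  for (i in seq_along(paths)) {
    cur <- ca
    ok <- TRUE
    sd <- 0
    nd <- 0
    for (pos in paths[[i]]) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") ok <- FALSE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tally[i, ] <- c(sd, nd)
    valid[i] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, length(paths))
  res <- colMeans(tally[use, , drop = FALSE])
  cache[[key]] <- res
  res
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori dN/dS for a pair of aligned coding sequences
#'
#' Site counts: each codon contributes a synonymous-site fraction equal to
#' the fraction of its nine single-nucleotide neighbors (per position,
#' three alternatives) that preserve the amino acid; counts are averaged
#' over the two sequences, so `S + N = 3 x` codons. Difference counts:
#' codons differing at several positions are resolved by averaging the
#' synonymous/nonsynonymous step counts over all orderings of the single
#' steps, excluding orderings that pass through a stop codon (if all do,
#' every ordering counts). Proportions `pS = Sd/S`, `pN = Nd/N` receive the
#' Jukes-Cantor correction `d = -(3/4) ln(1 - (4/3) p)`, undefined
#' (`valid = FALSE`) when the log argument is not positive.
#'
#' @param cds_a,cds_b gap-free aligned coding sequences of equal length, a
#'   multiple of 3, without stop codons (drop gapped codons before calling)
#' @return object of class `ng86`: list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `n_codons`, `valid`
#' @export
ng86 <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences differ in length")
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE)) {
    stop("gapped codons must be dropped before calling ng86")
  }
  translate_cds(cds_a, "cds_a")  # validates length, alphabet, stops
  translate_cds(cds_b, "cds_b")
  tabs <- ng86_tables()
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  n_cod <- length(ca)
  S <- (sum(tabs$syn[ca]) + sum(tabs$syn[cb])) / 2
  N <- 3 * n_cod - S
  Sd <- 0
  Nd <- 0
  for (i in which(ca != cb)) {
    cnt <- codon_path_counts(ca[i], cb[i])
    Sd <- Sd + cnt[["syn"]]
    Nd <- Nd + cnt[["nonsyn"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  dS <- jc(pS)
  dN <- jc(pN)
  out <- list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
              dS = dS, dN = dN, n_codons = n_cod, valid = !is.na(dS))
  class(out) <- "ng86"
  out
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf("NG86: %d codons  S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS=%.4f pN=%.4f dS=%s dN=%s%s\n", x$pS, x$pN,
              format(x$dS), format(x$dN),
              if (!x$valid) "  [dS undefined]" else ""))
  invisible(x)
}

#' Divergence time from a synonymous substitution rate
#'
#' `T = dS / (2 * lambda) * 1e-6` million years, where `lambda` is the
#' species' synonymous substitution rate per site per year.
#'
#' @param dS synonymous substitutions per synonymous site (vectorized; `NA`
#'   propagates)
#' @param lambda rate per synonymous site per year (> 0)
#' @return divergence time in million years
#' @examples
#' divergence_time(1.2528, 1.08e-8)  # 58 MY
#' @export
divergence_time <- function(dS, lambda) {
  stopifnot(all(lambda > 0))
  ifelse(is.na(dS), NA_real_, dS / (2 * lambda) * 1e-6)
}

#' Compute NG86 statistics and dates for duplicate pairs
#'
#' For each pair: global protein alignment, protein-guided codon alignment,
#' pairwise deletion of codons aligned to a gap in either sequence, NG86,
#' then `T = dS/(2 lambda)` with the species' rate.
#'
#' @param pairs data.frame from [find_duplicate_pairs()]
#' @param genes data.frame with `gene_id`, `protein`, `cds`
#' @param rates named numeric vector species -> lambda (per synonymous site
#'   per year)
#' @param scoring alignment scoring scheme
#' @return `pairs` with appended columns `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `valid`, `T_my`
#' @export
date_duplications <- function(pairs, genes, rates,
                              scoring = alignment_scoring()) {
  if (any(rates <= 0)) stop("all rates must be positive")
  prot <- setNames(genes$protein, genes$gene_id)
  cds <- setNames(genes$cds, genes$gene_id)
  stats <- matrix(NA_real_, nrow(pairs), 10,
                  dimnames = list(NULL, c("S", "N", "Sd", "Nd", "pS", "pN",
                                          "dS", "dN", "valid", "T_my")))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    aln <- global_align(prot[[a]], prot[[b]], scoring)
    codon <- codon_backtranslate(
      setNames(c(aln$aligned_a, aln$aligned_b), c(a, b)),
      cds[c(a, b)])
    dropped <- drop_gapped_codons(codon[[a]], codon[[b]])
    if (nchar(dropped[1]) == 0) next
    res <- ng86(dropped[1], dropped[2])
    lam <- rates[[pairs$species[i]]]
    if (is.null(lam)) stop("no rate for species ", pairs$species[i])
    stats[i, ] <- c(res$S, res$N, res$Sd, res$Nd, res$pS, res$pN,
                    res$dS, res$dN, as.numeric(res$valid),
                    if (res$valid) divergence_time(res$dS, lam) else NA_real_)
  }
  out <- cbind(pairs, as.data.frame(stats))
  out$valid <- !is.na(out$valid) & out$valid == 1
  out
}

drop_gapped_codons <- function(a, b) {
  ca <- split_codons(a)
  cb <- split_codons(b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  c(paste(ca[keep], collapse = ""), paste(cb[keep], collapse = ""))
}
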