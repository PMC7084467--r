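# Independent oracles, written before the implementations they check and
# kept free of any code path under test.

# --- affine global alignment score by memoized recursion -------------------
# Cost model: gap of length L costs open + L * ext; terminal gaps count.
# States track what the previous alignment column was, so the recursion is
# a direct transcription of the cost definition rather than a Gotoh sweep.
oracle_align_score <- function(a, b, sub, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j, prev)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best, rec(i - 1, j - 1, "m") + sub[av[i], bv[j]])
    }
    if (j > 0) {
      gap_cost <- ext + if (prev == "ga") 0 else open
      best <- max(best, rec(i, j - 1, "ga") - gap_cost)
    }
    if (i > 0) {
      gap_cost <- ext + if (prev == "gb") 0 else open
      best <- max(best, rec(i - 1, j, "gb") - gap_cost)
    }
    memo[[key]] <- best
    best
  }
  rec(length(av), length(bv), "m")
}

# --- Nei-Gojobori by direct enumeration ------------------------------------
oracle_ng86 <- function(cds_a, cds_b) {
  gc <- Biostrings::GENETIC_CODE
  codon_split <- function(x) {
    n <- nchar(x)
    substring(x, seq(1, n, 3), seq(3, n, 3))
  }
  syn_sites_of <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
        alt <- ch
        alt[pos] <- nt
        ac <- paste(alt, collapse = "")
        if (gc[[ac]] != "*" && gc[[ac]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (k in seq_along(v)) {
      for (tail in all_orders(v[-k])) res[[length(res) + 1]] <- c(v[k], tail)
    }
    res
  }
  ca <- codon_split(cds_a)
  cb <- codon_split(cds_b)
  S <- (sum(vapply(ca, syn_sites_of, numeric(1))) +
          sum(vapply(cb, syn_sites_of, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0
  Nd <- 0
  for (k in which(ca != cb)) {
    c1 <- strsplit(ca[k], "")[[1]]
    c2 <- strsplit(cb[k], "")[[1]]
    pos <- which(c1 != c2)
    res <- matrix(0, 0, 2)
    ok <- logical(0)
    for (ordv in all_orders(pos)) {
      cur <- c1
      sd_i <- 0
      nd_i <- 0
      valid <- TRUE
      for (p in ordv) {
        nxt <- cur
        nxt[p] <- c2[p]
        aa_cur <- gc[[paste(cur, collapse = "")]]
        aa_nxt <- gc[[paste(nxt, collapse = "")]]
        if (aa_cur == "*" || aa_nxt == "*") valid <- FALSE
        if (aa_cur == aa_nxt) sd_i <- sd_i + 1 else nd_i <- nd_i + 1
        cur <- nxt
      }
      res <- rbind(res, c(sd_i, nd_i))
      ok <- c(ok, valid)
    }
    use <- if (any(ok)) ok else rep(TRUE, length(ok))
    Sd <- Sd + mean(res[use, 1])
    Nd <- Nd + mean(res[use, 2])
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# random CDS without stops, standard code, ATG start
random_test_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

mutate_cds <- function(cds, n_mut) {
  gc <- Biostrings::GENETIC_CODE
  nts <- strsplit(cds, "")[[1]]
  tries <- 0
  done <- 0
  while (done < n_mut && tries < 200) {
    tries <- tries + 1
    pos <- sample(4:length(nts), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), nts[pos]), 1)
    ci <- (pos - 1) %/% 3
    cod <- nts[(ci * 3 + 1):(ci * 3 + 3)]
    cod[pos - ci * 3] <- alt
    if (gc[[paste(cod, collapse = "")]] == "*") next
    nts[pos] <- alt
    done <- done + 1
  }
  paste(nts, collapse = "")
}

# --- exhaustive topology search under least squares ------------------------
# For every unrooted topology on the taxa of D, fit branch lengths by
# ordinary least squares on the path-length design matrix and return the
# topology with minimal residual sum of squares.
oracle_best_topology <- function(D) {
  taxa <- rownames(D)
  n <- length(taxa)
  stopifnot(n >= 4, n <= 6)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  pair_idx <- t(combn(n, 2))
  best <- NULL
  best_rss <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]  # multiPhylo [[ re-attaches the shared tip labels
    ne <- nrow(tr$edge)
    A <- matrix(0, nrow(pair_idx), ne)
    for (r in seq_len(nrow(pair_idx))) {
      i <- match(taxa[pair_idx[r, 1]], tr$tip.label)
      j <- match(taxa[pair_idx[r, 2]], tr$tip.label)
      np <- ape::nodepath(tr, i, j)
      for (s in seq_len(length(np) - 1)) {
        e <- which((tr$edge[, 1] == np[s] & tr$edge[, 2] == np[s + 1]) |
                     (tr$edge[, 2] == np[s] & tr$edge[, 1] == np[s + 1]))
        A[r, e] <- 1
      }
    }
    y <- D[cbind(pair_idx[, 1], pair_idx[, 2])]
    fit <- qr.solve(crossprod(A) + diag(1e-10, ne), crossprod(A, y))
    rss <- sum((A %*% fit - y)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- tr
      best$edge.length <- as.numeric(fit)
    }
  }
  list(tree = best, rss = best_rss)
}

# random additive distance matrix from a random unrooted tree
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
  D <- cophenetic(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

# --- protein helpers -------------------------------------------------------
random_test_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

mutate_protein <- function(p, n_mut) {
  v <- strsplit(p, "")[[1]]
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (pos in sample(length(v), min(n_mut, length(v)))) {
    v[pos] <- sample(setdiff(aas, v[pos]), 1)
  }
  paste(v, collapse = "")
}
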