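# Candidate screening: keep authentic family members, log every exclusion
# with the first failing rule in a fixed order.

#' Screening configuration
#'
#' Thresholds for [screen_candidates()]. The length bounds are inclusive:
#' proteins of exactly `min_len` or `max_len` residues are kept (strictly
#' shorter / longer ones are excluded). The motif check passes when the best
#' ungapped window in the C-terminal half matches at least
#' `motif_min_fraction` of the aligned consensus columns and covers at least
#' `motif_min_coverage` of the 44 columns.
#'
#' @param min_len minimum protein length in residues (default 350)
#' @param max_len maximum protein length (default 600)
#' @param require_met_start exclude proteins not starting with methionine
#' @param motif_consensus 44-residue consensus motif
#' @param motif_min_fraction minimum fraction of aligned consensus positions
#'   matched (default 0.6)
#' @param motif_min_coverage minimum fraction of the 44 consensus columns
#'   aligned (default 0.9)
#' @return list of class `screen_config`
#' @export
screen_config <- function(min_len = 350, max_len = 600,
                          require_met_start = TRUE,
                          motif_consensus = default_motif(),
                          motif_min_fraction = 0.6,
                          motif_min_coverage = 0.9) {
  stopifnot(min_len > 0, min_len <= max_len,
            motif_min_fraction > 0, motif_min_fraction <= 1,
            motif_min_coverage > 0, motif_min_coverage <= 1,
            nchar(motif_consensus) == 44)
  structure(list(min_len = min_len, max_len = max_len,
                 require_met_start = require_met_start,
                 motif_consensus = motif_consensus,
                 motif_min_fraction = motif_min_fraction,
                 motif_min_coverage = motif_min_coverage),
            class = "screen_config")
}

#' Default diagnostic C-terminal motif
#'
#' A 44-residue consensus in the style of the plant secondary product
#' glycosyltransferase (PSPG) box that marks family 1 UGTs. It is the
#' default motif embedded by the simulator and searched by the screen.
#'
#' @return a 44-character string
#' @export
default_motif <- function() {
  "WAPQVEVLAHPAVGCFVTHCGWNSTLESLSSGVPMVAWPLYAEQ"
}

#' Scan a protein for the diagnostic motif
#'
#' Slides the 44-residue consensus ungapped over the C-terminal half of the
#' protein (windows may overhang the C terminus; overhanging columns count
#' against coverage). The best window maximizes the number of matching
#' positions; X never matches.
#'
#' @param protein amino-acid sequence
#' @param consensus 44-residue consensus
#' @param config a [screen_config()]; supplies the pass thresholds
#' @return list with `offset` (1-based start of the best window), `fraction`
#'   (matches over aligned columns), `coverage` (aligned columns over 44)
#'   and `pass`
#' @export
motif_scan <- function(protein, consensus = default_motif(),
                       config = screen_config(motif_consensus = consensus)) {
  stopifnot(nchar(consensus) == 44)
  L <- nchar(protein)
  k <- nchar(consensus)
  if (L < k) {
    return(list(offset = NA_integer_, fraction = 0, coverage = 0, pass = FALSE))
  }
  pc <- strsplit(protein, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  first <- max(1L, floor(L / 2) + 1L)  # windows start in the C-terminal half
  starts <- seq.int(first, L)
  best <- c(matches = -1, overlap = 0, offset = NA)
  for (s in starts) {
    ov <- min(k, L - s + 1L)
    w <- pc[s:(s + ov - 1L)]
    cw <- cc[seq_len(ov)]
    m <- sum(w == cw & w != "X")
    if (m > best["matches"] ||
        (m == best["matches"] && ov > best["overlap"])) {
      best <- c(matches = m, overlap = ov, offset = s)
    }
  }
  fraction <- unname(best["matches"] / best["overlap"])
  coverage <- unname(best["overlap"] / k)
  list(offset = unname(best["offset"]), fraction = fraction,
       coverage = coverage,
       pass = fraction >= config$motif_min_fraction &&
         coverage >= config$motif_min_coverage)
}

#' Screen candidate proteins
#'
#' Applies the family screening rules in a fixed order and stops at the
#' first failure per gene: (1) shorter than `min_len`, (2) longer than
#' `max_len`, (3) first residue not methionine, (4) incomplete diagnostic
#' motif, (5) 100% full-length identity with another same-species protein
#' (the lexicographically smallest gene id of each identical set is kept).
#'
#' @param proteins data.frame with columns `gene_id`, `species`, `protein`
#' @param config a [screen_config()]
#' @return list with `kept` (subset of the input rows) and `exclusions`
#'   (data.frame `gene_id`, `reason`, `detail`); together they partition the
#'   input
#' @export
screen_candidates <- function(proteins, config = screen_config()) {
  stopifnot(is.data.frame(proteins),
            all(c("gene_id", "species", "protein") %in% names(proteins)))
  if (nrow(proteins) == 0) {
    return(list(kept = proteins,
                exclusions = data.frame(gene_id = character(),
                                        reason = character(),
                                        detail = character())))
  }
  if (anyDuplicated(proteins$gene_id)) stop("duplicated gene ids in input")
  for (i in seq_len(nrow(proteins))) {
    p <- proteins$protein[i]
    if (!nzchar(p)) stop("empty sequence for gene ", proteins$gene_id[i])
    encode_aa(p, proteins$gene_id[i], allow_gap = FALSE)  # validates
  }

  len <- nchar(proteins$protein)
  reason <- rep(NA_character_, nrow(proteins))
  detail <- rep(NA_character_, nrow(proteins))

  short <- len < config$min_len
  reason[short] <- "short"
  detail[short] <- sprintf("%d aa < %d", len[short], config$min_len)

  long <- is.na(reason) & len > config$max_len
  reason[long] <- "long"
  detail[long] <- sprintf("%d aa > %d", len[long], config$max_len)

  if (config$require_met_start) {
    nm <- is.na(reason) & substring(proteins$protein, 1, 1) != "M"
    reason[nm] <- "non_met_start"
    detail[nm] <- sprintf("first residue %s",
                          substring(proteins$protein[nm], 1, 1))
  }

  for (i in which(is.na(reason))) {
    sc <- motif_scan(proteins$protein[i], config$motif_consensus, config)
    if (!sc$pass) {
      reason[i] <- "incomplete_motif"
      detail[i] <- sprintf("best window fraction %.2f coverage %.2f",
                           sc$fraction, sc$coverage)
    }
  }

  # dedup 100%-identical same-species full-length pairs among survivors
  surv <- which(is.na(reason))
  key <- paste(proteins$species[surv], proteins$protein[surv], sep = "\r")
  ord <- surv[order(key, proteins$gene_id[surv])]
  key_ord <- paste(proteins$species[ord], proteins$protein[ord], sep = "\r")
  dup <- duplicated(key_ord)
  if (any(dup)) {
    keep_of <- ord[match(key_ord[dup], key_ord)]
    reason[ord[dup]] <- "duplicate_identical"
    detail[ord[dup]] <- sprintf("identical to kept gene %s",
                                proteins$gene_id[keep_of])
  }

  kept <- proteins[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  excl <- data.frame(gene_id = proteins$gene_id[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     detail = detail[!is.na(reason)],
                     stringsAsFactors = FALSE)
  list(kept = kept, exclusions = excl)
}
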