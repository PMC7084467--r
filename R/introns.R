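# Intron-type classification of POLs and gain/loss calls per gene. Intron
# counts are coding-sequence introns (exon features minus one in the
# annotation); UTR introns are ignored upstream at parse time.

#' Classify a POL's intron type
#'
#' A POL represented in at least three species is a no-intron (one-intron)
#' POL when a strict majority of the represented species have modal intron
#' count 0 (1); modal ties within a species resolve toward the smaller
#' count. Everything else - including POLs seen in fewer than three
#' species, where the rule is undecidable - is a mixed-intron POL.
#'
#' @param members data.frame with columns `gene_id`, `species`, `introns`
#' @return one of `"no_intron"`, `"one_intron"`, `"mixed"`
#' @export
classify_pol_intron_type <- function(members) {
  if (nrow(members) == 0) stop("empty POL")
  stopifnot(all(members$introns >= 0))
  modes <- vapply(split(members$introns, members$species), function(x) {
    tab <- table(x)
    cnts <- as.integer(names(tab))
    min(cnts[tab == max(tab)])
  }, numeric(1))
  n_sp <- length(modes)
  if (n_sp < 3) return("mixed")
  if (sum(modes == 0) > n_sp / 2) return("no_intron")
  if (sum(modes == 1) > n_sp / 2) return("one_intron")
  "mixed"
}

#' Call intron gain/loss events within a POL
#'
#' Members that deviate from their POL's intron type are flagged: any
#' intron in a no-intron POL is a gain; zero introns in a one-intron POL is
#' a loss; and more than one intron is a gain in every POL type (so a
#' count of two or more is always `gained`).
#'
#' @param pol_type from [classify_pol_intron_type()]
#' @param members data.frame with `gene_id`, `species`, `introns`
#' @return data.frame `gene_id`, `species`, `introns`, `pol_type`, `event`
#'   (`none`, `gained` or `lost`)
#' @export
call_intron_events <- function(pol_type, members) {
  stopifnot(pol_type %in% c("no_intron", "one_intron", "mixed"))
  n <- members$introns
  event <- rep("none", nrow(members))
  if (pol_type == "no_intron") {
    event[n >= 1] <- "gained"
  } else if (pol_type == "one_intron") {
    event[n == 0] <- "lost"
    event[n >= 2] <- "gained"
  } else {
    event[n > 1] <- "gained"
  }
  data.frame(gene_id = members$gene_id, species = members$species,
             introns = n, pol_type = pol_type, event = event,
             stringsAsFactors = FALSE)
}

#' Intron calls for every POL in a table
#'
#' Convenience wrapper running [classify_pol_intron_type()] and
#' [call_intron_events()] per POL.
#'
#' @param pols a `pol_table` from [name_pols()]
#' @param introns named integer vector gene id -> intron count
#' @return data.frame with one row per gene: `pol_id`, `gene_id`,
#'   `species`, `introns`, `pol_type`, `event`
#' @export
intron_calls <- function(pols, introns) {
  miss <- setdiff(pols$gene_id, names(introns))
  if (length(miss)) {
    stop("intron counts missing for: ", paste(head(miss, 5), collapse = ", "))
  }
  out <- lapply(split(pols, pols$pol_id), function(sub) {
    members <- data.frame(gene_id = sub$gene_id, species = sub$species,
                          introns = unname(introns[sub$gene_id]),
                          stringsAsFactors = FALSE)
    calls <- call_intron_events(classify_pol_intron_type(members), members)
    calls$pol_id <- sub$pol_id[1]
    calls
  })
  out <- do.call(rbind, out)
  out <- out[order(out$pol_id, out$gene_id),
             c("pol_id", "gene_id", "species", "introns", "pol_type", "event")]
  rownames(out) <- NULL
  out
}
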