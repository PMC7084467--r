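# Shared alphabets, genetic-code tables and small helpers.

# 20 amino acids plus the ambiguity character X. Gap is coded 0 everywhere.
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")
X_CODE <- match("X", AA_LETTERS)

NUCS <- c("A", "C", "G", "T")

#' @noRd
aa_substitution_matrix <- function() {
  if (is.null(.famtrace_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .famtrace_env$blosum62 <- e$BLOSUM62[AA_LETTERS, AA_LETTERS]
  }
  .famtrace_env$blosum62
}

#' Default alignment scoring scheme
#'
#' BLOSUM62 substitution scores with affine gap penalties: a gap of length
#' L costs `gap_open + L * gap_ext`. Terminal gaps are penalized.
#'
#' @param gap_open gap opening penalty (positive number, default 10)
#' @param gap_ext gap extension penalty (positive number, default 0.5)
#' @return list with elements `sub` (21 x 21 substitution matrix over the
#'   20 amino acids plus X), `gap_open` and `gap_ext`
#' @export
alignment_scoring <- function(gap_open = 10, gap_ext = 0.5) {
  stopifnot(gap_open >= 0, gap_ext >= 0)
  list(sub = aa_substitution_matrix(), gap_open = gap_open, gap_ext = gap_ext)
}

# Encode an amino-acid string (possibly gapped) as integer codes, 0 = gap.
# Unknown characters are an error naming the sequence.
encode_aa <- function(seq, name = "sequence", allow_gap = TRUE) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, AA_LETTERS)
  gap <- ch == "-"
  if (allow_gap) code[gap] <- 0L
  bad <- is.na(code)
  if (any(bad)) {
    stop(sprintf("non-amino-acid character '%s' at position %d in %s",
                 ch[which(bad)[1]], which(bad)[1], name))
  }
  code
}

decode_aa <- function(code) {
  out <- rep("-", length(code))
  out[code > 0] <- AA_LETTERS[code[code > 0]]
  paste(out, collapse = "")
}

# Coded matrix (rows = sequences) from a named character vector of equal
# length (gapped) strings.
encode_msa <- function(aln) {
  stopifnot(length(unique(nchar(aln))) == 1)
  m <- t(vapply(seq_along(aln),
                function(i) encode_aa(aln[[i]], names(aln)[i]),
                integer(nchar(aln[[1]]))))
  rownames(m) <- names(aln)
  m
}

genetic_code <- function() {
  if (is.null(.famtrace_env$gcode)) {
    .famtrace_env$gcode <- Biostrings::GENETIC_CODE
  }
  .famtrace_env$gcode
}

# Translate an ungapped CDS (no terminal stop expected); errors on internal
# stops or length not a multiple of 3.
translate_cds <- function(cds, name = "cds") {
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0) {
    stop(sprintf("CDS length of %s (%d) is not a positive multiple of 3",
                 name, n))
  }
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa)) {
    stop(sprintf("invalid codon '%s' in %s", codons[which(is.na(aa))[1]], name))
  }
  if (any(aa == "*")) {
    stop(sprintf("internal stop codon at codon %d of %s",
                 which(aa == "*")[1], name))
  }
  paste(aa, collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# Percentage rounded half-up to `digits` decimals (round() rounds half to
# even, which does not reproduce conventional table percentages).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, format = "g", digits = 10))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
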