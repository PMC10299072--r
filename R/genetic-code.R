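#' Genetic-code helpers
#'
#' The package works under the invertebrate mitochondrial code (NCBI
#' translation table 5) by default: AGA/AGG encode Ser, ATA encodes Met,
#' TGA encodes Trp, and only TAA/TAG are stops, leaving 62 sense codons.
#' Code tables are taken from Biostrings and the synonymous-family
#' partition is derived programmatically, never hard-coded.
#'
#' @name genetic_code
NULL

BASES <- c("A", "C", "G", "T")

#' Fetch a genetic code as a named codon -> amino-acid vector
#'
#' @param code NCBI translation table id (default 5, invertebrate
#'   mitochondrial). Stops are encoded as `"*"`.
#' @return named character vector over the 64 codons.
#' @export
genetic_code <- function(code = 5) {
  tab <- tryCatch(Biostrings::getGeneticCode(as.character(code)),
                  error = function(e) NULL)
  if (is.null(tab)) {
    stop("unsupported translation table id: ", code, call. = FALSE)
  }
  tab
}

#' Synonymous-family partition of a genetic code
#'
#' @param code translation table id.
#' @return data.frame with columns `codon`, `aa`, `family_size` for the
#'   sense codons only.
#' @export
codon_families <- function(code = 5) {
  gc <- genetic_code(code)
  sense <- gc[gc != "*"]
  sizes <- table(sense)
  data.frame(
    codon = names(sense),
    aa = unname(sense),
    family_size = as.integer(sizes[sense]),
    stringsAsFactors = FALSE
  )
}

#' Translate an in-frame nucleotide string
#'
#' Codons containing characters outside ACGT translate to `NA`.
#'
#' @param seq nucleotide string, length a multiple of 3.
#' @param code translation table id.
#' @return character vector of single-letter amino acids (`"*"` = stop).
#' @export
translate_codons <- function(seq, code = 5) {
  codons <- split_codons(seq)
  gc <- genetic_code(code)
  aa <- unname(gc[codons])
  aa
}

# Split a sequence into complete codons, dropping a trailing partial codon.
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Reverse complement of a nucleotide string
#'
#' Accepts A, C, G, T, N and gap characters.
#'
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Vector of single characters for a sequence string.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_nucleotides <- function(seq, allow_gap = FALSE, what = "sequence") {
  ok <- c("A", "C", "G", "T", "N", if (allow_gap) "-")
  ch <- unique(seq_chars(toupper(seq)))
  bad <- setdiff(ch, ok)
  if (length(bad) > 0) {
    stop(what, " contains unsupported characters: ",
         paste(bad, collapse = ", "),
         " (only A/C/G/T/N", if (allow_gap) "/-", " are accepted)",
         call. = FALSE)
  }
  invisible(toupper(seq))
}
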