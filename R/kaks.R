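#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Counting-method estimator of nonsynonymous (Ka) and synonymous (Ks)
#' substitution rates on a codon-aware pairwise alignment: per-codon
#' synonymous/nonsynonymous site fractions from the genetic code in use,
#' multi-hit codon differences averaged over all minimal mutational
#' pathways (pathways through stop codons skipped), and a Jukes-Cantor
#' multiple-hit correction of the proportions.
#'
#' @name kaks
NULL

# synonymous site count of one codon: at each position, the fraction of
# non-stop single-base changes that preserve the amino acid. Denominators
# shrink when an alternative is a stop, so S + N = 3 per codon.
ng86_sites <- function(codon, code = 5) {
  gc <- genetic_code(code)
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- BASES[BASES != substring(codon, pos, pos)]
    muts <- vapply(alts, function(b) {
      m <- codon
      substring(m, pos, pos) <- b
      m
    }, "")
    keep <- gc[muts] != "*"
    if (!any(keep)) next
    s <- s + sum(gc[muts[keep]] == aa) / sum(keep)
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways (orderings of the differing positions).
ng86_diffs <- function(c1, c2, code = 5) {
  gc <- genetic_code(code)
  pos <- which(seq_chars(c1) != seq_chars(c2))
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(pos) else perm_list(pos)
  tally <- matrix(NA_real_, nrow = length(perms), ncol = 2)
  for (k in seq_along(perms)) {
    cur <- c1
    sd <- 0; ndif <- 0
    ok <- TRUE
    for (p in perms[[k]]) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else ndif <- ndif + 1
      cur <- nxt
    }
    if (ok) tally[k, ] <- c(sd, ndif)
  }
  valid <- !is.na(tally[, 1])
  if (!any(valid)) {
    # every ordering passes through a stop: fall back to averaging over
    # all orderings, counting the stop-crossing steps as nonsynonymous
    for (k in seq_along(perms)) {
      cur <- c1
      sd <- 0; ndif <- 0
      for (p in perms[[k]]) {
        nxt <- cur
        substring(nxt, p, p) <- substring(c2, p, p)
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else ndif <- ndif + 1
        cur <- nxt
      }
      tally[k, ] <- c(sd, ndif)
    }
    valid <- rep(TRUE, length(perms))
  }
  c(sd = mean(tally[valid, 1]), nd = mean(tally[valid, 2]))
}

perm_list <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perm_list(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka, Ks and their ratio for one codon-aligned pair
#'
#' @param seq1,seq2 in-frame aligned nucleotide strings of equal length
#'   divisible by 3 (gaps in whole-codon units); terminal stop codons must
#'   be removed beforehand.
#' @param code translation table id (default 5).
#' @return list: `ka`, `ks`, `ratio` (`NA` with flag `ks_zero` when
#'   Ks = 0), `S`, `N`, `Sd`, `Nd`, `n_codons`.
#' @export
ng86_kaks <- function(seq1, seq2, code = 5) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2) || nchar(seq1) %% 3 != 0) {
    stop("sequences must be equal length, divisible by 3", call. = FALSE)
  }
  gc <- genetic_code(code)
  cod1 <- split_codons(seq1); cod2 <- split_codons(seq2)
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_along(cod1)) {
    c1 <- cod1[i]; c2 <- cod2[i]
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (gc[[c1]] == "*" || gc[[c2]] == "*") {
      stop("in-frame stop codon at codon position ", i, call. = FALSE)
    }
    used <- used + 1L
    S1 <- S1 + ng86_sites(c1, code)
    S2 <- S2 + ng86_sites(c2, code)
    d <- ng86_diffs(c1, c2, code)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  if (used == 0L) stop("no comparable codons", call. = FALSE)
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  ratio <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  out <- list(ka = ka, ks = ks, ratio = ratio, S = S, N = N,
              Sd = Sd, Nd = Nd, n_codons = used)
  if (!is.na(ks) && ks == 0) out$ks_zero <- TRUE
  out
}

# strip a terminal stop codon (complete only) from an in-frame sequence
strip_terminal_stop <- function(seq, code = 5) {
  gc <- genetic_code(code)
  L <- nchar(seq)
  if (L %% 3 != 0 || L < 3) return(substring(seq, 1, L - L %% 3))
  last <- substring(seq, L - 2, L)
  if (!grepl("[^ACGT]", last) && gc[[last]] == "*") {
    substring(seq, 1, L - 3)
  } else seq
}

#' Ka/Ks for all pairs of a codon-aware alignment
#'
#' Gap-only columns per pair are skipped inside [ng86_kaks()]; a trailing
#' stop codon shared by the alignment is removed.
#'
#' @param aln a codon-aware [alignment_set()].
#' @param code translation table id.
#' @return data.frame: gene, taxon1, taxon2, ka, ks, ka_ks.
#' @export
kaks_table <- function(aln, code = 5) {
  stopifnot(inherits(aln, "alignment_set"))
  if (!aln$codon_aware) {
    stop("Ka/Ks needs a codon-aware alignment", call. = FALSE)
  }
  gc <- genetic_code(code)
  L <- aln$length
  last <- substring(aln$seqs, L - 2, L)
  seqs <- aln$seqs
  if (all(!grepl("[^ACGT]", last) & unname(gc[last]) == "*")) {
    seqs <- substring(seqs, 1, L - 3)
  }
  # replace gap codons by NNN so they are skipped pairwise
  seqs <- gsub("---", "NNN", seqs, fixed = TRUE)
  pairs <- utils::combn(length(aln$taxa), 2)
  rows <- apply(pairs, 2, function(ij) {
    r <- ng86_kaks(seqs[ij[1]], seqs[ij[2]], code)
    data.frame(gene = aln$gene, taxon1 = aln$taxa[ij[1]],
               taxon2 = aln$taxa[ij[2]], ka = r$ka, ks = r$ks,
               ka_ks = r$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summaries of a Ka/Ks table
#'
#' Mean ratio over species pairs per gene, and mean over genes per
#' species — the two usual boxplot axes of comparative studies.
#'
#' @param kaks row-bound [kaks_table()] rows over genes.
#' @return list with data.frames `by_gene` and `by_taxon`.
#' @export
kaks_summaries <- function(kaks) {
  by_gene <- stats::aggregate(ka_ks ~ gene, kaks, mean, na.rm = TRUE,
                              na.action = stats::na.pass)
  long <- rbind(data.frame(taxon = kaks$taxon1, gene = kaks$gene,
                           ka_ks = kaks$ka_ks),
                data.frame(taxon = kaks$taxon2, gene = kaks$gene,
                           ka_ks = kaks$ka_ks))
  per_taxon_gene <- stats::aggregate(ka_ks ~ taxon + gene, long, mean,
                                     na.rm = TRUE,
                                     na.action = stats::na.pass)
  by_taxon <- stats::aggregate(ka_ks ~ taxon, per_taxon_gene, mean,
                               na.rm = TRUE, na.action = stats::na.pass)
  list(by_gene = by_gene, by_taxon = by_taxon)
}
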