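#' Nucleotide diversity and pairwise divergence
#'
#' Sliding-window nucleotide diversity (Pi), pairwise distances under
#' nested substitution models (p, JC69, K2P, TN93 and a pooled-composite
#' TN93 variant), and neighbor-joining trees from any distance matrix.
#'
#' @name divergence
NULL

#' Construct an alignment set
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   over A/C/G/T/N/-.
#' @param gene gene name label.
#' @param codon_aware alignment is in reading frame with gaps in
#'   whole-codon units.
#' @return object of class `alignment_set`.
#' @export
alignment_set <- function(seqs, gene = "", codon_aware = FALSE) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("aligned sequences must be named by taxon", call. = FALSE)
  }
  seqs <- vapply(seqs, function(s) check_nucleotides(s, allow_gap = TRUE),
                 "")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("aligned sequences differ in length",
                           call. = FALSE)
  if (codon_aware && L %% 3 != 0) {
    stop("codon-aware alignment length must be divisible by 3",
         call. = FALSE)
  }
  structure(list(gene = gene, taxa = names(seqs), seqs = unname(seqs),
                 length = L, codon_aware = codon_aware),
            class = "alignment_set")
}

#' Read a per-gene aligned FASTA into an alignment set
#'
#' @param path FASTA file.
#' @param gene label (defaults to the file stem).
#' @param codon_aware see [alignment_set()].
#' @export
read_alignment <- function(path, gene = NULL, codon_aware = FALSE) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  alignment_set(read_fasta(path), gene = gene, codon_aware = codon_aware)
}

aln_matrix <- function(aln) {
  matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE)),
         nrow = length(aln$taxa), byrow = TRUE,
         dimnames = list(aln$taxa, NULL))
}

# columns comparable under complete deletion: no gap/N in any row
complete_columns <- function(mat) {
  apply(mat, 2, function(col) all(col %in% BASES))
}

#' Nucleotide diversity (Pi)
#'
#' Mean over all unordered sequence pairs of the per-site difference
#' fraction. Under the default complete-deletion policy, columns with a
#' gap or N in any taxon are excluded alignment-wide; under pairwise
#' deletion each pair uses its own comparable columns.
#'
#' @param aln an [alignment_set()].
#' @param deletion "complete" (default) or "pairwise".
#' @return Pi value (NA with a warning when no comparable sites remain).
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  mat <- aln_matrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("nucleotide diversity needs >= 2 taxa", call. = FALSE)
  if (deletion == "complete") mat <- mat[, complete_columns(mat), drop = FALSE]
  pairs <- utils::combn(n, 2)
  d <- apply(pairs, 2, function(ij) {
    a <- mat[ij[1], ]; b <- mat[ij[2], ]
    ok <- a %in% BASES & b %in% BASES
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  })
  if (all(is.na(d))) {
    warning("no comparable sites; Pi undefined [W_NO_SITES]", call. = FALSE)
    return(NA_real_)
  }
  mean(d, na.rm = TRUE)
}

#' Sliding-window nucleotide diversity
#'
#' Windows tile `[0, L - w]` at the given step; when `L - w` is not a step
#' multiple a final window ending at the last site is appended and flagged.
#'
#' @param aln an [alignment_set()].
#' @param w window length in alignment columns (default 100).
#' @param step step size (default 25).
#' @param deletion gap policy per window, see [nucleotide_diversity()].
#' @return list of class `window_diversity`: `windows` (data.frame with
#'   `start`, `midpoint`, `pi`, `flagged_tail`), `overall_pi`, `gene`,
#'   `w`, `step`.
#' @export
sliding_window_pi <- function(aln, w = 100L, step = 25L,
                              deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (w < 2 || step < 1) stop("window must be >= 2 and step >= 1",
                              call. = FALSE)
  L <- aln$length
  if (L < w) stop("alignment shorter than the window", call. = FALSE)
  starts <- seq(0L, L - w, by = step)
  tail_flag <- rep(FALSE, length(starts))
  if ((L - w) %% step != 0L) {
    starts <- c(starts, L - w)
    tail_flag <- c(tail_flag, TRUE)
  }
  pis <- vapply(starts, function(s) {
    sub <- alignment_set(
      stats::setNames(substring(aln$seqs, s + 1L, s + w), aln$taxa),
      gene = aln$gene)
    suppressWarnings(nucleotide_diversity(sub, deletion))
  }, 0)
  structure(list(
    windows = data.frame(start = starts, midpoint = starts + w / 2,
                         pi = pis, flagged_tail = tail_flag),
    overall_pi = nucleotide_diversity(aln, deletion),
    gene = aln$gene, w = w, step = step), class = "window_diversity")
}

# transition/transversion partition for one pair of base vectors
pair_counts <- function(a, b) {
  ok <- a %in% BASES & b %in% BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  diff <- a != b
  pur <- c("A", "G")
  ts1 <- diff & a %in% pur & b %in% pur           # A<->G
  ts2 <- diff & !(a %in% pur) & !(b %in% pur)     # C<->T
  list(n = n, P1 = sum(ts1) / n, P2 = sum(ts2) / n,
       Q = sum(diff & !ts1 & !ts2) / n, p = mean(diff))
}

tn93_from_counts <- function(P1, P2, Q, freqs) {
  gA <- freqs["A"]; gC <- freqs["C"]; gG <- freqs["G"]; gT <- freqs["T"]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

#' Pairwise distance matrix under a substitution model
#'
#' Models: `p` (mismatch fraction), `JC69`, `K2P`, `TN93`, and
#' `MCL-composite` — the TN93 functional form with base frequencies
#' estimated once from all sequences pooled (a composite estimate applied
#' per pair). Pairs whose corrections leave the logarithm domain are
#' returned as `NA` and flagged in attribute `saturated` rather than
#' clamped.
#'
#' @param aln an [alignment_set()].
#' @param model one of p, JC69, K2P, TN93, MCL-composite.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln,
                              model = c("p", "JC69", "K2P", "TN93",
                                        "MCL-composite")) {
  model <- match.arg(model)
  mat <- aln_matrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("need >= 2 taxa", call. = FALSE)
  pooled_freqs <- NULL
  if (model == "MCL-composite") {
    ch <- as.vector(mat)
    ch <- ch[ch %in% BASES]
    pooled_freqs <- table(factor(ch, levels = BASES)) / length(ch)
    pooled_freqs <- stats::setNames(as.numeric(pooled_freqs), BASES)
  }
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pc <- pair_counts(mat[i, ], mat[j, ])
      d <- switch(model,
        "p" = pc$p,
        "JC69" = {
          if (pc$p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * pc$p / 3)
        },
        "K2P" = {
          P <- pc$P1 + pc$P2; Q <- pc$Q
          w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
          if (w1 <= 0 || w2 <= 0) NA_real_
          else -0.5 * log(w1) - 0.25 * log(w2)
        },
        "TN93" = {
          a <- mat[i, ]; b <- mat[j, ]
          ok <- a %in% BASES & b %in% BASES
          ch <- c(a[ok], b[ok])
          fr <- table(factor(ch, levels = BASES)) / length(ch)
          tn93_from_counts(pc$P1, pc$P2, pc$Q,
                           stats::setNames(as.numeric(fr), BASES))
        },
        "MCL-composite" = tn93_from_counts(pc$P1, pc$P2, pc$Q, pooled_freqs))
      if (is.na(d)) {
        saturated <- c(saturated,
                       paste(aln$taxa[i], aln$taxa[j], sep = "|"))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (length(saturated) > 0) {
    warning("saturated pair(s) flagged NA [W_SATURATED]: ",
            paste(saturated, collapse = ", "), call. = FALSE)
    attr(D, "saturated") <- saturated
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via ape); negative branch lengths are
#' clamped to zero with a warning. Row order (taxon labels) fixes
#' tie-breaking deterministically.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return Newick string (also returned invisibly as an `ape::phylo` in
#'   attribute `phylo`).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (anyNA(d)) stop("distance matrix contains NA (saturated pairs?)",
                     call. = FALSE)
  if (nrow(d) == 2) {
    nwk <- sprintf("(%s:%g,%s:%g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2)
    return(nwk)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0 [W_NEG_BRANCH]",
            call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}

#' Write a distance matrix as TSV and PHYLIP
#'
#' @param d distance matrix.
#' @param path_tsv,path_phylip output files (either may be NULL).
#' @export
write_distance_matrix <- function(d, path_tsv = NULL, path_phylip = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(data.frame(taxon = rownames(d), d,
                                  check.names = FALSE),
                       path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_phylip)) {
    lines <- c(sprintf("%5d", nrow(d)),
               vapply(seq_len(nrow(d)), function(i) {
                 paste0(formatC(rownames(d)[i], width = -10),
                        paste(sprintf("%.6f", d[i, ]), collapse = " "))
               }, ""))
    writeLines(lines, path_phylip)
  }
  invisible(NULL)
}
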