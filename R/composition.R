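#' Base composition and strand skews
#'
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), the standard
#' strand-asymmetry summaries for mitochondrial genomes. N sites are
#' excluded from every denominator.
#'
#' @name composition
NULL

#' Base composition of a sequence
#'
#' @param seq nucleotide string over A/C/G/T/N (gaps tolerated and ignored).
#' @param region_label text label carried into the report.
#' @return one-row data.frame: `region`, `A`, `T`, `G`, `C`, `n_sites`,
#'   `at_content`, `gc_content`, `at_skew`, `gc_skew`. A skew whose
#'   pair-sum is zero is `NA` (undefined, flagged), not zero.
#' @export
base_composition <- function(seq, region_label = "") {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop("base_composition needs a nonempty sequence", call. = FALSE)
  }
  ch <- seq_chars(toupper(seq))
  ch <- ch[ch != "-"]
  counts <- c(A = sum(ch == "A"), T = sum(ch == "T"),
              G = sum(ch == "G"), C = sum(ch == "C"))
  n <- sum(counts)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  data.frame(
    region = region_label,
    A = counts[["A"]], T = counts[["T"]], G = counts[["G"]], C = counts[["C"]],
    n_sites = n,
    at_content = if (n > 0) at / n else NA_real_,
    gc_content = if (n > 0) gc / n else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_,
    stringsAsFactors = FALSE)
}

#' Skews from printed percentage compositions
#'
#' Convenience for reproducing published skew values from a printed
#' base-percentage table.
#'
#' @param A,T,G,C percentages or fractions (consistent units).
#' @return list with `at_skew` and `gc_skew`.
#' @export
skew_from_percentages <- function(A, T, G, C) {
  list(at_skew = (A - T) / (A + T), gc_skew = (G - C) / (G + C))
}

# Concatenated sequence of all features of a type, each in its own
# reading orientation.
concat_type <- function(genome, type) {
  nm <- genome$features$name[genome$features$type == type]
  if (length(nm) == 0) return("")
  paste(vapply(nm, function(n) extract_gene_sequence(genome, n), ""),
        collapse = "")
}

# In-frame codon matrix (3 columns) for all PCGs of a genome, incomplete
# terminal codons dropped.
pcg_codon_positions <- function(genome) {
  nm <- genome$features$name[genome$features$type == "PCG"]
  mats <- lapply(nm, function(n) {
    s <- extract_gene_sequence(genome, n)
    cod <- split_codons(s)
    if (length(cod) == 0) return(NULL)
    matrix(unlist(strsplit(cod, "", fixed = TRUE)), ncol = 3, byrow = TRUE)
  })
  do.call(rbind, mats)
}

#' Region-wise composition of a mitogenome
#'
#' Rows: full mitogenome (J strand); concatenated PCGs and their codon
#' positions 1-3 (each PCG read in its own orientation, incomplete terminal
#' codons dropped from positional rows); concatenated tRNAs; concatenated
#' rRNAs; CR; plus one row per PCG. Rows for absent regions are omitted
#' with a warning.
#'
#' @param genome a [mitogenome()].
#' @return data.frame of [base_composition()] rows with a `genome` column.
#' @export
region_composition <- function(genome) {
  rows <- list(base_composition(genome$sequence, "full_mitogenome"))
  pcg_all <- concat_type(genome, "PCG")
  if (nzchar(pcg_all)) {
    rows <- c(rows, list(base_composition(pcg_all, "PCG_all")))
    mat <- pcg_codon_positions(genome)
    for (p in 1:3) {
      rows <- c(rows, list(base_composition(
        paste(mat[, p], collapse = ""), sprintf("PCG_pos%d", p))))
    }
  }
  for (ty in c("tRNA", "rRNA")) {
    s <- concat_type(genome, ty)
    if (nzchar(s)) {
      rows <- c(rows, list(base_composition(s, paste0(ty, "_all"))))
    } else {
      warning("genome ", genome$id, " has no ", ty,
              " features; row omitted [W_NO_", toupper(ty), "]",
              call. = FALSE)
    }
  }
  if ("CR" %in% genome$features$name) {
    rows <- c(rows, list(base_composition(
      extract_gene_sequence(genome, "CR"), "CR")))
  } else {
    warning("genome ", genome$id,
            " has no control region; row omitted [W_NO_CR]", call. = FALSE)
  }
  for (nm in genome$features$name[genome$features$type == "PCG"]) {
    rows <- c(rows, list(base_composition(
      extract_gene_sequence(genome, nm), nm)))
  }
  out <- do.call(rbind, rows)
  cbind(genome = genome$id, out, stringsAsFactors = FALSE)
}

#' Write a composition table as TSV
#'
#' Percentages are printed at one decimal place; skews at three.
#'
#' @param comp output of [region_composition()] (possibly row-bound over
#'   genomes).
#' @param path output file.
#' @export
write_composition_tsv <- function(comp, path) {
  out <- data.frame(
    genome = comp$genome, region = comp$region,
    A = comp$A, T = comp$T, G = comp$G, C = comp$C,
    AT_pct = sprintf("%.1f", 100 * comp$at_content),
    GC_pct = sprintf("%.1f", 100 * comp$gc_content),
    AT_skew = sprintf("%.3f", comp$at_skew),
    GC_skew = sprintf("%.3f", comp$gc_skew),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
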