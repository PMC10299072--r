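#' Codon-usage bias statistics
#'
#' Codon counting under the invertebrate mitochondrial code, relative
#' synonymous codon usage (RSCU), Wright's effective number of codons
#' (ENC) generalized to the family structure of the code in use, positional
#' GC content, the ENC-GC3 expectation curve, and the neutrality
#' (GC12 on GC3) regression that partitions codon-composition evolution
#' into mutational (slope) and selective (1 - slope) contributions.
#'
#' @name codon_usage
NULL

#' Count codons of in-frame coding sequences
#'
#' Only complete codons are counted; stop codons and codons containing N
#' are excluded from the sense-codon table but tallied separately.
#'
#' @param cds_sequences character vector (or list) of in-frame nucleotide
#'   strings, each read in frame 0 of its own orientation.
#' @param code translation table id (default 5).
#' @return object of class `codon_usage_table`: data.frame with `codon`,
#'   `aa`, `family_size`, `count`, plus attributes `n_stop`, `n_ambiguous`,
#'   `code`.
#' @export
count_codons <- function(cds_sequences, code = 5) {
  fams <- codon_families(code)
  cds_sequences <- unlist(cds_sequences, use.names = FALSE)
  codons <- unlist(lapply(toupper(cds_sequences), split_codons),
                   use.names = FALSE)
  gc <- genetic_code(code)
  clean <- codons[!grepl("[^ACGT]", codons)]
  n_ambiguous <- length(codons) - length(clean)
  is_stop <- gc[clean] == "*"
  n_stop <- sum(is_stop)
  clean <- clean[!is_stop]
  counts <- table(factor(clean, levels = fams$codon))
  out <- fams
  out$count <- as.integer(counts[fams$codon])
  structure(out, class = c("codon_usage_table", "data.frame"),
            n_stop = n_stop, n_ambiguous = n_ambiguous, code = code)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon j in a synonymous family of size k with counts x_j and
#' family total n is x_j * k / n; families never observed are flagged
#' unused (`NA`) rather than zero.
#'
#' @param table a [count_codons()] result.
#' @return the table with an `rscu` column added.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam_tot <- tapply(table$count, table$aa, sum)
  n_i <- as.numeric(fam_tot[table$aa])
  table$rscu <- ifelse(n_i > 0, table$count * table$family_size / n_i,
                       NA_real_)
  table
}

#' Effective number of codons (ENC)
#'
#' Wright's estimator generalized to any family partition: per family with
#' n >= 2 observations the codon homozygosity is
#' F = (n * sum p_j^2 - 1)/(n - 1); the mean F is taken per family-size
#' class, and ENC = sum over classes of n_k / F_bar_k. Under table 5 the
#' classes are 12 twofold, 6 fourfold, 1 sixfold and 1 eightfold family, so
#' ENC ranges from 20 (one codon per family) to 62 (uniform usage). A size
#' class with no defined mean imputes it from the defined classes scaled by
#' 1/k; the result is capped at the number of sense codons.
#'
#' @param table a [count_codons()] result.
#' @param min_codons totals below this flag the value low-confidence
#'   (attribute `low_confidence`).
#' @return numeric ENC value.
#' @export
enc <- function(table, min_codons = 100L) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam <- split(table, table$aa)
  sizes <- vapply(fam, function(f) f$family_size[1], 0L)
  F_vals <- vapply(fam, function(f) {
    n <- sum(f$count)
    if (n < 2) return(NA_real_)
    p <- f$count / n
    F <- (n * sum(p^2) - 1) / (n - 1)
    if (F <= 0) NA_real_ else F
  }, 0)
  classes <- sort(unique(sizes))
  n_k <- vapply(classes, function(k) sum(sizes == k), 0L)
  F_bar <- vapply(classes, function(k) {
    v <- F_vals[sizes == k]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, 0)
  if (anyNA(F_bar)) {
    # impute a missing class mean from defined classes: F scales ~ 1/k
    # under uniform usage, so carry k * F_bar across classes
    defined <- !is.na(F_bar)
    if (!any(defined)) return(NA_real_)
    scale <- mean(classes[defined] * F_bar[defined])
    F_bar[!defined] <- scale / classes[!defined]
  }
  val <- sum(n_k / F_bar)
  n_sense <- nrow(table)
  val <- min(val, n_sense)
  if (sum(table$count) < min_codons) attr(val, "low_confidence") <- TRUE
  val
}

#' Expected ENC under mutation alone at a given GC3
#'
#' The no-selection expectation curve for an ENC-GC3 plot:
#' ENC = 2 + s + 29 / (s^2 + (1 - s)^2).
#'
#' @param s GC3 fraction in `[0, 1]` (vectorized).
#' @return expected ENC.
#' @export
enc_expected <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Positional GC content of coding sequences
#'
#' GC fraction at codon positions 1, 2, 3 pooled over all complete sense
#' codons; GC12 is the mean of positions 1 and 2. Stop codons and codons
#' containing N are excluded.
#'
#' @param cds_sequences in-frame nucleotide strings.
#' @param code translation table id.
#' @return list with `gc1`, `gc2`, `gc3`, `gc12`, `n_codons`.
#' @export
positional_gc <- function(cds_sequences, code = 5) {
  gc <- genetic_code(code)
  codons <- unlist(lapply(toupper(unlist(cds_sequences, use.names = FALSE)),
                          split_codons), use.names = FALSE)
  codons <- codons[!grepl("[^ACGT]", codons)]
  codons <- codons[gc[codons] != "*"]
  if (length(codons) == 0) {
    return(list(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
                gc12 = NA_real_, n_codons = 0L))
  }
  mat <- matrix(unlist(strsplit(codons, "", fixed = TRUE)),
                ncol = 3, byrow = TRUE)
  gcp <- vapply(1:3, function(p) mean(mat[, p] %in% c("G", "C")), 0)
  list(gc1 = gcp[1], gc2 = gcp[2], gc3 = gcp[3],
       gc12 = mean(gcp[1:2]), n_codons = length(codons))
}

#' Codon-bias summary for one genome
#'
#' @param genome a [mitogenome()].
#' @param code translation table id.
#' @return one-row data.frame: genome, n_codons, enc, gc1..gc3, gc12.
#' @export
codon_bias_summary <- function(genome, code = 5) {
  cds <- vapply(genome$features$name[genome$features$type == "PCG"],
                function(n) extract_gene_sequence(genome, n), "")
  tab <- count_codons(cds, code)
  pg <- positional_gc(cds, code)
  data.frame(genome = genome$id, n_codons = pg$n_codons,
             enc = as.numeric(enc(tab)),
             gc1 = pg$gc1, gc2 = pg$gc2, gc3 = pg$gc3, gc12 = pg$gc12,
             stringsAsFactors = FALSE)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 on GC3 across genomes; the slope is read
#' as the share of codon-composition evolution attributable to mutational
#' pressure and 1 - slope as the share attributable to selection.
#'
#' @param gc3,gc12 numeric vectors (>= 3 points) or a 2-column data.frame
#'   in `gc3`.
#' @return list of class `neutrality_fit`: `slope`, `intercept`, `r`,
#'   `p_value`, `mutation_share_pct`, `selection_share_pct`, `n`.
#' @export
neutrality_fit <- function(gc3, gc12 = NULL) {
  if (is.null(gc12)) {
    stopifnot(is.data.frame(gc3), all(c("gc3", "gc12") %in% names(gc3)))
    gc12 <- gc3$gc12; gc3 <- gc3$gc3
  }
  ok <- !is.na(gc3) & !is.na(gc12)
  gc3 <- gc3[ok]; gc12 <- gc12[ok]
  if (length(gc3) < 3) stop("neutrality fit needs at least 3 points",
                            call. = FALSE)
  if (stats::sd(gc3) == 0) stop("degenerate fit: GC3 has zero variance",
                                call. = FALSE)
  fit <- stats::lm(gc12 ~ gc3)
  ct <- stats::cor.test(gc3, gc12)
  b <- unname(stats::coef(fit)[2])
  structure(list(
    slope = b, intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate), p_value = ct$p.value,
    mutation_share_pct = 100 * b, selection_share_pct = 100 * (1 - b),
    n = length(gc3)), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "neutrality plot fit (n = %d): GC12 = %.3f + %.3f * GC3\n", x$n,
    x$intercept, x$slope))
  cat(sprintf("Pearson r = %.3f (p = %.3g)\n", x$r, x$p_value))
  cat(sprintf("mutation %.1f%% / selection %.1f%%\n",
              x$mutation_share_pct, x$selection_share_pct))
  invisible(x)
}

#' Plot-data for an ENC-GC3 plot
#'
#' @param summaries row-bound [codon_bias_summary()] rows.
#' @return data.frame: genome, gc3, enc, enc_expected.
#' @export
enc_gc3_plotdata <- function(summaries) {
  data.frame(genome = summaries$genome, gc3 = summaries$gc3,
             enc = summaries$enc, enc_expected = enc_expected(summaries$gc3),
             stringsAsFactors = FALSE)
}
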