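#' Gene-order rearrangement analysis
#'
#' Signed circular gene orders, detection and classification of
#' rearrangements against a reference order, and a lower bound on the
#' number of tandem duplication-random loss (TDRL) events separating two
#' orders. A TDRL event duplicates a contiguous gene block and then loses
#' one copy of each gene; it changes gene positions but never
#' orientations, and a single event yields a permutation whose elements
#' fall into at most two increasing runs. The minimal number of events is
#' therefore ceil(log2(r)) where r is the number of maximal increasing
#' runs (descent count + 1), minimized over circular rotations.
#'
#' @name gene_order
NULL

#' Construct a gene-order permutation
#'
#' @param genes character vector of canonical symbols (37 genes + CR for a
#'   complete record; subsets allowed).
#' @param strands matching "J"/"N" vector.
#' @param genome_id provenance label.
#' @return object of class `gene_order`: data.frame `gene`, `strand`.
#' @export
gene_order <- function(genes, strands, genome_id = "") {
  if (anyDuplicated(genes)) {
    stop("duplicate gene in order: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(data.frame(gene = genes, strand = strands,
                       stringsAsFactors = FALSE),
            class = c("gene_order", "data.frame"), genome_id = genome_id)
}

#' Extract the signed circular gene order of a genome
#'
#' Features sorted by start position after rotation so that the anchor
#' gene comes first; the control region participates as a positional
#' token.
#'
#' @param genome a [mitogenome()].
#' @param anchor anchor gene symbol (default cox1).
#' @return a [gene_order()].
#' @export
extract_gene_order <- function(genome, anchor = "cox1") {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  i <- match(anchor, f$name)
  if (is.na(i)) stop("anchor gene '", anchor, "' absent from ", genome$id,
                     call. = FALSE)
  idx <- c(i:nrow(f), seq_len(i - 1))[seq_len(nrow(f))]
  gene_order(f$name[idx], f$strand[idx], genome_id = genome$id)
}

#' Load the packaged reference gene order
#'
#' A constructed reference representing the conserved salticid-type
#' arrangement (control region between trnQ and trnM, rrnL between trnL1
#' and trnV, rrnS between trnV and trnQ, 9 J-strand and 4 N-strand PCGs);
#' replace with your own TSV (`columns gene, strand`) for other taxa.
#'
#' @param path optional TSV path overriding the packaged table.
#' @return a [gene_order()].
#' @export
reference_gene_order <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "salticid_gene_order.tsv",
                        package = "mitocomp")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_order(tab$gene, tab$strand, genome_id = "reference")
}

rotate_vec <- function(x, i) if (i <= 1) x else c(x[i:length(x)],
                                                 x[seq_len(i - 1)])

#' Test circular equality of two gene orders
#'
#' @param a,b [gene_order()] objects over the same gene set.
#' @return TRUE when some rotation of `a` equals `b` gene-for-gene with
#'   matching strands.
#' @export
orders_equal <- function(a, b) {
  if (nrow(a) != nrow(b) || !setequal(a$gene, b$gene)) return(FALSE)
  i <- match(b$gene[1], a$gene)
  ga <- rotate_vec(a$gene, i); sa <- rotate_vec(a$strand, i)
  identical(ga, b$gene) && identical(sa, b$strand)
}

# longest common subsequence of two character vectors -> logical keep mask
# on x (prefers, among equal-length LCS, the standard DP traceback which
# retains the earliest matches; deterministic)
lcs_mask <- function(x, y) {
  nx <- length(x); ny <- length(y)
  L <- matrix(0L, nx + 1, ny + 1)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      L[i + 1, j + 1] <- if (x[i] == y[j]) L[i, j] + 1L
        else max(L[i, j + 1], L[i + 1, j])
    }
  }
  keep <- logical(nx)
  i <- nx; j <- ny
  while (i > 0 && j > 0) {
    if (x[i] == y[j] && L[i + 1, j + 1] == L[i, j] + 1L) {
      keep[i] <- TRUE; i <- i - 1; j <- j - 1
    } else if (L[i, j + 1] >= L[i + 1, j]) i <- i - 1 else j <- j - 1
  }
  keep
}

#' Compare a gene order against a reference
#'
#' Returns one call per moved block, computed by excluding the longest
#' common circular subsequence (best rotation; ties broken by fewest moved
#' genes then gene name). Blocks are classified: `tRNA-shuffle` when only
#' tRNAs move without crossing a PCG or rRNA, `tRNA-translocation` when
#' they cross one, `PCG-move` when a protein-coding gene moves, and
#' `inversion` when any strand flips.
#'
#' @param order,reference [gene_order()] objects over the same gene set.
#' @return data.frame (possibly 0-row): `genes`, `kind`, `flank_before`,
#'   `flank_after`, `ref_flank_before`, `ref_flank_after`, `tdrl_events`.
#' @export
compare_orders <- function(order, reference) {
  if (!setequal(order$gene, reference$gene)) {
    stop("gene sets differ: only in order: ",
         paste(setdiff(order$gene, reference$gene), collapse = ", "),
         "; only in reference: ",
         paste(setdiff(reference$gene, order$gene), collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(genes = character(0), kind = character(0),
                      flank_before = character(0),
                      flank_after = character(0),
                      ref_flank_before = character(0),
                      ref_flank_after = character(0),
                      tdrl_events = integer(0), stringsAsFactors = FALSE)
  if (orders_equal(order, reference)) return(empty)
  n <- nrow(order)
  best <- NULL
  for (r in seq_len(n)) {
    g <- rotate_vec(order$gene, r)
    keep <- lcs_mask(g, reference$gene)
    if (is.null(best) || sum(keep) > sum(best$score)) {
      best <- list(rot = r, genes = g,
                   strands = rotate_vec(order$strand, r), keep = keep,
                   score = keep)
    }
  }
  g <- best$genes; strands <- best$strands; keep <- best$keep
  # a strand flip with no positional move is still a rearrangement
  ref_strand0 <- stats::setNames(reference$strand, reference$gene)
  keep[strands != ref_strand0[g]] <- FALSE
  moved_idx <- which(!keep)
  if (length(moved_idx) == 0) return(empty)
  # group moved genes into blocks contiguous in the observed order
  block_id <- cumsum(c(1, diff(moved_idx) != 1))
  ref_strand <- stats::setNames(reference$strand, reference$gene)
  ref_pos <- stats::setNames(seq_len(n), reference$gene)
  ref_type <- stats::setNames(
    vapply(reference$gene, function(x) {
      t <- canonical_type(x); if (is.na(t)) "other" else t
    }, ""), reference$gene)
  calls <- lapply(split(moved_idx, block_id), function(idx) {
    genes <- g[idx]
    flips <- strands[idx] != ref_strand[genes]
    fb <- if (min(idx) > 1) g[min(idx) - 1] else g[n]
    fa <- if (max(idx) < n) g[max(idx) + 1] else g[1]
    src <- range(ref_pos[genes])
    rfb <- reference$gene[ifelse(src[1] > 1, src[1] - 1, n)]
    rfa <- reference$gene[ifelse(src[2] < n, src[2] + 1, 1)]
    kind <- if (any(flips)) "inversion"
      else if (any(ref_type[genes] == "PCG")) "PCG-move"
      else if (any(ref_type[genes] == "rRNA")) "PCG-move"
      else {
        # does the move cross a PCG or rRNA? examine the reference arc
        # between the source span and the destination insertion point
        dest <- ref_pos[fb]
        lo <- min(c(src, dest)); hi <- max(c(src, dest))
        arc <- setdiff(seq(lo, hi), c(ref_pos[genes], dest))
        crossed <- reference$gene[arc]
        if (any(ref_type[crossed] %in% c("PCG", "rRNA")))
          "tRNA-translocation" else "tRNA-shuffle"
      }
    data.frame(genes = paste(genes, collapse = ","), kind = kind,
               flank_before = fb, flank_after = fa,
               ref_flank_before = rfb, ref_flank_after = rfa,
               tdrl_events = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  bound <- tdrl_event_bound(order, reference)
  out$tdrl_events <- if (is.na(bound)) NA_integer_ else as.integer(bound)
  if (is.na(bound)) attr(out, "tdrl") <- "not TDRL-explainable"
  out
}

descents <- function(perm) sum(diff(perm) < 0)

#' Minimal-event TDRL bound between two gene orders
#'
#' The observed order is mapped to a permutation of the reference indices
#' (the control region is excluded: it rearranges by other mechanisms);
#' the bound is ceil(log2(descents + 1)) minimized over circular
#' rotations. 0 means circularly identical; 1 means explainable by a
#' single TDRL event. Orientation changes make an order not
#' TDRL-explainable: the result is `NA` with attribute `reason`.
#'
#' @param order,reference [gene_order()] objects over the same gene set,
#'   or plain integer permutations (then used as-is).
#' @param circular minimize over rotations (default TRUE; FALSE treats
#'   the permutation linearly).
#' @return integer bound, or `NA` when not TDRL-explainable.
#' @export
tdrl_event_bound <- function(order, reference = NULL, circular = TRUE) {
  if (is.numeric(order)) {
    perm <- as.integer(order)
  } else {
    stopifnot(inherits(order, "gene_order"), inherits(reference, "gene_order"))
    o <- order[order$gene != "CR", , drop = FALSE]
    r <- reference[reference$gene != "CR", , drop = FALSE]
    if (!setequal(o$gene, r$gene)) {
      stop("gene sets differ between order and reference", call. = FALSE)
    }
    ref_strand <- stats::setNames(r$strand, r$gene)
    if (any(o$strand != ref_strand[o$gene])) {
      out <- NA_integer_
      attr(out, "reason") <- "not TDRL-explainable"
      return(out)
    }
    perm <- match(o$gene, r$gene)
  }
  n <- length(perm)
  if (n <= 1) return(0L)
  if (!circular) {
    d <- descents(perm)
    return(as.integer(ceiling(log2(d + 1))))
  }
  bounds <- vapply(seq_len(n), function(i) {
    rot <- rotate_vec(perm, i)
    rel <- ((rot - rot[1]) %% n) + 1L
    as.integer(ceiling(log2(descents(rel) + 1)))
  }, 0L)
  min(bounds)
}

#' Enumerate all single-TDRL products of the identity permutation
#'
#' Brute-force oracle: every contiguous block `[i, j]` is duplicated and
#' each element keeps either its first or its second copy. Intended for
#' small n.
#'
#' @param n permutation size (<= 10).
#' @return list of unique non-identity integer permutations.
#' @export
enumerate_single_tdrl <- function(n) {
  stopifnot(n <= 10)
  id <- seq_len(n)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      block <- i:j
      m <- length(block)
      for (mask in 0:(2^m - 1)) {
        first <- block[bitwAnd(bitwShiftR(mask, seq_len(m) - 1), 1L) == 1L]
        second <- setdiff(block, first)
        perm <- c(if (i > 1) id[1:(i - 1)], first, second,
                  if (j < n) id[(j + 1):n])
        key <- paste(perm, collapse = ",")
        if (!identical(perm, id) && !exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1]] <- perm
        }
      }
    }
  }
  out
}

#' Write gene orders and rearrangement calls as TSV
#'
#' @param orders list of [gene_order()] objects.
#' @param calls named list of [compare_orders()] results (may be NULL).
#' @param orders_path,calls_path output files.
#' @export
write_gene_order_tsv <- function(orders, calls = NULL, orders_path,
                                 calls_path = NULL) {
  tab <- do.call(rbind, lapply(orders, function(o) {
    data.frame(genome = attr(o, "genome_id"),
               position = seq_len(nrow(o)), gene = o$gene,
               strand = o$strand, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, orders_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(calls) && !is.null(calls_path)) {
    ct <- do.call(rbind, lapply(names(calls), function(id) {
      if (nrow(calls[[id]]) == 0) return(NULL)
      cbind(genome = id, calls[[id]], stringsAsFactors = FALSE)
    }))
    if (is.null(ct)) {
      ct <- data.frame(genome = character(0), genes = character(0),
                       kind = character(0))
    }
    utils::write.table(ct, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
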