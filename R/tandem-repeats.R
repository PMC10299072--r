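#' Tandem-repeat detection in control regions
#'
#' Self-contained tandem-repeat finder for short non-coding sequences:
#' for each candidate period the sequence is compared with itself at that
#' lag, high-scoring self-match segments (match +2, mismatch -7, in the
#' spirit of common tandem-repeat-finder weights) become candidate
#' arrays, each array is scored against its column-majority consensus,
#' and overlapping candidates are resolved by score then by smaller
#' period, so a perfect period-p array is never reported at a 2p
#' harmonic. Copy number is fractional (array span / period) and the
#' portions of the span that do not fill whole copies are reported as
#' leading/trailing partial segments.
#'
#' @name tandem_repeats
NULL

# maximal positive-scoring segments of a logical match vector
xdrop_segments <- function(m, match = 2, mismatch = -7) {
  v <- ifelse(m, match, mismatch)
  segs <- list()
  score <- 0; best <- 0; start <- NA_integer_; best_end <- NA_integer_
  flush <- function() {
    if (!is.na(start) && best > 0) {
      segs[[length(segs) + 1]] <<- c(start = start, end = best_end,
                                     score = best)
    }
    score <<- 0; best <<- 0; start <<- NA_integer_; best_end <<- NA_integer_
  }
  for (i in seq_along(v)) {
    if (score == 0 && v[i] < 0) next
    if (score == 0) { start <- i; best <- 0 }
    score <- score + v[i]
    if (score > best) { best <- score; best_end <- i }
    if (score <= 0) flush()
  }
  flush()
  segs
}

consensus_of_span <- function(chars, period) {
  cols <- (seq_along(chars) - 1L) %% period
  vapply(0:(period - 1L), function(cc) {
    tab <- table(chars[cols == cc])
    names(tab)[which.max(tab)]
  }, "")
}

# identity of a span against a consensus repeated in phase
span_identity <- function(chars, consensus) {
  period <- length(consensus)
  cols <- (seq_along(chars) - 1L) %% period
  mean(chars == consensus[cols + 1L])
}

evaluate_candidate <- function(chars, a, b, period, min_copies,
                               min_identity, match = 2, mismatch = -7) {
  span <- a:b
  span_len <- length(span)
  copies <- span_len / period
  if (copies < min_copies) return(NULL)
  sub <- chars[span]
  cons <- consensus_of_span(sub, period)
  ident <- span_identity(sub, cons)
  if (ident < min_identity) return(NULL)
  n_match <- round(ident * span_len)
  score <- match * n_match + mismatch * (span_len - n_match)
  # phase: put copy boundaries where the most exact consensus copies sit
  phase_hits <- vapply(0:(period - 1L), function(phi) {
    k <- (span_len - phi) %/% period
    if (k < 1) return(0L)
    hits <- 0L
    for (i in seq_len(k)) {
      w <- sub[(phi + (i - 1) * period + 1):(phi + i * period)]
      if (mean(w == cons_rot(cons, phi)) >= min_identity) hits <- hits + 1L
    }
    hits
  }, 0L)
  phi <- which.max(phase_hits) - 1L
  k <- (span_len - phi) %/% period
  trail <- span_len - phi - k * period
  list(start = a - 1L, end = b, period = period,
       copy_number = copies, consensus = paste(cons_rot(cons, phi),
                                               collapse = ""),
       identity = ident, partial_lead = phi, partial_trail = trail,
       score = score)
}

cons_rot <- function(cons, phi) {
  p <- length(cons)
  phi <- phi %% p
  if (phi == 0) cons else c(cons[(phi + 1):p], cons[1:phi])
}

#' Find tandem repeats in a sequence
#'
#' @param seq nucleotide string (typically a control region).
#' @param min_period,max_period period range searched (defaults 5 and
#'   `min(500, floor(L / min_copies))`).
#' @param min_copies minimum fractional copy number (default 1.9).
#' @param min_identity minimum identity of the array to its consensus
#'   (default 0.8).
#' @param match,mismatch self-alignment scores (defaults +2/-7).
#' @param min_score minimum consensus-alignment score
#'   (`match * matches + mismatch * mismatches`, default 50), the usual
#'   tandem-repeat-finder minscore that keeps very short arrays out.
#' @return data.frame of hits (0-based half-open spans): `start`, `end`,
#'   `period`, `copy_number`, `consensus`, `identity`, `partial_lead`,
#'   `partial_trail`, `score`; 0 rows when nothing qualifies.
#' @export
find_tandem_repeats <- function(seq, min_period = 5L, max_period = NULL,
                                min_copies = 1.9, min_identity = 0.8,
                                match = 2, mismatch = -7,
                                min_score = 50) {
  seq <- check_nucleotides(seq, what = "repeat-search sequence")
  L <- nchar(seq)
  if (is.null(max_period)) max_period <- min(500L, floor(L / min_copies))
  if (min_period > max_period) {
    stop("min_period exceeds max_period", call. = FALSE)
  }
  chars <- seq_chars(seq)
  hits <- list()
  for (p in seq(min_period, max_period)) {
    if (L - p < (min_copies - 1) * p) break
    m <- chars[seq_len(L - p)] == chars[(p + 1):L]
    for (seg in xdrop_segments(m, match, mismatch)) {
      # self-match run [a, b] at lag p covers sequence span [a, b + p]
      cand <- evaluate_candidate(chars, seg[["start"]],
                                 min(seg[["end"]] + p, L), p,
                                 min_copies, min_identity, match, mismatch)
      if (!is.null(cand) && cand$score >= min_score) {
        hits[[length(hits) + 1]] <- cand
      }
    }
  }
  cols <- c("start", "end", "period", "copy_number", "consensus",
            "identity", "partial_lead", "partial_trail", "score")
  if (length(hits) == 0) {
    out <- as.data.frame(stats::setNames(
      list(integer(0), integer(0), integer(0), numeric(0), character(0),
           numeric(0), integer(0), integer(0), numeric(0)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  tab <- do.call(rbind, lapply(hits, function(h) {
    data.frame(h, stringsAsFactors = FALSE)
  }))
  # resolve overlaps: best score first, then smaller period
  tab <- tab[order(-tab$score, tab$period, tab$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(tab$end[i], tab$end[j]) - max(tab$start[i], tab$start[j])
      if (ov > 0.5 * (tab$end[i] - tab$start[i])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  tab <- tab[keep, , drop = FALSE]
  # harmonic reduction: re-report each hit at the smallest divisor period
  # whose consensus still explains the span (a mutated array can score
  # higher at 2p because the mutations are baked into the doubled
  # consensus; the smallest consistent period is the real one)
  for (i in seq_len(nrow(tab))) {
    p0 <- tab$period[i]
    divs <- seq_len(p0 %/% 2)
    divs <- divs[p0 %% divs == 0 & divs >= min_period]
    for (d in sort(divs)) {
      cand <- evaluate_candidate(chars, tab$start[i] + 1L, tab$end[i], d,
                                 min_copies, min_identity, match, mismatch)
      if (!is.null(cand) && cand$score >= min_score) {
        tab[i, names(cand)] <- data.frame(cand, stringsAsFactors = FALSE)
        break
      }
    }
  }
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Brute-force tandem-repeat oracle
#'
#' Independent check used in tests: for every (start, period) pair it
#' scores candidate windows directly against their column-majority
#' consensus and reports the qualifying ones. Windows examined per pair
#' are the minimal window (`min_copies * period`) and every whole-copy
#' extension, which covers any array a consensus-based detector may
#' legitimately call. Quadratic; only for short strings.
#'
#' @param seq nucleotide string (<= a few hundred nt).
#' @inheritParams find_tandem_repeats
#' @return data.frame of qualifying windows: `start`, `period`, `len`
#'   (0 rows when none qualifies).
#' @export
brute_force_repeat_scan <- function(seq, min_period = 5L, max_period = NULL,
                                    min_copies = 1.9, min_identity = 0.8,
                                    match = 2, mismatch = -7,
                                    min_score = 50) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (is.null(max_period)) max_period <- floor(L / min_copies)
  chars <- seq_chars(seq)
  base_id <- match(chars, BASES)  # N and others become NA
  # majority-consensus identity of window [a, a+len-1] at period p
  win_identity <- function(a, len, p) {
    ids <- base_id[a:(a + len - 1)]
    cols <- (seq_len(len) - 1L) %% p
    # per-base counts per column; the column maxima are the majority
    # consensus matches
    counts <- vapply(1:4, function(b) {
      tabulate(cols[!is.na(ids) & ids == b] + 1L, nbins = p)
    }, integer(p))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = p)
    sum(do.call(pmax, asplit(counts, 2))) / len
  }
  rows <- list()
  for (p in seq(min_period, max_period)) {
    min_len <- as.integer(ceiling(min_copies * p))
    if (min_len > L) break
    for (a in seq_len(L - min_len + 1)) {
      max_k <- (L - a + 1) %/% p
      lens <- unique(c(min_len, p * seq(2, max(2, max_k))))
      lens <- lens[lens >= min_len & lens <= L - a + 1]
      for (len in lens) {
        ident <- win_identity(a, len, p)
        n_match <- round(ident * len)
        score <- match * n_match + mismatch * (len - n_match)
        if (ident >= min_identity && score >= min_score) {
          rows[[length(rows) + 1]] <- c(start = a - 1L, period = p,
                                        len = len)
          break  # one qualifying window per (start, period) is enough
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), period = integer(0),
                      len = integer(0)))
  }
  as.data.frame(do.call(rbind, rows))
}

#' Write repeat hits as TSV and BED
#'
#' @param hits named list of [find_tandem_repeats()] tables (one per
#'   genome/CR).
#' @param tsv_path,bed_path output files (either may be NULL).
#' @export
write_repeats <- function(hits, tsv_path = NULL, bed_path = NULL) {
  tab <- do.call(rbind, lapply(names(hits), function(id) {
    h <- hits[[id]]
    if (nrow(h) == 0) return(NULL)
    cbind(genome = id, h, stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(genome = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      copy_number = numeric(0), consensus = character(0),
                      identity = numeric(0), partial_lead = integer(0),
                      partial_trail = integer(0), score = numeric(0))
  }
  if (!is.null(tsv_path)) {
    out <- tab
    if (nrow(out) > 0) out$copy_number <- round(out$copy_number, 1)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- if (nrow(tab) > 0) {
      data.frame(tab$genome, tab$start, tab$end,
                 sprintf("period%d_x%.1f", tab$period,
                         round(tab$copy_number, 1)))
    } else data.frame(character(0), integer(0), integer(0), character(0))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
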