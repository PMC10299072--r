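#' Annotated mitogenome container and GenBank I/O
#'
#' An annotated mitogenome is a circular nucleotide sequence (the majority,
#' J, strand) plus a typed, stranded feature table. Internally all
#' coordinates are 0-based half-open on the linearized J strand; GenBank
#' 1-based inclusive coordinates exist only at the I/O boundary. Features
#' that span the origin of the linearization are stored with `end <= start`
#' and interpreted modulo the genome length.
#'
#' @name genome_io
NULL

FEATURE_TYPES <- c("PCG", "tRNA", "rRNA", "CR")

PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
TRNA_NAMES <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnQ", "trnE",
                "trnG", "trnH", "trnI", "trnK", "trnL1", "trnL2", "trnM",
                "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY",
                "trnV")
RRNA_NAMES <- c("rrnS", "rrnL")

#' Construct an annotated mitogenome
#'
#' @param id accession or label.
#' @param sequence J-strand nucleotide string over A/C/G/T/N.
#' @param features data.frame with columns `name`, `type`, `start`, `end`,
#'   `strand`, `codon_offset` (0-based half-open coordinates; strand "J" or
#'   "N"; `codon_offset` 0 except for PCGs annotated with a reading-frame
#'   offset).
#' @param circular logical; mitogenomes are circular.
#' @param taxon free-text species name.
#' @param min_cr_length CR features shorter than this are flagged (attribute
#'   `cr_short`), not rejected: some deposited records carry incomplete
#'   control regions.
#' @return object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, features, circular = TRUE, taxon = "",
                       min_cr_length = 200L) {
  sequence <- check_nucleotides(sequence, what = paste0("genome ", id))
  len <- nchar(sequence)
  if (len == 0L) stop("empty genome sequence for ", id, call. = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("name", "type", "start", "end", "strand", "codon_offset")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  features <- features[, needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$codon_offset <- as.integer(features$codon_offset)
  if (anyDuplicated(features$name)) {
    dup <- unique(features$name[duplicated(features$name)])
    stop("duplicate canonical gene name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(features$type %in% FEATURE_TYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(features$type, FEATURE_TYPES), collapse = ", "),
         call. = FALSE)
  }
  if (!all(features$strand %in% c("J", "N"))) {
    stop("strand must be J or N", call. = FALSE)
  }
  bad <- features$start < 0L | features$start >= len |
    features$end < 0L | features$end > len
  if (any(bad)) {
    stop("feature(s) outside [0, genome length): ",
         paste(features$name[bad], collapse = ", "), call. = FALSE)
  }
  if (any(features$codon_offset != 0L & features$type != "PCG")) {
    stop("codon_offset must be 0 for non-PCG features", call. = FALSE)
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  g <- structure(
    list(id = id, taxon = taxon, sequence = sequence,
         circular = isTRUE(circular), features = features),
    class = "mitogenome")
  cr <- features[features$type == "CR", , drop = FALSE]
  if (nrow(cr) > 0) {
    cr_len <- feature_length(g, cr$name[1])
    if (cr_len < min_cr_length) attr(g, "cr_short") <- cr_len
  }
  g
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("mitogenome %s (%s): %d bp, %s\n", x$id,
              if (nzchar(x$taxon)) x$taxon else "unknown taxon",
              genome_length(x), if (x$circular) "circular" else "linear"))
  tab <- table(factor(x$features$type, levels = FEATURE_TYPES))
  cat(sprintf("features: %d PCG, %d tRNA, %d rRNA, %d CR\n",
              tab["PCG"], tab["tRNA"], tab["rRNA"], tab["CR"]))
  invisible(x)
}

#' @export
genome_length <- function(genome) nchar(genome$sequence)

# Length of a feature on the circle, honouring origin-spanning intervals.
feature_length <- function(genome, name) {
  f <- get_feature(genome, name)
  len <- genome_length(genome)
  span <- (f$end - f$start) %% len
  if (span == 0L && f$end == f$start) len else if (span == 0L) len else span
}

get_feature <- function(genome, name) {
  i <- match(name, genome$features$name)
  if (is.na(i)) stop("no feature named '", name, "' in ", genome$id,
                     call. = FALSE)
  genome$features[i, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Gene-name normalization

normalize_gene_key <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9]", "", x)
}

synonym_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$canonical, tab$synonym)
    }
    cache
  }
})

#' Map a gene/product label to its canonical symbol
#'
#' Uses the packaged synonym table (case- and punctuation-insensitive);
#' deposited records name the same gene COX1, COI, CO1, ...
#'
#' @param ... one or more candidate labels (e.g. the /gene and /product
#'   qualifiers); the first that resolves wins.
#' @return canonical symbol, or `NA_character_` if none resolves.
#' @export
canonical_gene_name <- function(...) {
  cands <- unlist(list(...), use.names = FALSE)
  cands <- cands[!is.na(cands) & nzchar(cands)]
  map <- synonym_map()
  for (x in cands) {
    key <- normalize_gene_key(x)
    if (key %in% names(map)) return(unname(map[[key]]))
  }
  NA_character_
}

canonical_type <- function(name) {
  if (name %in% PCG_NAMES) "PCG"
  else if (name %in% TRNA_NAMES) "tRNA"
  else if (name %in% RRNA_NAMES) "rRNA"
  else if (name == "CR") "CR"
  else NA_character_
}

# ---------------------------------------------------------------------------
# GenBank flat-file parsing

parse_gb_location <- function(loc, len) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    rng <- do.call(rbind, lapply(parts, function(p) {
      m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
      if (length(m) != 3) stop("unparsable location segment: ", p,
                               call. = FALSE)
      as.integer(m[2:3])
    }))
    # origin-spanning join: last segment restarts at 1
    start1 <- rng[1, 1]; end1 <- rng[nrow(rng), 2]
    wraps <- nrow(rng) > 1 && rng[nrow(rng), 1] == 1L
    if (!wraps && nrow(rng) > 1) {
      # contiguous join pieces; treat as the covering interval
      end1 <- max(rng[, 2])
    }
    start <- start1 - 1L
    end <- if (wraps) end1 else end1
  } else {
    m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
    if (length(m) != 3) stop("unparsable location: ", loc, call. = FALSE)
    start <- as.integer(m[2]) - 1L
    end <- as.integer(m[3])
  }
  if (end == len) end <- if (start == 0L) len else end
  list(start = start, end = if (wraps) end else end, strand = strand,
       wraps = wraps)
}

#' Parse a GenBank flat file into an annotated mitogenome
#'
#' 1-based inclusive GenBank coordinates are converted to 0-based half-open;
#' gene names are normalized to canonical symbols via the packaged synonym
#' map; complement-strand features become strand N. When the record has no
#' control-region feature but trnQ and trnM are annotated, the unannotated
#' gap between them is labeled CR (the control region of these genomes sits
#' between trnQ and trnM).
#'
#' @param path GenBank flat file with source, CDS, tRNA, rRNA (optionally
#'   D-loop/misc_feature) features.
#' @param infer_cr infer a CR feature from the trnQ..trnM gap when absent.
#' @param min_cr_length see [mitogenome()].
#' @return a [mitogenome()].
#' @export
parse_genbank <- function(path, infer_cr = TRUE, min_cr_length = 200L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file: ", path, call. = FALSE)
  }
  locus <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  id <- locus[2]
  circular <- any(grepl("circular", lines[1]))
  taxon <- ""
  org <- grep("^[[:space:]]+ORGANISM", lines, value = TRUE)
  if (length(org) > 0) taxon <- trimws(sub("^[[:space:]]+ORGANISM", "", org[1]))

  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1) stop("no ORIGIN section in ", path, call. = FALSE)
  seq_lines <- lines[(ori + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  len <- nchar(sequence)

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) != 1) stop("no FEATURES section in ", path,
                                    call. = FALSE)
  flines <- lines[(feat_start + 1):(ori - 1)]

  # group feature blocks: a new feature starts with a key at column 6
  key_idx <- grep("^ {5}[A-Za-z]", flines)
  feats <- list()
  for (k in seq_along(key_idx)) {
    from <- key_idx[k]
    to <- if (k < length(key_idx)) key_idx[k + 1] - 1 else length(flines)
    block <- flines[from:to]
    head <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
    key <- head[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    # location may continue on following lines until a /qualifier appears
    loc <- paste(head[-1], collapse = "")
    i <- 2
    while (i <= length(block) && !grepl("^\\s*/", block[i])) {
      loc <- paste0(loc, trimws(block[i])); i <- i + 1
    }
    quals <- paste(block[seq(i, length.out = max(0, length(block) - i + 1))],
                   collapse = " ")
    getq <- function(q) {
      m <- regmatches(quals,
                      regexec(sprintf('/%s="?([^"/]+)"?', q), quals))[[1]]
      if (length(m) == 2) trimws(m[2]) else NA_character_
    }
    gene <- getq("gene"); product <- getq("product"); note <- getq("note")
    cs <- getq("codon_start")
    name <- canonical_gene_name(gene, product, note)
    if (key %in% c("D-loop", "misc_feature")) {
      if (is.na(name) || name != "CR") {
        if (key == "D-loop") name <- "CR" else next
      }
    }
    if (is.na(name)) {
      stop("cannot normalize gene name for a ", key, " feature (gene=",
           gene, ", product=", product, ") in ", path, call. = FALSE)
    }
    pl <- parse_gb_location(loc, len)
    type <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "CR")
    offset <- if (!is.na(cs)) as.integer(cs) - 1L else 0L
    feats[[length(feats) + 1]] <- data.frame(
      name = name, type = type, start = pl$start, end = pl$end %% max(len, 1L),
      strand = pl$strand, codon_offset = if (type == "PCG") offset else 0L,
      stringsAsFactors = FALSE)
  }
  if (length(feats) == 0) stop("no gene features found in ", path,
                               call. = FALSE)
  features <- do.call(rbind, feats)
  # GenBank end == len maps to end == 0 under modulo; restore full-span ends
  features$end <- ifelse(features$end == 0L & features$start != 0L,
                         len, features$end) %% len
  features$end[features$end == 0L] <- len
  g <- mitogenome(id, sequence, features, circular = circular, taxon = taxon,
                  min_cr_length = min_cr_length)
  if (infer_cr && !"CR" %in% g$features$name &&
      all(c("trnQ", "trnM") %in% g$features$name)) {
    q <- get_feature(g, "trnQ"); m <- get_feature(g, "trnM")
    s <- q$end %% len; e <- m$start
    if ((e - s) %% len > 0) {
      features <- rbind(g$features, data.frame(
        name = "CR", type = "CR", start = s, end = e, strand = "J",
        codon_offset = 0L, stringsAsFactors = FALSE))
      g <- mitogenome(id, sequence, features, circular = circular,
                      taxon = taxon, min_cr_length = min_cr_length)
    }
  }
  g
}

# ---------------------------------------------------------------------------
# GenBank writing

format_gb_location <- function(f, len) {
  wraps <- f$end <= f$start
  core <- if (wraps) {
    sprintf("join(%d..%d,1..%d)", f$start + 1L, len, f$end)
  } else {
    sprintf("%d..%d", f$start + 1L, f$end)
  }
  if (f$strand == "N") sprintf("complement(%s)", core) else core
}

#' Write an annotated mitogenome as a GenBank flat file
#'
#' @param genome a [mitogenome()].
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  len <- genome_length(genome)
  out <- c(sprintf(
    "LOCUS       %-16s %d bp    DNA     %s   INV",
    genome$id, len, if (genome$circular) "circular" else "linear"),
    sprintf("DEFINITION  %s mitochondrion, complete genome.",
            if (nzchar(genome$taxon)) genome$taxon else genome$id),
    sprintf("ACCESSION   %s", genome$id),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s",
            if (nzchar(genome$taxon)) genome$taxon else "unknown"),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("                     /organism=\"%s\"",
            if (nzchar(genome$taxon)) genome$taxon else "unknown"))
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    key <- switch(f$type, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop")
    out <- c(out, sprintf("     %-15s %s", key, format_gb_location(f, len)),
             sprintf("                     /gene=\"%s\"", f$name))
    if (f$type == "PCG") {
      out <- c(out,
               sprintf("                     /codon_start=%d",
                       f$codon_offset + 1L),
               "                     /transl_table=5")
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substring(genome$sequence, p, min(p + 59L, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sequence extraction and codon validation

#' Extract a gene sequence in its reading orientation
#'
#' J-strand features are returned verbatim, N-strand features
#' reverse-complemented; origin-spanning features are concatenated across
#' the junction. For PCGs the returned sequence starts at the annotated
#' reading-frame offset.
#'
#' @param genome a [mitogenome()].
#' @param name canonical gene symbol.
#' @param apply_offset drop the first `codon_offset` bases of a PCG
#'   (default TRUE).
#' @return nucleotide string.
#' @export
extract_gene_sequence <- function(genome, name, apply_offset = TRUE) {
  f <- get_feature(genome, name)
  len <- genome_length(genome)
  raw <- if (f$end > f$start) {
    substring(genome$sequence, f$start + 1L, f$end)
  } else {
    paste0(substring(genome$sequence, f$start + 1L, len),
           substring(genome$sequence, 1L, f$end))
  }
  s <- if (f$strand == "N") revcomp(raw) else raw
  if (apply_offset && f$type == "PCG" && f$codon_offset > 0L) {
    s <- substring(s, f$codon_offset + 1L)
  }
  s
}

#' Validate PCG start and stop codons
#'
#' Start codons are classed canonical-ATN, canonical-TTN or unconventional
#' (unconventional starts such as CTG, GTA, CGA and AGA occur in some
#' arthropod cox1 genes); stops are classed complete, truncated-T or
#' truncated-TA by the residual length of the reading frame — incomplete
#' stops are completed to TAA by transcript polyadenylation.
#'
#' @param genome a [mitogenome()].
#' @return data.frame with one row per PCG: `gene`, `start_codon`,
#'   `stop_codon`, `start_class`, `stop_class`.
#' @export
validate_pcg_codons <- function(genome) {
  pcgs <- genome$features[genome$features$type == "PCG", , drop = FALSE]
  rows <- lapply(pcgs$name, function(nm) {
    s <- extract_gene_sequence(genome, nm)
    L <- nchar(s)
    start_codon <- substring(s, 1, 3)
    rem <- L %% 3L
    if (rem == 0L) {
      stop_codon <- substring(s, L - 2, L); stop_class <- "complete"
    } else if (rem == 1L) {
      stop_codon <- substring(s, L, L); stop_class <- "truncated-T"
    } else {
      stop_codon <- substring(s, L - 1, L); stop_class <- "truncated-TA"
    }
    start_class <- if (grepl("^AT[ACGT]$", start_codon)) "canonical-ATN"
      else if (grepl("^TT[ACGT]$", start_codon)) "canonical-TTN"
      else "unconventional"
    data.frame(gene = nm, start_codon = start_codon, stop_codon = stop_codon,
               start_class = start_class, stop_class = stop_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Feature table and FASTA I/O

#' Tabulate features of one or more genomes
#'
#' @param genomes a [mitogenome()] or list of them.
#' @return data.frame: genome, gene, type, start, end, strand, length.
#' @export
feature_table <- function(genomes) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  do.call(rbind, lapply(genomes, function(g) {
    len <- genome_length(g)
    data.frame(
      genome = g$id, gene = g$features$name, type = g$features$type,
      start = g$features$start, end = g$features$end,
      strand = g$features$strand,
      length = (g$features$end - g$features$start) %% len +
        ifelse(g$features$end == g$features$start, len, 0L),
      stringsAsFactors = FALSE)
  }))
}

#' Read aligned or unaligned FASTA sequences
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
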