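#' Synthetic annotated mitogenomes and diverged genome sets
#'
#' Generator for download-free, parameter-known test inputs with the
#' statistical structure the analyses assume: a circular genome of 13
#' protein-coding genes, 22 tRNAs, 2 rRNAs and a control region on two
#' strands; AT-rich composition with tunable AT/GC skews hit in
#' expectation by compensating the non-coding base distribution for the
#' coding-sequence composition; codon usage with tunable GC3, GC12 and a
#' usage-concentration knob controlling the effective number of codons;
#' gene orders transformed by explicit TDRL events; a control-region
#' tandem repeat with partial copies; and a codon-level divergence
#' simulator with tunable omega (Ka/Ks) and transition bias kappa.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# amino-acid base weights shaped like an AT-rich arthropod mitochondrial
# proteome (Leu/Ile/Phe/Ser-heavy); tilted at run time to hit target GC12
AA_BASE_WEIGHTS <- c(
  L = 0.14, I = 0.10, F = 0.09, S = 0.11, M = 0.06, N = 0.06, K = 0.05,
  T = 0.06, A = 0.05, V = 0.06, G = 0.06, P = 0.04, Y = 0.04, W = 0.02,
  H = 0.02, Q = 0.02, E = 0.03, D = 0.03, C = 0.01, R = 0.02)

PCG_DEFAULT_LENGTHS <- c(
  cox1 = 1539, cox2 = 684, cox3 = 786, atp6 = 666, atp8 = 156,
  cytb = 1119, nad1 = 936, nad2 = 960, nad3 = 336, nad4 = 1338,
  nad4L = 270, nad5 = 1575, nad6 = 432)

codon_gc12 <- function(codon) {
  ch <- seq_chars(codon)
  mean(ch[1:2] %in% c("G", "C"))
}

#' Codon sampling distribution with target GC3, GC12 and usage concentration
#'
#' Two-level construction per synonymous family: third-position class mass
#' (AT-ending vs GC-ending codons) carries the GC3 target exactly; within
#' the AT-ending class one preferred codon takes extra mass
#' 1/m + concentration * (1 - 1/m), which lowers the implied ENC. The
#' amino-acid distribution is an exponential tilt of AT-rich base weights
#' solved (uniroot) so the expected GC12 matches its target.
#'
#' @param gc3 target third-position GC fraction.
#' @param gc12 target mean GC of positions 1 and 2.
#' @param concentration within-family usage concentration in `[0, 1)`
#'   (0 = no preferred-codon boost within third-position class).
#' @param c_penalty strength of the within-family bias against C-rich
#'   codons (weight factor `exp(-c_penalty * #C)`), mirroring the strong
#'   C avoidance of AT-skewed mitogenomes; the preferred codon of each
#'   family is its most T-rich/C-poor AT-ending codon (UUA for Leu).
#' @param code translation table id.
#' @return data.frame `codon`, `aa`, `prob` with attributes
#'   `implied_enc`, `implied_gc3`, `implied_gc12`.
#' @export
codon_distribution <- function(gc3 = 0.12, gc12 = 0.30,
                               concentration = 0.5, c_penalty = 1.0,
                               code = 5) {
  stopifnot(gc3 >= 0, gc3 <= 1, gc12 >= 0, gc12 <= 1,
            concentration >= 0, concentration < 1)
  fams <- codon_families(code)
  count_base <- function(codon, b) {
    sum(seq_chars(codon) == b)
  }
  # within-family conditional probabilities
  cond <- numeric(nrow(fams))
  for (aa in unique(fams$aa)) {
    idx <- which(fams$aa == aa)
    ends <- substring(fams$codon[idx], 3, 3)
    is_gc <- ends %in% c("G", "C")
    p <- numeric(length(idx))
    m_at <- sum(!is_gc); m_gc <- sum(is_gc)
    at_mass <- if (m_at > 0 && m_gc > 0) 1 - gc3 else as.numeric(m_at > 0)
    gc_mass <- 1 - at_mass
    nC <- vapply(fams$codon[idx], count_base, 0, b = "C")
    nT <- vapply(fams$codon[idx], count_base, 0, b = "T")
    if (m_at > 0) {
      w <- exp(-c_penalty * nC[!is_gc])
      w <- (1 - concentration) * w / sum(w)
      pref <- which.max(nT[!is_gc] - nC[!is_gc])
      w[pref] <- w[pref] + concentration
      p[!is_gc] <- at_mass * w
    }
    if (m_gc > 0) {
      w <- exp(-c_penalty * nC[is_gc])
      p[is_gc] <- gc_mass * w / sum(w)
    }
    cond[idx] <- p
  }
  gcc12 <- vapply(fams$codon, codon_gc12, 0)
  aa_names <- names(AA_BASE_WEIGHTS)
  base_w <- AA_BASE_WEIGHTS / sum(AA_BASE_WEIGHTS)
  expected_gc12 <- function(lambda) {
    w <- base_w * exp(lambda * vapply(aa_names, function(a) {
      idx <- fams$aa == a
      sum(cond[idx] * gcc12[idx])
    }, 0))
    w <- w / sum(w)
    p_aa <- stats::setNames(as.numeric(w), aa_names)
    sum(p_aa[fams$aa] * cond * gcc12)
  }
  lam <- stats::uniroot(function(l) expected_gc12(l) - gc12,
                        c(-40, 40), tol = 1e-9)$root
  w <- base_w * exp(lam * vapply(aa_names, function(a) {
    idx <- fams$aa == a
    sum(cond[idx] * gcc12[idx])
  }, 0))
  p_aa <- stats::setNames(as.numeric(w / sum(w)), aa_names)
  out <- fams
  out$prob <- p_aa[out$aa] * cond
  # implied statistics under iid sampling from this distribution
  F_by_aa <- vapply(split(seq_len(nrow(out)), out$aa), function(idx) {
    pc <- cond[idx]
    sum(pc^2)
  }, 0)
  sizes <- vapply(split(out$family_size, out$aa), function(x) x[1], 0L)
  classes <- sort(unique(sizes))
  implied_enc <- sum(vapply(classes, function(k) {
    sum(sizes == k) / mean(F_by_aa[sizes == k])
  }, 0))
  ends_gc <- substring(out$codon, 3, 3) %in% c("G", "C")
  attr(out, "implied_enc") <- min(implied_enc, nrow(out))
  attr(out, "implied_gc3") <- sum(out$prob * ends_gc)
  attr(out, "implied_gc12") <- sum(out$prob * vapply(out$codon,
                                                     codon_gc12, 0))
  out
}

#' Specification for a synthetic mitogenome
#'
#' Defaults emulate a jumping-spider-like mitogenome: ~14.8 kb, AT
#' content 0.74 with AT skew -0.12 and GC skew 0.36 on the J strand,
#' GC3 0.12 and GC12 0.30 (the observed salticid ranges are roughly
#' 0.06-0.215 and 0.288-0.329), moderate codon-usage concentration, a
#' 24-nt control-region tandem repeat with partial copies of 22 and 9 nt,
#' and a handful of truncated stop codons.
#'
#' @param seed integer random seed (fixed seed => byte-identical output).
#' @param at_content,at_skew,gc_skew full-genome J-strand composition
#'   targets.
#' @param gc3,gc12,concentration codon-usage targets, see
#'   [codon_distribution()].
#' @param tdrl_events list of TDRL events applied to the reference order;
#'   each event is `list(block = <contiguous gene names>, keep_first =
#'   <subset surviving in the first copy>)`.
#' @param cr_repeat `NULL` or `list(motif=, copies=, partial_lead=,
#'   partial_trail=)` (partials in nt; lead is a motif suffix, trail a
#'   motif prefix).
#' @param cr_length total control-region length.
#' @param truncated_stops PCGs given a truncated (single-T) stop codon.
#' @param pcg_lengths named lengths (complete-stop equivalents).
#' @param trna_length,rrnl_length,rrns_length RNA gene lengths.
#' @param reference_order a [gene_order()]; defaults to the packaged one.
#' @param code translation table id.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, at_content = 0.74, at_skew = -0.12,
                           gc_skew = 0.36, gc3 = 0.12, gc12 = 0.30,
                           concentration = 0.5, tdrl_events = list(),
                           cr_repeat = list(motif = "TATTAGGTATAATTACAATTATTA",
                                            copies = 5L,
                                            partial_lead = 22L,
                                            partial_trail = 9L),
                           cr_length = 800L,
                           truncated_stops = c("atp6", "cox3", "nad4",
                                               "nad5"),
                           pcg_lengths = PCG_DEFAULT_LENGTHS,
                           trna_length = 66L, rrnl_length = 1260L,
                           rrns_length = 720L,
                           reference_order = NULL, code = 5) {
  if (abs((at_content + (1 - at_content)) - 1) > 1e-9 || at_content < 0 ||
      at_content > 1) {
    stop("infeasible composition target", call. = FALSE)
  }
  if (is.null(reference_order)) reference_order <- reference_gene_order()
  structure(list(
    seed = as.integer(seed), at_content = at_content, at_skew = at_skew,
    gc_skew = gc_skew, gc3 = gc3, gc12 = gc12,
    concentration = concentration, tdrl_events = tdrl_events,
    cr_repeat = cr_repeat, cr_length = as.integer(cr_length),
    truncated_stops = truncated_stops, pcg_lengths = pcg_lengths,
    trna_length = as.integer(trna_length),
    rrnl_length = as.integer(rrnl_length),
    rrns_length = as.integer(rrns_length),
    reference_order = reference_order, code = code),
    class = "synthetic_spec")
}

# apply one TDRL event (duplicate block, keep chosen copies) to an order
apply_tdrl_event <- function(order, event) {
  block <- event$block
  idx <- match(block, order$gene)
  if (anyNA(idx) || !all(diff(sort(idx)) == 1)) {
    stop("TDRL block must be contiguous genes of the current order",
         call. = FALSE)
  }
  idx <- sort(idx)
  in_block_order <- order$gene[idx]
  keep_first <- intersect(in_block_order, event$keep_first)
  keep_second <- setdiff(in_block_order, keep_first)
  new_genes <- c(if (min(idx) > 1) order$gene[1:(min(idx) - 1)],
                 keep_first, keep_second,
                 if (max(idx) < nrow(order))
                   order$gene[(max(idx) + 1):nrow(order)])
  strands <- stats::setNames(order$strand, order$gene)
  gene_order(new_genes, unname(strands[new_genes]),
             genome_id = attr(order, "genome_id"))
}

# quota sampling: item counts fixed at n*probs by largest-remainder
# rounding, order randomized -- composition targets are then hit by
# construction and sampling noise affects arrangement only
quota_sample <- function(items, probs, n) {
  if (n <= 0) return(character(0))
  raw <- probs / sum(probs) * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1L
  }
  sample(rep(items, times = cnt))
}

sample_bases <- function(n, probs) {
  if (n <= 0) return("")
  paste(quota_sample(BASES, probs[BASES], n), collapse = "")
}

base_counts_of <- function(s) {
  ch <- seq_chars(s)
  vapply(BASES, function(b) sum(ch == b), 0L)
}

flip_counts <- function(cnt) {
  c(A = unname(cnt["T"]), C = unname(cnt["G"]),
    G = unname(cnt["C"]), T = unname(cnt["A"]))
}

#' Generate a synthetic annotated mitogenome
#'
#' See [synthetic_spec()] for the tunable structure. The non-coding and
#' RNA-gene base distribution is solved so that the expected full-genome
#' J-strand composition equals the spec targets given the coding-sequence
#' codon distribution; an unattainable target raises an infeasibility
#' error instead of silently drifting.
#'
#' @param spec a [synthetic_spec()].
#' @param id,taxon labels for the genome.
#' @return a [mitogenome()] with attribute `truth` (a list of generating
#'   parameters: codon distribution, implied ENC/GC3/GC12, order applied).
#' @export
generate_mitogenome <- function(spec, id = "SYN000001",
                                taxon = "Synthia exempli") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    dist <- codon_distribution(spec$gc3, spec$gc12, spec$concentration,
                               spec$code)
    order <- spec$reference_order
    for (ev in spec$tdrl_events) order <- apply_tdrl_event(order, ev)

    # --- expected composition of the fixed/coding parts (J strand) -----
    strands <- stats::setNames(order$strand, order$gene)
    e_codon <- c(A = 0, C = 0, G = 0, T = 0)
    for (i in seq_len(nrow(dist))) {
      e_codon <- e_codon + dist$prob[i] * base_counts_of(dist$codon[i])
    }
    fixed <- c(A = 0, C = 0, G = 0, T = 0)
    n_rand <- 0L
    pcg_ncod <- integer(0)
    for (g in names(spec$pcg_lengths)) {
      L <- spec$pcg_lengths[[g]]
      ncod <- L %/% 3L - 2L  # minus start and stop
      pcg_ncod[g] <- ncod
      stop_str <- if (g %in% spec$truncated_stops) "T" else "TAA"
      cnt <- ncod * e_codon + base_counts_of(paste0("ATG", stop_str))
      if (strands[g] == "N") cnt <- flip_counts(cnt)
      fixed <- fixed + cnt
    }
    rep_str <- ""
    if (!is.null(spec$cr_repeat)) {
      r <- spec$cr_repeat
      motif <- toupper(r$motif)
      p <- nchar(motif)
      rep_str <- paste0(
        if (r$partial_lead > 0) substring(motif, p - r$partial_lead + 1, p)
        else "",
        paste(rep(motif, r$copies), collapse = ""),
        if (r$partial_trail > 0) substring(motif, 1, r$partial_trail)
        else "")
      fixed <- fixed + base_counts_of(rep_str)  # CR is J-strand
    }
    cr_rand <- spec$cr_length - nchar(rep_str)
    if (cr_rand < 20) stop("cr_length too short for the repeat spec",
                           call. = FALSE)
    n_rand <- 22L * spec$trna_length + spec$rrnl_length +
      spec$rrns_length + cr_rand
    L_total <- sum(vapply(names(spec$pcg_lengths), function(g) {
      spec$pcg_lengths[[g]] - if (g %in% spec$truncated_stops) 2L else 0L
    }, 0)) + n_rand + nchar(rep_str)
    at <- spec$at_content; gc <- 1 - at
    target <- c(A = at * (1 + spec$at_skew) / 2,
                C = gc * (1 - spec$gc_skew) / 2,
                G = gc * (1 + spec$gc_skew) / 2,
                T = at * (1 - spec$at_skew) / 2)
    q <- (target * L_total - fixed) / n_rand
    if (any(q < 0 | q > 1)) {
      stop("infeasible composition: required non-coding base frequencies ",
           "fall outside [0, 1]; relax the targets", call. = FALSE)
    }

    # --- realize sequences ---------------------------------------------
    gene_seqs <- list()    # reading orientation
    for (g in names(spec$pcg_lengths)) {
      codons <- quota_sample(dist$codon, dist$prob, pcg_ncod[g])
      stop_str <- if (g %in% spec$truncated_stops) "T" else "TAA"
      gene_seqs[[g]] <- paste0("ATG", paste(codons, collapse = ""),
                               stop_str)
    }
    for (g in order$gene[!order$gene %in%
                         c(names(spec$pcg_lengths), "CR")]) {
      len <- switch(g, rrnL = spec$rrnl_length, rrnS = spec$rrns_length,
                    spec$trna_length)
      gene_seqs[[g]] <- sample_bases(len, q)
    }
    lead <- sample_bases(cr_rand %/% 2L, q)
    trail <- sample_bases(cr_rand - cr_rand %/% 2L, q)
    gene_seqs[["CR"]] <- paste0(lead, rep_str, trail)

    # --- assemble the J strand along the order -------------------------
    pos <- 0L
    feats <- list()
    pieces <- character(0)
    for (i in seq_len(nrow(order))) {
      g <- order$gene[i]
      s <- gene_seqs[[g]]
      # RNA genes and the CR are composition-matched random sequence
      # generated directly on the J strand; only PCGs carry reading-frame
      # structure that must be reverse-complemented into place
      jseq <- if (strands[g] == "N" && g %in% names(spec$pcg_lengths)) {
        revcomp(s)
      } else s
      len <- nchar(jseq)
      ty <- canonical_type(g)
      feats[[i]] <- data.frame(
        name = g, type = ty, start = pos, end = pos + len,
        strand = if (ty == "CR") "J" else strands[g],
        codon_offset = 0L, stringsAsFactors = FALSE)
      pieces <- c(pieces, jseq)
      pos <- pos + len
    }
    genome <- mitogenome(id, paste(pieces, collapse = ""),
                         do.call(rbind, feats), circular = TRUE,
                         taxon = taxon)
    attr(genome, "truth") <- list(
      spec = spec, order = order,
      implied_enc = attr(dist, "implied_enc"),
      implied_gc3 = attr(dist, "implied_gc3"),
      implied_gc12 = attr(dist, "implied_gc12"),
      codon_distribution = dist)
    genome
  })
}

# ---------------------------------------------------------------------------
# codon-level divergence simulation

# single accepted-substitution sweep on a codon vector
mutate_codons <- function(codons, n_subs, omega, kappa, gc) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  accepted <- 0L
  guard <- 0L
  max_tries <- max(1000L, 1000L * n_subs)
  while (accepted < n_subs && guard < max_tries) {
    guard <- guard + 1L
    i <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    old <- substring(codons[i], pos, pos)
    # propose: transition with weight kappa, each transversion weight 1
    alts <- BASES[BASES != old]
    w <- ifelse(alts == transitions[[old]], kappa, 1)
    new_base <- sample(alts, 1L, prob = w)
    cand <- codons[i]
    substring(cand, pos, pos) <- new_base
    if (gc[[cand]] == "*") next
    syn <- gc[[cand]] == gc[[codons[i]]]
    p_acc <- if (syn) min(1, 1 / omega) else min(1, omega)
    if (stats::runif(1) <= p_acc) {
      codons[i] <- cand
      accepted <- accepted + 1L
    }
  }
  codons
}

#' Evolve a genome set under a codon model on a star tree
#'
#' Synonymous changes are accepted at relative rate 1 and nonsynonymous
#' at omega (acceptance/rejection on proposed single-base changes);
#' transitions are proposed kappa times as often as each transversion;
#' proposals through stop codons are rejected. Alignments are gap-free.
#'
#' @param root a [mitogenome()] (typically from [generate_mitogenome()]).
#' @param n_taxa number of tip genomes.
#' @param branch_length expected substitutions per nucleotide site on
#'   each root-to-tip branch.
#' @param omega Ka/Ks target (>= 0; 0 allowed: synonymous-only).
#' @param kappa transition/transversion proposal ratio (default 1, the
#'   mutation model the NG86 site counting assumes; under kappa > 1 the
#'   NG86 ratio is biased downward, see the methods vignette).
#' @param seed random seed.
#' @param genes PCGs to simulate (default: all 13).
#' @return list: `alignments` (named list of codon-aware
#'   [alignment_set()]s), `taxa`, `realized` (data.frame of accepted
#'   substitution counts per taxon).
#' @export
evolve_set <- function(root, n_taxa = 4L, branch_length = 0.05,
                       omega = 0.2, kappa = 1, seed = 1L, genes = NULL) {
  stopifnot(inherits(root, "mitogenome"))
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  if (is.null(genes)) {
    genes <- root$features$name[root$features$type == "PCG"]
  }
  gc <- genetic_code(5)
  with_seed(seed, {
    root_codons <- lapply(genes, function(g) {
      s <- strip_terminal_stop(extract_gene_sequence(root, g))
      cod <- split_codons(s)
      cod[!vapply(cod, function(cd) grepl("[^ACGT]", cd) ||
                    gc[[cd]] == "*", TRUE)]
    })
    names(root_codons) <- genes
    taxa <- sprintf("taxon%02d", seq_len(n_taxa))
    tip_codons <- list()
    realized <- data.frame(taxon = taxa, n_subs = 0L)
    for (t in seq_len(n_taxa)) {
      cods <- root_codons
      L_nt <- 3L * sum(lengths(cods))
      n_subs <- stats::rpois(1L, branch_length * L_nt)
      # distribute substitutions over genes by length
      gene_n <- stats::rmultinom(1, n_subs,
                                 prob = lengths(cods) / sum(lengths(cods)))
      if (omega == 0) {
        # synonymous-only: accept no nonsynonymous change at all
        for (g in genes) {
          cods[[g]] <- mutate_codons_syn_only(cods[[g]], gene_n[g, 1], gc,
                                              kappa)
        }
      } else {
        for (g in genes) {
          cods[[g]] <- mutate_codons(cods[[g]], gene_n[g, 1], omega,
                                     kappa, gc)
        }
      }
      tip_codons[[taxa[t]]] <- cods
      realized$n_subs[t] <- n_subs
    }
    alignments <- lapply(genes, function(g) {
      seqs <- vapply(taxa, function(tx) {
        paste(tip_codons[[tx]][[g]], collapse = "")
      }, "")
      alignment_set(seqs, gene = g, codon_aware = TRUE)
    })
    names(alignments) <- genes
    list(alignments = alignments, taxa = taxa, realized = realized)
  })
}

mutate_codons_syn_only <- function(codons, n_subs, gc, kappa) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  accepted <- 0L
  guard <- 0L
  max_tries <- max(1000L, 2000L * n_subs)
  while (accepted < n_subs && guard < max_tries) {
    guard <- guard + 1L
    i <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    old <- substring(codons[i], pos, pos)
    alts <- BASES[BASES != old]
    w <- ifelse(alts == transitions[[old]], kappa, 1)
    new_base <- sample(alts, 1L, prob = w)
    cand <- codons[i]
    substring(cand, pos, pos) <- new_base
    if (gc[[cand]] == "*" || gc[[cand]] != gc[[codons[i]]]) next
    codons[i] <- cand
    accepted <- accepted + 1L
  }
  codons
}

#' Generate a panel of genomes for neutrality-plot recovery
#'
#' Draws per-genome GC3 targets on a grid and couples the GC12 target
#' linearly (`gc12 = intercept + coupling * gc3`); each genome's coding
#' set is sampled iid from its own [codon_distribution()]. The OLS slope
#' of measured GC12 on measured GC3 then recovers `coupling`.
#'
#' @param n_genomes number of genomes.
#' @param gc3_range range of the GC3 grid.
#' @param coupling,intercept linear coupling of GC12 to GC3.
#' @param n_codons codons sampled per genome.
#' @param concentration see [codon_distribution()].
#' @param seed random seed.
#' @return data.frame: genome, gc3_target, gc12_target, gc1..gc3, gc12,
#'   enc (measured).
#' @export
neutrality_panel <- function(n_genomes = 10L, gc3_range = c(0.06, 0.22),
                             coupling = 0.25, intercept = 0.27,
                             n_codons = 3000L, concentration = 0.5,
                             seed = 1L) {
  with_seed(seed, {
    gc3s <- seq(gc3_range[1], gc3_range[2], length.out = n_genomes)
    rows <- lapply(seq_len(n_genomes), function(i) {
      gc12_t <- intercept + coupling * gc3s[i]
      dist <- codon_distribution(gc3s[i], gc12_t, concentration)
      codons <- sample(dist$codon, n_codons, replace = TRUE,
                       prob = dist$prob)
      seqs <- paste(codons, collapse = "")
      pg <- positional_gc(seqs)
      tab <- count_codons(seqs)
      data.frame(genome = sprintf("panel%02d", i), gc3_target = gc3s[i],
                 gc12_target = gc12_t, gc1 = pg$gc1, gc2 = pg$gc2,
                 gc3 = pg$gc3, gc12 = pg$gc12,
                 enc = as.numeric(enc(tab)),
                 implied_enc = attr(dist, "implied_enc"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
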