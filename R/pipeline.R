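#' One-command comparative-mitogenomics pipeline
#'
#' Runs every analysis over a directory of GenBank files (plus optional
#' per-gene codon-aware alignments) and writes the full table bundle:
#' composition, codon usage and bias summaries, ENC-GC3 and neutrality
#' plot data, sliding-window diversity, distance matrices, Ka/Ks, gene
#' orders and rearrangement calls, control-region repeats, NJ trees and
#' a JSON run manifest. Partial inputs (missing control regions, missing
#' alignments) degrade gracefully with stable-coded warnings.
#'
#' @name cli_report
NULL

#' Pipeline configuration
#'
#' Defaults follow the study settings for this genome class: translation
#' table 5, a 100-bp window with 25-bp step for sliding-window diversity,
#' and the pooled-composite distance model.
#'
#' @param genbank_dir directory of `.gb`/`.gbk`/`.gbff` files (or a
#'   vector of file paths).
#' @param alignment_dir optional directory of per-gene aligned FASTA
#'   (`<gene>.fasta`, codon-aware).
#' @param out_dir output directory (created).
#' @param anchor linearization anchor gene.
#' @param code translation table id.
#' @param window,step sliding-window parameters (nt).
#' @param distance_model see [pairwise_distance()].
#' @param deletion gap policy, see [nucleotide_diversity()].
#' @param reference_order_path optional TSV overriding the packaged
#'   reference order.
#' @param repeat_params list passed to [find_tandem_repeats()].
#' @param seed seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genbank_dir, alignment_dir = NULL, out_dir,
                            anchor = "cox1", code = 5, window = 100L,
                            step = 25L,
                            distance_model = "MCL-composite",
                            deletion = "complete",
                            reference_order_path = NULL,
                            repeat_params = list(), seed = 1L) {
  structure(list(genbank_dir = genbank_dir, alignment_dir = alignment_dir,
                 out_dir = out_dir, anchor = anchor, code = code,
                 window = as.integer(window), step = as.integer(step),
                 distance_model = distance_model, deletion = deletion,
                 reference_order_path = reference_order_path,
                 repeat_params = repeat_params, seed = as.integer(seed)),
            class = "pipeline_config")
}

list_genbank_files <- function(x) {
  if (length(x) == 1 && dir.exists(x)) {
    list.files(x, pattern = "\\.(gb|gbk|gbff)$", full.names = TRUE)
  } else {
    x[file.exists(x)]
  }
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results; files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- list_genbank_files(config$genbank_dir)
  if (length(files) == 0) stop("empty input set: no GenBank files found",
                               call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) stop("cannot create output directory",
                                        call. = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  genomes <- lapply(files, parse_genbank)
  names(genomes) <- vapply(genomes, function(g) g$id, "")

  # composition ------------------------------------------------------------
  comp <- do.call(rbind, lapply(genomes, region_composition))
  write_composition_tsv(comp, out("composition.tsv"))

  # codon usage ------------------------------------------------------------
  usage_rows <- lapply(genomes, function(g) {
    cds <- vapply(g$features$name[g$features$type == "PCG"],
                  function(n) extract_gene_sequence(g, n), "")
    tab <- rscu(count_codons(cds, config$code))
    cbind(genome = g$id, as.data.frame(tab), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, usage_rows), out("codon_usage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bias <- do.call(rbind, lapply(genomes, codon_bias_summary,
                                code = config$code))
  utils::write.table(bias, out("bias_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(enc_gc3_plotdata(bias), out("enc_gc3_plotdata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  neut <- NULL
  if (nrow(bias) >= 3 && stats::sd(bias$gc3) > 0) {
    neut <- neutrality_fit(bias$gc3, bias$gc12)
    nd <- data.frame(genome = bias$genome, gc3 = bias$gc3,
                     gc12 = bias$gc12,
                     fit = neut$intercept + neut$slope * bias$gc3)
    utils::write.table(nd, out("neutrality_plotdata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(c(
      sprintf("slope\t%.6f", neut$slope),
      sprintf("intercept\t%.6f", neut$intercept),
      sprintf("pearson_r\t%.6f", neut$r),
      sprintf("p_value\t%.6g", neut$p_value),
      sprintf("mutation_share_pct\t%.1f", neut$mutation_share_pct),
      sprintf("selection_share_pct\t%.1f", neut$selection_share_pct)),
      out("neutrality_fit.tsv"))
  } else {
    warning("fewer than 3 genomes: neutrality fit skipped [W_NO_NEUTRALITY]",
            call. = FALSE)
  }

  # validation -------------------------------------------------------------
  val <- do.call(rbind, lapply(genomes, function(g) {
    cbind(genome = g$id, validate_pcg_codons(g), stringsAsFactors = FALSE)
  }))
  utils::write.table(val, out("codon_validation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # alignments: diversity, distances, Ka/Ks, trees --------------------------
  kaks_all <- NULL
  if (!is.null(config$alignment_dir) && dir.exists(config$alignment_dir)) {
    aln_files <- list.files(config$alignment_dir,
                            pattern = "\\.(fa|fasta|fna)$",
                            full.names = TRUE)
    pi_rows <- list(); kaks_rows <- list()
    dir.create(out("distances"), showWarnings = FALSE)
    for (f in aln_files) {
      aln <- read_alignment(f, codon_aware = TRUE)
      if (aln$length >= config$window) {
        wd <- sliding_window_pi(aln, config$window, config$step,
                                config$deletion)
        pi_rows[[aln$gene]] <- cbind(gene = aln$gene, wd$windows,
                                     overall_pi = wd$overall_pi,
                                     stringsAsFactors = FALSE)
      }
      d <- suppressWarnings(pairwise_distance(aln, config$distance_model))
      write_distance_matrix(
        d, out("distances", sprintf("%s.%s.tsv", aln$gene,
                                    config$distance_model)),
        out("distances", sprintf("%s.%s.phy", aln$gene,
                                 config$distance_model)))
      if (!anyNA(d)) {
        writeLines(nj_tree(d),
                   out(sprintf("nj.%s.%s.nwk", aln$gene,
                               config$distance_model)))
      }
      kaks_rows[[aln$gene]] <- kaks_table(aln, config$code)
    }
    if (length(pi_rows) > 0) {
      utils::write.table(do.call(rbind, pi_rows), out("pi_windows.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(kaks_rows) > 0) {
      kaks_all <- do.call(rbind, kaks_rows)
      utils::write.table(kaks_all, out("kaks.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else {
    warning("no alignment directory: diversity/distances/KaKs skipped ",
            "[W_NO_ALIGNMENTS]", call. = FALSE)
  }

  # gene order --------------------------------------------------------------
  ref <- reference_gene_order(config$reference_order_path)
  orders <- lapply(genomes, extract_gene_order, anchor = config$anchor)
  calls <- lapply(orders, function(o) {
    if (setequal(o$gene, ref$gene)) compare_orders(o, ref) else {
      warning("genome ", attr(o, "genome_id"),
              " has a partial gene set; order not compared [W_PARTIAL_SET]",
              call. = FALSE)
      NULL
    }
  })
  calls <- calls[!vapply(calls, is.null, TRUE)]
  write_gene_order_tsv(orders, calls, out("gene_orders.tsv"),
                       out("rearrangements.tsv"))

  # control-region repeats ---------------------------------------------------
  hits <- list()
  for (g in genomes) {
    if (!"CR" %in% g$features$name) next
    cr <- extract_gene_sequence(g, "CR")
    hits[[g$id]] <- do.call(find_tandem_repeats,
                            c(list(cr), config$repeat_params))
  }
  write_repeats(hits, out("repeats.tsv"), out("repeats.bed"))

  # manifest -----------------------------------------------------------------
  manifest <- list(
    package = "mitocomp",
    version = as.character(utils::packageVersion("mitocomp")),
    config = config[setdiff(names(config), "reference_order")],
    inputs = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    genomes = names(genomes))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genomes = genomes, composition = comp, bias = bias,
                 neutrality = neut, orders = orders, calls = calls,
                 repeats = hits, kaks = kaks_all))
}
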