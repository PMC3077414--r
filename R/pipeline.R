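#' Configuration for a full pipeline run
#'
#' All inputs are optional except the fragments; a stage whose input is
#' missing is skipped and noted in the run log. Paths and in-memory
#' objects are both accepted.
#'
#' @param fragments Fragment FASTA path or [Biostrings::DNAStringSet].
#' @param genome Genome FASTA path or [Biostrings::DNAStringSet]
#'   (required for the AT-background and scan stages).
#' @param genes Gene-model file path (BED12/GFF3 by extension) or a list
#'   of [gene_model()] objects.
#' @param loci Fragment coordinates: TSV path or data frame with
#'   `fragment_id`, `chrom`, `start`, `end` (0-based half-open). Required
#'   for the annotation stage.
#' @param patterns IUPAC pattern file path or character vector.
#' @param qpcr qPCR Ct table path or data frame.
#' @param outdir Output directory (created if absent).
#' @param window_size AT-background window size in bp.
#' @param word_size Seed word length for the short-match stage.
#' @param segment_lengths Segment lengths collected for the logos.
#' @param strands Scan strand mode, `"forward"` or `"both"`.
#' @param seed Integer seed recorded in the log (the analysis stages are
#'   deterministic; the seed matters when inputs are simulated upstream).
#' @return A `run_config` list.
#' @export
run_config <- function(fragments, genome = NULL, genes = NULL, loci = NULL,
                       patterns = NULL, qpcr = NULL, outdir,
                       window_size = 500L, word_size = 7L,
                       segment_lengths = c(11L, 12L),
                       strands = c("forward", "both"), seed = 1L) {
  strands <- match.arg(strands)
  for (p in list(fragments, genome, genes, loci, patterns, qpcr)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop("input file not found: ", p)
    }
  }
  structure(
    list(
      fragments = fragments, genome = genome, genes = genes, loci = loci,
      patterns = patterns, qpcr = qpcr, outdir = outdir,
      window_size = as.integer(window_size),
      word_size = as.integer(word_size),
      segment_lengths = as.integer(segment_lengths),
      strands = strands, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

.load_fragments <- function(x) {
  if (is.character(x) && length(x) == 1L) read_fasta(x) else x
}

.load_genes <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    fmt <- if (grepl("\\.bed$", x, ignore.case = TRUE)) "bed12" else "gff3"
    read_gene_models(x, format = fmt)
  } else {
    x
  }
}

.load_loci <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else {
    x
  }
}

#' Run the fragment-characterization pipeline end-to-end
#'
#' Executes, in order: AT-composition comparison, consensus genome scan,
#' cross-fragment short matching with logo construction, qPCR enrichment,
#' and locus annotation. Each stage writes its outputs to the configured
#' directory; a run log records parameters, the seed and which stages ran.
#' Re-running with an identical config reproduces the data outputs
#' byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `outputs` (named vector of written file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("chipfrag pipeline run"),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("chipfrag"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %d", config$seed),
    sprintf("window_size: %d", config$window_size),
    sprintf("word_size: %d", config$word_size),
    sprintf("segment_lengths: %s",
            paste(config$segment_lengths, collapse = ",")),
    sprintf("strands: %s", config$strands)
  )
  outputs <- character(0)
  results <- list()
  out_path <- function(name) file.path(config$outdir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  fragments <- stage("load_fragments", .load_fragments(config$fragments))

  # --- composition_stats -------------------------------------------------
  if (!is.null(config$genome)) {
    genome <- stage("load_genome",
                    if (is.character(config$genome)) {
                      read_fasta(config$genome)
                    } else {
                      config$genome
                    })
    cmp <- stage("atstats", compare_fragments_to_genome(
      fragments, genome, window_size = config$window_size
    ))
    write_at_comparison(cmp, out_path("at_histogram.tsv"),
                        out_path("at_test.json"))
    outputs <- c(outputs, out_path("at_histogram.tsv"),
                 out_path("at_test.json"))
    results$at <- cmp
    log_lines <- c(log_lines, "stage atstats: run")
  } else {
    genome <- NULL
    log_lines <- c(log_lines, "stage atstats: skipped (no genome)")
  }

  # --- motif_engine ------------------------------------------------------
  if (!is.null(config$patterns) && !is.null(genome)) {
    pats <- stage("load_patterns",
                  if (is.character(config$patterns) &&
                      length(config$patterns) == 1L &&
                      file.exists(config$patterns)) {
                    read_patterns(config$patterns)
                  } else {
                    config$patterns
                  })
    expanded <- stage("scan", expand_iupac(pats))
    report <- stage("scan", scan_genome(genome, expanded,
                                        strands = config$strands))
    write_matches_bed(report, out_path("scan_matches.bed"))
    write_scan_summary(report, out_path("scan_summary.json"))
    outputs <- c(outputs, out_path("scan_matches.bed"),
                 out_path("scan_summary.json"))
    results$scan <- report
    log_lines <- c(log_lines, sprintf("stage scan: run (K=%d, n=%d)",
                                      report$K, report$n))
  } else {
    log_lines <- c(log_lines, "stage scan: skipped (no patterns or genome)")
  }

  # --- short_match + logo_builder ---------------------------------------
  if (length(fragments) >= 2L) {
    aligns <- stage("shortmatch",
                    all_pairs_matches(fragments, k = config$word_size))
    write_alignments(aligns, out_path("alignments.tsv"))
    outputs <- c(outputs, out_path("alignments.tsv"))
    results$alignments <- aligns
    results$logos <- list()
    for (sl in config$segment_lengths) {
      segs <- stage("logo", collect_segments(aligns, sl, fragments))
      fa <- out_path(sprintf("segments_%d.fasta", sl))
      write_segments_fasta(segs, fa)
      outputs <- c(outputs, fa)
      if (segs$n > 0L) {
        logo <- information_content(build_pfm(segs))
        tsv <- out_path(sprintf("logo_%d.tsv", sl))
        write_logo_tsv(logo, tsv)
        outputs <- c(outputs, tsv)
        results$logos[[as.character(sl)]] <- logo
        log_lines <- c(log_lines,
                       sprintf("stage logo %d: run (%d segments)", sl, segs$n))
      } else {
        log_lines <- c(log_lines,
                       sprintf("stage logo %d: no segments", sl))
      }
    }
    log_lines <- c(log_lines,
                   sprintf("stage shortmatch: run (%d alignments)",
                           nrow(aligns)))
  } else {
    log_lines <- c(log_lines, "stage shortmatch: skipped (<2 fragments)")
  }

  # --- chip_quant --------------------------------------------------------
  if (!is.null(config$qpcr)) {
    qtab <- stage("qpcr",
                  if (is.character(config$qpcr)) {
                    read_qpcr_table(config$qpcr)
                  } else {
                    config$qpcr
                  })
    enr <- stage("qpcr", fold_enrichment(qtab))
    write_enrichment_table(enr, out_path("enrichment.tsv"))
    outputs <- c(outputs, out_path("enrichment.tsv"))
    results$enrichment <- enr
    log_lines <- c(log_lines,
                   sprintf("stage qpcr: run (mean fold %.2f)",
                           mean_enrichment(enr)))
  } else {
    log_lines <- c(log_lines, "stage qpcr: skipped (no Ct table)")
  }

  # --- locus_annotator ---------------------------------------------------
  if (!is.null(config$genes) && !is.null(config$loci)) {
    genes <- stage("annotate", .load_genes(config$genes))
    loci <- stage("annotate", .load_loci(config$loci))
    ann <- stage("annotate", classify_loci(loci, genes))
    rep_df <- write_locus_report(ann, loci, fragments,
                                 out_path("fragment_report.tsv"))
    outputs <- c(outputs, out_path("fragment_report.tsv"))
    results$annotations <- ann
    results$tally <- tally_annotations(ann)
    log_lines <- c(
      log_lines,
      sprintf("stage annotate: run (%s)",
              paste(names(results$tally$by_category),
                    results$tally$by_category,
                    sep = "=", collapse = ", "))
    )
  } else {
    log_lines <- c(log_lines, "stage annotate: skipped (no genes or loci)")
  }

  log_lines <- c(log_lines, sprintf("finished: %s", format(Sys.time())))
  writeLines(log_lines, out_path("run_log.txt"))
  results$outputs <- c(outputs, out_path("run_log.txt"))
  invisible(results)
}
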