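#' Read a multi-record FASTA file into a genome assembly
#'
#' Sequences are uppercased on read. Only the unambiguous DNA alphabet plus
#' `N` is accepted in sequence files; IUPAC ambiguity codes belong in pattern
#' files (see [read_patterns()]), not in genomes or fragments, so that exact
#' scanning semantics stay unambiguous.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique record ids as names.
#'   Record ids are the FASTA header up to the first whitespace.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">frag1", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) {
    stop("no records in FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == "")) {
    stop("empty record id in FASTA file: ", path)
  }
  if (anyDuplicated(ids)) {
    stop(
      "duplicate record ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  names(x) <- ids
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  bad <- Biostrings::letterFrequency(x, letters = "ACGTN") !=
    Biostrings::width(x)
  if (any(bad)) {
    for (i in which(bad)) {
      chars <- strsplit(as.character(x[[i]]), "")[[1]]
      pos <- which(!chars %in% c("A", "C", "G", "T", "N"))
      stop(
        "illegal character '", chars[pos[1]], "' in record '", ids[i],
        "' at position ", pos[1],
        " (only A/C/G/T/N are allowed in sequence files)"
      )
    }
  }
  x
}

#' Total length of a genome assembly
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Total number of bases summed over all records.
#' @export
genome_length <- function(genome) {
  sum(as.numeric(Biostrings::width(genome)))
}

#' Write sequences to a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all records must be named")
  }
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is one transcript-like unit: a chromosome, a strand, and a
#' sorted set of non-overlapping exons. All coordinates are 0-based
#' half-open internally; user-facing reports print 1-based inclusive.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon boundaries, 0-based
#'   half-open. Exons must be sorted ascending and non-overlapping (abutting
#'   exons are not merged but are rejected as overlapping in spirit only if
#'   they truly intersect).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  if (!strand %in% c("+", "-")) {
    stop("unknown strand symbol '", strand, "' for gene ", gene_id)
  }
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L) {
    stop("gene ", gene_id, ": need at least one exon with matching boundaries")
  }
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts)) {
    stop("gene ", gene_id, ": exon end must exceed exon start")
  }
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]
  exon_ends <- exon_ends[o]
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  structure(
    list(
      gene_id = as.character(gene_id),
      chrom = as.character(chrom),
      strand = strand,
      exon_starts = exon_starts,
      exon_ends = exon_ends,
      span_start = exon_starts[1L],
      span_end = exon_ends[length(exon_ends)]
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(
    sprintf(
      "<gene_model> %s %s:%d-%d (%s), %d exon(s)\n",
      x$gene_id, x$chrom, x$span_start + 1L, x$span_end, x$strand,
      length(x$exon_starts)
    )
  )
  invisible(x)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 is parsed directly (its block fields map one-to-one onto exons and
#' its coordinates are already 0-based half-open); GFF3 is read through
#' `rtracklayer` and gene/exon features are assembled by their `Parent`
#' relations, with 1-based inclusive coordinates converted on read. Either
#' route yields identical `gene_model` values for the same gene.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"gff3"`.
#' @return A list of [gene_model()] objects, named by gene id.
#' @export
read_gene_models <- function(path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("gene model file not found: ", path)
  }
  models <- switch(format,
    bed12 = .read_bed12(path),
    gff3 = .read_gff3_genes(path)
  )
  if (anyDuplicated(vapply(models, `[[`, "", "gene_id"))) {
    stop("duplicate gene ids in ", path)
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models
}

.read_bed12 <- function(path) {
  tab <- utils::read.table(
    path, sep = "\t", header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE, quote = ""
  )
  if (ncol(tab) < 12L) {
    stop("BED12 requires 12 columns, found ", ncol(tab), " in ", path)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    n_blocks <- as.integer(row[[10]])
    sizes <- as.integer(strsplit(as.character(row[[11]]), ",")[[1]])
    starts <- as.integer(strsplit(as.character(row[[12]]), ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop("BED12 line ", i, ": blockCount disagrees with block lists")
    }
    if (is.unsorted(starts, strictly = TRUE)) {
      stop("BED12 line ", i, ": blockStarts must be strictly increasing")
    }
    chrom_start <- as.integer(row[[2]])
    gene_model(
      gene_id = as.character(row[[4]]),
      chrom = as.character(row[[1]]),
      strand = as.character(row[[6]]),
      exon_starts = chrom_start + starts,
      exon_ends = chrom_start + starts + sizes
    )
  })
}

.read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (length(genes) == 0L) {
    stop("no gene features in GFF3 file: ", path)
  }
  gene_ids <- as.character(genes$ID)
  parent <- vapply(
    as.list(exons$Parent),
    function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
    ""
  )
  lapply(seq_along(genes), function(i) {
    g <- genes[i]
    ex <- exons[!is.na(parent) & parent == gene_ids[i]]
    if (length(ex) == 0L) {
      stop("GFF3 gene '", gene_ids[i], "' has no exon children")
    }
    strand <- as.character(BiocGenerics::strand(g))
    if (!strand %in% c("+", "-")) {
      stop("unknown strand symbol '", strand, "' for gene ", gene_ids[i])
    }
    gene_model(
      gene_id = gene_ids[i],
      chrom = as.character(GenomeInfoDb::seqnames(g)),
      strand = strand,
      exon_starts = BiocGenerics::start(ex) - 1L,  # GFF3 is 1-based inclusive
      exon_ends = BiocGenerics::end(ex)
    )
  })
}

#' Write a uniform table of records as TSV
#'
#' Tab-separated, header row, newline-terminated, UTF-8, never quoted;
#' fields must therefore be tab-free.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  has_tab <- vapply(
    rows,
    function(col) any(grepl("\t", as.character(col), fixed = TRUE)),
    logical(1)
  )
  if (any(has_tab)) {
    stop(
      "fields must be tab-free; offending column(s): ",
      paste(names(rows)[has_tab], collapse = ", ")
    )
  }
  utils::write.table(
    rows, file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
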