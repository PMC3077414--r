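#' @keywords internal
.iupac_map <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand IUPAC-degenerate consensus patterns into a plain-sequence set
#'
#' Each degenerate pattern (e.g. `"ATATTCGCGAWWATT"`, where `W` denotes A
#' or T) is expanded by Cartesian product of the base sets its codes denote;
#' the union over all input patterns is returned with duplicates removed.
#'
#' @param patterns Character vector of IUPAC strings, all of equal length.
#' @return Character vector of distinct plain ACGT sequences (sorted), with
#'   attribute `L` (pattern length).
#' @examples
#' expand_iupac("AWWT")                 # 4 variants
#' length(expand_iupac(c("ATATTCGCGAWWATT", "ATATTGCGCAWWATT")))  # 8
#' @export
expand_iupac <- function(patterns) {
  patterns <- toupper(patterns)
  if (length(patterns) < 1L) {
    stop("need at least one pattern")
  }
  L <- unique(nchar(patterns))
  if (length(L) != 1L) {
    stop("all patterns must have the same length; got lengths ",
         paste(sort(L), collapse = ", "))
  }
  if (L < 1L) {
    stop("patterns must be non-empty")
  }
  out <- unlist(lapply(patterns, function(p) {
    codes <- strsplit(p, "")[[1]]
    bad <- !codes %in% names(.iupac_map)
    if (any(bad)) {
      stop("invalid IUPAC code '", codes[bad][1], "' in pattern ", p)
    }
    sets <- .iupac_map[codes]
    grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
    do.call(paste0, rev(grid))
  }))
  out <- sort(unique(out))
  attr(out, "L") <- L
  out
}

#' Read IUPAC patterns from a plain-text file
#'
#' One pattern per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the pattern file.
#' @return Character vector of IUPAC pattern strings.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) {
    stop("pattern file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("no patterns in file: ", path)
  }
  toupper(lines)
}

#' Theoretical spacing of a pattern set under a uniform base model
#'
#' Under an i.i.d. uniform-base model a set of `K` distinct `L`-mers is
#' expected once every `4^L / K` bases. For the two 15-bp HMGA2 consensus
#' patterns expanded to 4,096 variants this is 262,144 bp.
#'
#' @param L Pattern length in bases.
#' @param K Number of distinct plain sequences in the set.
#' @return Expected bases per match.
#' @examples
#' expected_spacing(15, 4096)  # 262144
#' @export
expected_spacing <- function(L, K) {
  if (L < 1L || K < 1L) {
    stop("L and K must be at least 1")
  }
  total <- 4^L
  if (K > total) {
    stop("K may not exceed 4^L (", format(total, scientific = FALSE), ")")
  }
  total / K
}

#' Observed spacing: genome length per match
#'
#' @param G Genome length in bp.
#' @param n Number of matches.
#' @return `G / n` in bp per match.
#' @export
observed_spacing <- function(G, n) {
  if (G < 1) {
    stop("genome length must be at least 1")
  }
  if (n == 0) {
    stop("no matches: observed spacing is undefined")
  }
  G / n
}

#' Overrepresentation ratio of observed versus expected spacing
#'
#' A ratio above 1 means the pattern set occurs more often than the uniform
#' base model predicts (262,144 / 104,565 = 2.5 in the headline analysis).
#'
#' @param expected Expected spacing (bp per match).
#' @param observed Observed spacing (bp per match).
#' @return `expected / observed` (dimensionless).
#' @export
overrepresentation <- function(expected, observed) {
  if (expected <= 0 || observed <= 0) {
    stop("spacings must be positive")
  }
  expected / observed
}

#' Scan a genome for exact occurrences of a plain-sequence pattern set
#'
#' Every occurrence of every member sequence is reported, overlaps
#' included; windows containing `N` never match. A position matching
#' several variants is reported once per (sequence, position, strand).
#' With `strands = "both"`, reverse-strand sites are located by matching
#' the reverse complements of the set and are reported at their leftmost
#' plus-strand coordinate with strand `"-"`.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_fasta()]).
#' @param patterns Character vector of plain ACGT sequences of equal
#'   length, e.g. from [expand_iupac()].
#' @param strands `"forward"` (default) or `"both"`.
#' @return A `match_report` object: list with `matches` (data frame of
#'   `seqid`, `start` (0-based), `strand`, `variant`), `n`, `G`,
#'   `observed_spacing`, `expected_spacing`, `ratio`, `L`, `K`.
#'   Spacings and ratio are `NA` when `n = 0`.
#' @export
scan_genome <- function(genome, patterns, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (length(genome) == 0L) {
    stop("empty genome")
  }
  patterns <- as.character(patterns)
  L <- unique(nchar(patterns))
  if (length(L) != 1L) {
    stop("pattern set must have uniform length")
  }
  if (any(!grepl("^[ACGT]+$", patterns))) {
    stop("pattern set must be plain ACGT; expand IUPAC patterns first")
  }
  patterns <- unique(patterns)
  K <- length(patterns)

  scan_one_orientation <- function(pats_oriented, variant_labels, strand_label) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats_oriented))
    frames <- list()
    for (i in seq_along(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[i]])
      starts <- IRanges::start(m)
      lens <- S4Vectors::elementNROWS(starts)
      if (sum(lens) == 0L) next
      frames[[length(frames) + 1L]] <- data.frame(
        seqid = names(genome)[i],
        start = unlist(starts, use.names = FALSE) - 1L,
        strand = strand_label,
        variant = rep(variant_labels, lens),
        stringsAsFactors = FALSE
      )
    }
    frames
  }

  frames <- scan_one_orientation(patterns, patterns, "+")
  if (strands == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(patterns))
    )
    frames <- c(frames, scan_one_orientation(rc, patterns, "-"))
  }
  matches <- if (length(frames)) {
    do.call(rbind, frames)
  } else {
    data.frame(
      seqid = character(), start = integer(), strand = character(),
      variant = character(), stringsAsFactors = FALSE
    )
  }
  # one site per (seqid, position, strand), keep lexicographically first variant
  matches <- matches[order(matches$seqid, matches$start, matches$strand,
                           matches$variant), , drop = FALSE]
  dup <- duplicated(matches[, c("seqid", "start", "strand")])
  matches <- matches[!dup, , drop = FALSE]
  rownames(matches) <- NULL

  n <- nrow(matches)
  G <- genome_length(genome)
  obs <- if (n > 0) G / n else NA_real_
  exp_sp <- expected_spacing(L, K)
  structure(
    list(
      matches = matches,
      n = n,
      G = G,
      observed_spacing = obs,
      expected_spacing = exp_sp,
      ratio = if (n > 0) exp_sp / obs else NA_real_,
      L = L,
      K = K
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> %d match(es) of a %d-member %d-mer set in %s bp\n",
    x$n, x$K, x$L, format(x$G, big.mark = ",", scientific = FALSE)
  ))
  if (x$n > 0) {
    cat(sprintf(
      "  observed spacing: one per %.0f bp; expected: one per %.0f bp; ratio %.2f\n",
      x$observed_spacing, x$expected_spacing, x$ratio
    ))
  }
  invisible(x)
}

#' Write scan matches as BED6
#'
#' Name column carries the matched variant, score is 0, strand honored.
#'
#' @param report A `match_report` from [scan_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matches_bed <- function(report, path) {
  m <- report$matches
  bed <- data.frame(
    chrom = m$seqid,
    chromStart = m$start,
    chromEnd = m$start + report$L,
    name = m$variant,
    score = rep(0L, nrow(m)),
    strand = m$strand
  )
  utils::write.table(
    bed, file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write the scan summary as JSON
#'
#' @param report A `match_report` from [scan_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan_summary <- function(report, path) {
  jsonlite::write_json(
    list(
      n = report$n,
      G = report$G,
      L = report$L,
      K = report$K,
      observed_spacing = report$observed_spacing,
      expected_spacing = report$expected_spacing,
      ratio = report$ratio
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
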