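#' Classify a fragment locus against gene models
#'
#' The taxonomy used for reporting cloned ChIP fragments:
#' \describe{
#'   \item{intragenic}{the fragment overlaps a gene span; the reported
#'     feature is the exon or intron with the largest overlap, numbered
#'     1-based in transcript orientation (intron 1 of a minus-strand gene
#'     is the gap closest to its highest-coordinate exon). Ties between an
#'     exon and an intron break toward the exon.}
#'   \item{intergenic}{no gene overlap but the chromosome carries genes;
#'     the nearest gene by edge-to-edge distance is reported together with
#'     the fragment's position relative to that gene's transcription
#'     direction (upstream/downstream) and the distance in bp.}
#'   \item{unplaced}{the fragment sits on a contig with no gene models, or
#'     its chromosome is literally `"unplaced"`.}
#' }
#'
#' @param fragment A list or one-row data frame with `fragment_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param genes A list of [gene_model()] objects.
#' @return A one-row data frame: `fragment_id`, `category`, `feature`
#'   (e.g. `"intron 1"`, `NA` unless intragenic), `gene_id`, `relation`
#'   (`"upstream"`/`"downstream"`, `NA` unless intergenic), `distance`
#'   (bp, `NA` unless intergenic).
#' @export
classify_locus <- function(fragment, genes) {
  fragment <- as.list(fragment)
  start <- as.integer(fragment$start)
  end <- as.integer(fragment$end)
  if (is.na(start) || is.na(end) || end <= start) {
    stop("malformed fragment interval: end must exceed start")
  }
  chrom <- as.character(fragment$chrom)
  ans <- data.frame(
    fragment_id = as.character(fragment$fragment_id),
    category = NA_character_, feature = NA_character_,
    gene_id = NA_character_, relation = NA_character_,
    distance = NA_integer_,
    stringsAsFactors = FALSE
  )
  gene_chroms <- vapply(genes, `[[`, "", "chrom")
  on_chrom <- genes[gene_chroms == chrom]
  if (identical(chrom, "unplaced") || length(on_chrom) == 0L) {
    ans$category <- "unplaced"
    return(ans)
  }
  spans_start <- vapply(on_chrom, `[[`, integer(1), "span_start")
  spans_end <- vapply(on_chrom, `[[`, integer(1), "span_end")
  ov <- pmin(end, spans_end) - pmax(start, spans_start)
  if (any(ov > 0L)) {
    # intragenic: gene with the largest overlap, ties to smaller gene_id
    gids <- vapply(on_chrom, `[[`, "", "gene_id")
    best <- order(-ov, gids)[1L]
    g <- on_chrom[[best]]
    ans$category <- "intragenic"
    ans$gene_id <- g$gene_id
    ans$feature <- .best_feature(start, end, g)
    return(ans)
  }
  # intergenic: nearest gene by edge distance; ties to smaller gene_id
  dist_left <- spans_start - end   # fragment entirely left of gene
  dist_right <- start - spans_end  # fragment entirely right of gene
  edge_dist <- pmax(dist_left, dist_right)
  edge_dist[edge_dist < 0L] <- 0L  # abutting
  gids <- vapply(on_chrom, `[[`, "", "gene_id")
  best <- order(edge_dist, gids)[1L]
  g <- on_chrom[[best]]
  frag_left_of_gene <- end <= g$span_start
  relation <- if (g$strand == "+") {
    if (frag_left_of_gene) "upstream" else "downstream"
  } else {
    if (frag_left_of_gene) "downstream" else "upstream"
  }
  ans$category <- "intergenic"
  ans$gene_id <- g$gene_id
  ans$relation <- relation
  ans$distance <- edge_dist[best]
  ans
}

# exon/intron with maximal overlap, strand-aware 1-based numbering;
# exon wins ties
.best_feature <- function(start, end, g) {
  ne <- length(g$exon_starts)
  feats_start <- g$exon_starts
  feats_end <- g$exon_ends
  feats_type <- rep("exon", ne)
  feats_idx_genomic <- seq_len(ne)
  if (ne > 1L) {
    feats_start <- c(feats_start, g$exon_ends[-ne])
    feats_end <- c(feats_end, g$exon_starts[-1L])
    feats_type <- c(feats_type, rep("intron", ne - 1L))
    feats_idx_genomic <- c(feats_idx_genomic, seq_len(ne - 1L))
  }
  # transcript-orientation numbering
  idx <- if (g$strand == "+") {
    feats_idx_genomic
  } else {
    ifelse(feats_type == "exon",
           ne + 1L - feats_idx_genomic,
           ne - feats_idx_genomic)
  }
  ov <- pmin(end, feats_end) - pmax(start, feats_start)
  ov[ov < 0L] <- 0L
  # order: overlap desc, exon before intron on ties, then lower index
  pref <- ifelse(feats_type == "exon", 0L, 1L)
  best <- order(-ov, pref, idx)[1L]
  paste(feats_type[best], idx[best])
}

#' Classify many fragment loci
#'
#' @param loci A data frame with `fragment_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes A list of [gene_model()] objects.
#' @return A data frame, one annotation row per locus (see
#'   [classify_locus()]).
#' @export
classify_loci <- function(loci, genes) {
  stopifnot(is.data.frame(loci), nrow(loci) >= 1L)
  do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    classify_locus(loci[i, ], genes)
  }))
}

#' Tally annotations into the report's marginal counts
#'
#' @param annotations Data frame with `category` and `feature` columns
#'   (from [classify_loci()] or [parse_location_labels()]).
#' @return A list with `n` (total), `by_category` (named integer vector
#'   over intragenic/intergenic/unplaced, a partition of the input),
#'   `by_intron` and `by_exon` (named counts per 1-based feature index).
#' @export
tally_annotations <- function(annotations) {
  cats <- c("intragenic", "intergenic", "unplaced")
  if (nrow(annotations) == 0L) {
    return(list(
      n = 0L,
      by_category = stats::setNames(integer(3L), cats),
      by_intron = integer(0),
      by_exon = integer(0)
    ))
  }
  if (!all(annotations$category %in% cats)) {
    stop("unknown category value")
  }
  by_cat <- vapply(cats, function(cc) sum(annotations$category == cc), 0L)
  feat <- annotations$feature[!is.na(annotations$feature)]
  intron_idx <- as.integer(sub("^intron ", "", feat[grepl("^intron ", feat)]))
  exon_idx <- as.integer(sub("^exon ", "", feat[grepl("^exon ", feat)]))
  list(
    n = nrow(annotations),
    by_category = by_cat,
    by_intron = if (length(intron_idx)) table(intron_idx) else integer(0),
    by_exon = if (length(exon_idx)) table(exon_idx) else integer(0)
  )
}

#' Parse printed locus-report labels into annotations
#'
#' Converts the human-readable columns of a fragment locus report (the
#' style in which cloned ChIP fragments are published: a cytoband or
#' "unplaced" localization plus a "location to gene" label such as
#' `"intron 1"`, `"exon 2"`, `"upstream"` or `"downstream"`) back into
#' category/feature annotations so the marginal counts can be re-tallied.
#'
#' @param localization Character vector; `"unplaced"` flags unplaced rows.
#' @param location_to_gene Character vector of feature/relation labels.
#' @return Data frame with `category` and `feature` columns.
#' @export
parse_location_labels <- function(localization, location_to_gene) {
  loc <- trimws(as.character(location_to_gene))
  category <- ifelse(
    trimws(as.character(localization)) == "unplaced", "unplaced",
    ifelse(grepl("^(intron|exon) [0-9]+$", loc), "intragenic",
      ifelse(loc %in% c("upstream", "downstream"), "intergenic",
             NA_character_)
    )
  )
  if (anyNA(category)) {
    stop("unrecognized location label: ",
         loc[is.na(category)][1])
  }
  data.frame(
    category = category,
    feature = ifelse(category == "intragenic", loc, NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write a fragment locus report
#'
#' One row per fragment: id, length, AT percent, localization, gene,
#' location to gene, distance. Distances are printed exactly in bp;
#' positions are 1-based in any coordinate column.
#'
#' @param annotations Data frame from [classify_loci()].
#' @param loci The input loci data frame (`fragment_id`, `chrom`, `start`,
#'   `end`).
#' @param fragments Optional [Biostrings::DNAStringSet] to derive length
#'   and AT percent from sequence; otherwise lengths come from the loci.
#' @param path Output path.
#' @return Invisibly, the report data frame.
#' @export
write_locus_report <- function(annotations, loci, fragments = NULL, path) {
  m <- match(annotations$fragment_id, loci$fragment_id)
  len <- loci$end[m] - loci$start[m]
  at <- rep(NA_real_, nrow(annotations))
  if (!is.null(fragments)) {
    fm <- match(annotations$fragment_id, names(fragments))
    ok <- !is.na(fm)
    len[ok] <- Biostrings::width(fragments)[fm[ok]]
    at[ok] <- round(at_content(fragments[fm[ok]]), 1)
  }
  rep_df <- data.frame(
    fragment = annotations$fragment_id,
    length_bp = len,
    at_percent = at,
    localization = ifelse(annotations$category == "unplaced",
                          "unplaced", loci$chrom[m]),
    gene = ifelse(is.na(annotations$gene_id), "-", annotations$gene_id),
    location_to_gene = ifelse(
      !is.na(annotations$feature), annotations$feature,
      ifelse(!is.na(annotations$relation), annotations$relation, "-")
    ),
    distance_bp = ifelse(is.na(annotations$distance), "-",
                         as.character(annotations$distance)),
    stringsAsFactors = FALSE
  )
  write_table(rep_df, path)
  invisible(rep_df)
}
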