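# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the code paths they are used to check.

# Naive sliding-window scan: every window compared by string equality.
naive_scan <- function(genome_chr, patterns, strands = "forward") {
  L <- unique(nchar(patterns))
  stopifnot(length(L) == 1L)
  rc <- function(x) {
    chartr("ACGT", "TGCA", vapply(
      x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""
    ))
  }
  rows <- list()
  for (id in names(genome_chr)) {
    s <- genome_chr[[id]]
    n <- nchar(s)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    win <- substring(s, starts, starts + L - 1L)
    fwd <- win %in% patterns
    if (any(fwd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = id, start = starts[fwd] - 1L, strand = "+",
        stringsAsFactors = FALSE
      )
    }
    if (strands == "both") {
      rev_hit <- unname(rc(win)) %in% patterns
      if (any(rev_hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = id, start = starts[rev_hit] - 1L, strand = "-",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seqid = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$seqid, out$start, out$strand), , drop = FALSE]
}

# Random ACGT sequence as a plain string.
random_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

rc_string <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Exhaustive best ungapped segment on the seed's diagonal containing the
# seed (brute force over all left/right boundaries).
oracle_extend <- function(query, subject, qpos0, spos0, k,
                          reward = 1, penalty = -3) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  qpos <- qpos0 + 1L
  spos <- spos0 + 1L
  max_left <- min(qpos, spos) - 1L
  max_right <- min(length(q) - (qpos + k - 1L), length(s) - (spos + k - 1L))
  best <- -Inf
  best_seg <- NULL
  for (a in 0:max_left) {
    for (b in 0:max_right) {
      qi <- (qpos - a):(qpos + k - 1L + b)
      si <- (spos - a):(spos + k - 1L + b)
      m <- sum(q[qi] == s[si])
      sc <- reward * m + penalty * (length(qi) - m)
      if (sc > best) {
        best <- sc
        best_seg <- c(qstart = qpos - a - 1L, len = length(qi))
      }
    }
  }
  list(score = best, qstart = unname(best_seg["qstart"]),
       length = unname(best_seg["len"]))
}

# Best seedable segment score per (diagonal, strand) for a fragment pair:
# segments must contain a run of >= k consecutive matches (a seed) and the
# maximum score over such segments is returned per diagonal.
oracle_pair_best <- function(q, s, k, reward = 1, penalty = -3) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  nq <- length(qc)
  ns <- length(sc)
  res <- list()
  for (d in (-(ns - 1L)):(nq - 1L)) {
    qlo <- max(1L, 1L + d)
    qhi <- min(nq, ns + d)
    if (qhi - qlo + 1L < k) next
    qi <- qlo:qhi
    si <- qi - d
    m <- qc[qi] == sc[si]
    len <- length(m)
    run <- rle(m)
    if (!any(run$values & run$lengths >= k)) next
    best <- -Inf
    for (i in seq_len(len)) {
      for (j in i:len) {
        if (j - i + 1L < k) next
        seg <- m[i:j]
        r <- rle(seg)
        if (!any(r$values & r$lengths >= k)) next
        scr <- reward * sum(seg) + penalty * sum(!seg)
        if (scr > best) best <- scr
      }
    }
    if (is.finite(best)) {
      res[[length(res) + 1L]] <- data.frame(diag = d, best = best)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(diag = integer(), best = numeric()))
  }
  do.call(rbind, res)
}

# A small deterministic three-exon plus-strand gene on chr1 for annotation
# tests: exons [100,200) [300,400) [500,650).
fixture_gene <- function(gene_id = "geneA", chrom = "chr1", strand = "+") {
  gene_model(gene_id, chrom, strand,
             exon_starts = c(100L, 300L, 500L),
             exon_ends = c(200L, 400L, 650L))
}

write_tmp_fasta <- function(named_seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(
    unlist(lapply(names(named_seqs), function(id) {
      c(paste0(">", id), named_seqs[[id]])
    })),
    path
  )
  path
}

table2_path <- function() {
  system.file("extdata", "table2_loci.tsv", package = "chipfrag")
}

table1_path <- function() {
  system.file("extdata", "table1_qpcr.tsv", package = "chipfrag")
}
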