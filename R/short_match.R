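#' Index all words (k-mers) of a fragment set
#'
#' Maps every k-mer that occurs in the fragments, skipping windows that
#' contain `N`, to its occurrences. The default word size of 7 matches the
#' seeding granularity of blastn tuned for short sequences.
#'
#' @param fragments A named [Biostrings::DNAStringSet] or named character
#'   vector.
#' @param k Word length (>= 4).
#' @return A `word_index`: named list mapping each word to a data frame of
#'   `id` (fragment id) and `pos` (0-based start); attribute `k`.
#' @export
index_words <- function(fragments, k = 7L) {
  k <- as.integer(k)
  if (k < 4L) {
    stop("word length must be at least 4")
  }
  seqs <- stats::setNames(as.character(fragments), names(fragments))
  if (length(seqs) == 0L) {
    stop("no fragments to index")
  }
  if (is.null(names(seqs))) {
    stop("fragments must be named")
  }
  if (all(nchar(seqs) < k)) {
    stop("word length exceeds every fragment length")
  }
  ids <- character(0)
  pos <- integer(0)
  words <- character(0)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    w <- substring(seqs[i], starts, starts + k - 1L)
    keep <- !grepl("N", w, fixed = TRUE)
    if (!any(keep)) next
    words <- c(words, w[keep])
    ids <- c(ids, rep(names(seqs)[i], sum(keep)))
    pos <- c(pos, starts[keep] - 1L)
  }
  occ <- data.frame(id = ids, pos = pos, stringsAsFactors = FALSE)
  idx <- split(occ, words)
  attr(idx, "k") <- k
  class(idx) <- "word_index"
  idx
}

# X-drop ungapped extension on raw byte vectors. qpos/spos are 1-based seed
# starts; returns 1-based inclusive coordinates of the maximal segment.
.extend_raw <- function(q, s, qpos, spos, k, reward, penalty, xdrop) {
  seed_score <- k * reward
  # rightwards from the seed's right edge
  score <- seed_score
  best <- score
  best_right <- 0L
  i <- 1L
  qn <- length(q)
  sn <- length(s)
  while (qpos + k - 1L + i <= qn && spos + k - 1L + i <= sn) {
    score <- score +
      if (q[qpos + k - 1L + i] == s[spos + k - 1L + i]) reward else penalty
    if (score > best) {
      best <- score
      best_right <- i
    } else if (best - score >= xdrop) {
      break
    }
    i <- i + 1L
  }
  # leftwards from the seed's left edge, starting from the trimmed best
  score <- best
  best_left <- 0L
  j <- 1L
  while (qpos - j >= 1L && spos - j >= 1L) {
    score <- score + if (q[qpos - j] == s[spos - j]) reward else penalty
    if (score > best) {
      best <- score
      best_left <- j
    } else if (best - score >= xdrop) {
      break
    }
    j <- j + 1L
  }
  qa <- qpos - best_left
  qb <- qpos + k - 1L + best_right
  identities <- sum(q[qa:qb] == s[(spos - best_left):(spos + k - 1L + best_right)])
  list(
    qstart = qa, qend = qb,
    sstart = spos - best_left, send = spos + k - 1L + best_right,
    length = qb - qa + 1L,
    identities = identities,
    score = best
  )
}

#' Extend a seed hit into a maximal ungapped alignment
#'
#' X-drop extension in both directions: each direction accumulates a
#' running score (`reward` per match, `penalty` per mismatch), stops once
#' the score falls `xdrop` below its running maximum, and trims back to the
#' maximum. The returned segment is the maximal-scoring ungapped extension
#' containing the seed. With a very large `xdrop` the result is the
#' globally maximal-scoring segment on the seed's diagonal.
#'
#' @param query,subject Character strings (or anything coercible).
#' @param qpos,spos 0-based seed starts in query and subject.
#' @param k Seed length; the query and subject words at the seed must be
#'   identical.
#' @param reward Match score (default +1).
#' @param penalty Mismatch score (default -3), as in blastn-short.
#' @param xdrop Drop-off that terminates extension (default 10).
#' @return A one-row data frame with `qstart`, `qend`, `sstart`, `send`
#'   (0-based half-open), `length`, `identities`, `score`.
#' @export
extend_hit <- function(query, subject, qpos, spos, k,
                       reward = 1, penalty = -3, xdrop = 10) {
  query <- as.character(query)
  subject <- as.character(subject)
  q <- charToRaw(query)
  s <- charToRaw(subject)
  qpos1 <- as.integer(qpos) + 1L
  spos1 <- as.integer(spos) + 1L
  if (qpos1 < 1L || spos1 < 1L ||
      qpos1 + k - 1L > length(q) || spos1 + k - 1L > length(s)) {
    stop("seed out of range")
  }
  if (!identical(q[qpos1:(qpos1 + k - 1L)], s[spos1:(spos1 + k - 1L)])) {
    stop("seed words differ between query and subject")
  }
  e <- .extend_raw(q, s, qpos1, spos1, as.integer(k), reward, penalty, xdrop)
  data.frame(
    qstart = e$qstart - 1L, qend = e$qend,
    sstart = e$sstart - 1L, send = e$send,
    length = e$length, identities = e$identities, score = e$score
  )
}

#' All-pairs conserved short segments between fragments
#'
#' Every unordered pair of distinct fragments is examined on both subject
#' strands: shared words (see [index_words()]) seed ungapped X-drop
#' extensions ([extend_hit()]). Seeds falling inside an alignment already
#' produced on the same diagonal are skipped, and alignments from distinct
#' seeds that trim to identical coordinates are merged. Reverse-strand
#' alignments report subject coordinates on the plus strand.
#'
#' @param fragments A named [Biostrings::DNAStringSet] or named character
#'   vector with at least two fragments.
#' @param k Word (seed) length, default 7.
#' @param reward,penalty,xdrop Extension scoring, see [extend_hit()].
#' @param min_length Minimum alignment length to report (default `k`).
#' @return Data frame of alignments sorted by (query_id, subject_id,
#'   qstart): `query_id`, `subject_id`, `qstart`, `qend`, `sstart`, `send`
#'   (0-based half-open, subject coordinates always plus-strand),
#'   `strand`, `length`, `identities`, `score`.
#' @export
all_pairs_matches <- function(fragments, k = 7L, reward = 1, penalty = -3,
                              xdrop = 10, min_length = k) {
  seqs <- stats::setNames(as.character(fragments), names(fragments))
  if (length(seqs) < 2L) {
    stop("need at least two fragments")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("fragments must have unique names")
  }
  k <- as.integer(k)
  ids <- names(seqs)
  raw <- lapply(seqs, charToRaw)
  raw_rc <- lapply(seqs, function(s) {
    charToRaw(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))
    ))
  })
  words <- lapply(seqs, .fragment_words, k = k)
  words_rc <- lapply(raw_rc, function(r) {
    .fragment_words(rawToChar(r), k = k)
  })

  out <- list()
  for (qi in seq_len(length(seqs) - 1L)) {
    for (si in (qi + 1L):length(seqs)) {
      for (strand in c("+", "-")) {
        sw <- if (strand == "+") words[[si]] else words_rc[[si]]
        sr <- if (strand == "+") raw[[si]] else raw_rc[[si]]
        aligns <- .pair_alignments(
          raw[[qi]], sr, words[[qi]], sw,
          k = k, reward = reward, penalty = penalty, xdrop = xdrop
        )
        if (is.null(aligns) || nrow(aligns) == 0L) next
        if (strand == "-") {
          # map subject coordinates back to the plus strand
          slen <- length(raw[[si]])
          sstart <- slen - aligns$send + 1L
          send <- slen - aligns$sstart + 1L
          aligns$sstart <- sstart
          aligns$send <- send
        }
        aligns$query_id <- ids[qi]
        aligns$subject_id <- ids[si]
        aligns$strand <- strand
        out[[length(out) + 1L]] <- aligns
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      query_id = character(), subject_id = character(),
      qstart = integer(), qend = integer(),
      sstart = integer(), send = integer(), strand = character(),
      length = integer(), identities = integer(), score = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  # 1-based inclusive -> 0-based half-open
  res$qstart <- res$qstart - 1L
  res$sstart <- res$sstart - 1L
  res <- res[res$length >= min_length, , drop = FALSE]
  res <- res[, c("query_id", "subject_id", "qstart", "qend", "sstart",
                 "send", "strand", "length", "identities", "score")]
  res <- unique(res)
  res <- res[order(res$query_id, res$subject_id, res$qstart, res$strand,
                   res$sstart), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# words of one sequence: data.frame(word, pos 1-based), N windows skipped
.fragment_words <- function(s, k) {
  n <- nchar(s)
  if (n < k) {
    return(data.frame(word = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- seq_len(n - k + 1L)
  w <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", w, fixed = TRUE)
  data.frame(word = w[keep], pos = starts[keep], stringsAsFactors = FALSE)
}

# all alignments for one (query, oriented subject) pair
.pair_alignments <- function(q, s, qw, sw, k, reward, penalty, xdrop) {
  shared <- intersect(unique(qw$word), unique(sw$word))
  if (length(shared) == 0L) {
    return(NULL)
  }
  qocc <- split(qw$pos, qw$word)
  socc <- split(sw$pos, sw$word)
  seeds_q <- integer(0)
  seeds_s <- integer(0)
  for (w in shared) {
    grid <- expand.grid(qp = qocc[[w]], sp = socc[[w]])
    seeds_q <- c(seeds_q, grid$qp)
    seeds_s <- c(seeds_s, grid$sp)
  }
  diag_id <- seeds_q - seeds_s
  o <- order(diag_id, seeds_q)
  seeds_q <- seeds_q[o]
  seeds_s <- seeds_s[o]
  diag_id <- diag_id[o]
  rows <- list()
  last_diag <- NA_integer_
  covered_to <- -1L
  for (t in seq_along(seeds_q)) {
    if (!identical(diag_id[t], last_diag)) {
      last_diag <- diag_id[t]
      covered_to <- -1L
    } else if (seeds_q[t] + k - 1L <= covered_to) {
      next  # seed lies inside the previous alignment on this diagonal
    }
    e <- .extend_raw(q, s, seeds_q[t], seeds_s[t], k, reward, penalty, xdrop)
    covered_to <- e$qend
    rows[[length(rows) + 1L]] <- e
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Collect deduplicated fixed-length aligned segments
#'
#' Keeps alignments whose length equals `segment_length` exactly, extracts
#' the query-side sequence (queries are always in plus orientation, so
#' reverse-strand matches contribute their plus-oriented query segment),
#' removes duplicate strings and sorts lexicographically. This is the
#' programmatic counterpart of collecting the 11- and 12-bp cross-fragment
#' matches and adjusting them for redundancy before logo construction.
#'
#' @param alignments Data frame from [all_pairs_matches()].
#' @param segment_length Target length, conventionally 11 or 12.
#' @param fragments The fragment set the alignments refer to.
#' @return A `segment_set`: list with `segment_length`, `segments`
#'   (character vector, deduplicated and sorted) and `n`.
#' @export
collect_segments <- function(alignments, segment_length, fragments) {
  seqs <- stats::setNames(as.character(fragments), names(fragments))
  keep <- alignments$length == segment_length
  segs <- character(0)
  if (any(keep)) {
    al <- alignments[keep, , drop = FALSE]
    segs <- substring(
      seqs[al$query_id], al$qstart + 1L, al$qend
    )
    segs <- sort(unique(segs))
  }
  structure(
    list(segment_length = as.integer(segment_length), segments = segs,
         n = length(segs)),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d distinct %d-bp segment(s)\n",
              x$n, x$segment_length))
  invisible(x)
}

#' Write alignments as a pairwise TSV report
#'
#' Coordinates are printed 1-based inclusive.
#'
#' @param alignments Data frame from [all_pairs_matches()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(alignments, path) {
  out <- alignments
  out$qstart <- out$qstart + 1L
  out$sstart <- out$sstart + 1L
  write_table(out, path)
  invisible(path)
}

#' Write a segment set as FASTA
#'
#' @param segset A `segment_set` from [collect_segments()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segments_fasta <- function(segset, path) {
  if (segset$n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  segs <- segset$segments
  names(segs) <- sprintf("segment_%0*d", nchar(length(segs)),
                         seq_along(segs))
  write_fasta(segs, path)
}
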