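test_that("index_words maps k-mers to occurrences and skips N windows", {
  idx <- index_words(c(f = "ACGTACG"), k = 7L)
  expect_length(idx, 1L)
  expect_equal(idx[["ACGTACG"]]$pos, 0L)

  idx2 <- index_words(c(f = "AAAA"), k = 4L)
  expect_equal(idx2[["AAAA"]]$pos, 0L)
  idx3 <- index_words(c(f = "AAAAA"), k = 4L)
  expect_equal(idx3[["AAAA"]]$pos, c(0L, 1L))

  idx4 <- index_words(c(f = "ACNGT", g = "ACGTT"), k = 4L)
  expect_false(any(grepl("N", names(idx4))))
  expect_true(all(vapply(idx4[["ACGT"]]$id, identical, TRUE, "g")))
  expect_error(index_words(c(f = "ACG"), k = 4L), "exceeds")
})

test_that("extension stops immediately when flanks mismatch", {
  # seed flanked by immediate mismatches on both sides
  q <- "GGGGACGTACGTGGGG"
  s <- "CCCCACGTACGTCCCC"
  hit <- extend_hit(q, s, 4, 4, 8)
  expect_equal(hit$length, 8L)
  expect_equal(hit$identities, 8L)
  expect_equal(hit$score, 8)
})

test_that("identical embedded 20-mers extend to exactly their length", {
  set.seed(5)
  core <- random_seq(20)
  repeat {
    left_q <- random_seq(15); right_q <- random_seq(15)
    left_s <- random_seq(10); right_s <- random_seq(25)
    # ensure flanks mismatch right at the junction so extension stops
    if (substring(left_q, 15, 15) != substring(left_s, 10, 10) &&
        substring(right_q, 1, 1) != substring(right_s, 1, 1)) break
  }
  q <- paste0(left_q, core, right_q)
  s <- paste0(left_s, core, right_s)
  hit <- extend_hit(q, s, 15 + 5, 10 + 5, 7)
  expect_equal(hit$length, 20L)
  expect_equal(hit$identities, 20L)
  expect_equal(hit$qstart, 15L)
  expect_equal(hit$sstart, 10L)
})

test_that("unbounded-xdrop extension equals the exhaustive segment oracle", {
  set.seed(21)
  for (i in 1:40) {
    q <- random_seq(sample(20:60, 1))
    s <- random_seq(sample(20:60, 1))
    k <- 5L
    # find a shared word to seed from; construct one if absent
    idx <- suppressWarnings(tryCatch(index_words(c(a = q, b = s), k = k),
                                     error = function(e) NULL))
    seed_found <- FALSE
    if (!is.null(idx)) {
      for (w in names(idx)) {
        occ <- idx[[w]]
        if (all(c("a", "b") %in% occ$id)) {
          qpos <- occ$pos[occ$id == "a"][1]
          spos <- occ$pos[occ$id == "b"][1]
          seed_found <- TRUE
          break
        }
      }
    }
    if (!seed_found) {
      word <- random_seq(k)
      qat <- sample(nchar(q) - k + 1, 1)
      sat <- sample(nchar(s) - k + 1, 1)
      substring(q, qat, qat + k - 1) <- word
      substring(s, sat, sat + k - 1) <- word
      qpos <- qat - 1L
      spos <- sat - 1L
    }
    got <- extend_hit(q, s, qpos, spos, k, xdrop = 1e9)
    want <- oracle_extend(q, s, qpos, spos, k)
    expect_equal(got$score, want$score)
    expect_equal(got$length, want$length)
  }
})

test_that("all-pairs matching finds planted shared 15-mers in all pairs", {
  set.seed(8)
  core <- random_seq(15)
  frags <- vapply(1:3, function(i) {
    pre <- random_seq(40)
    post <- random_seq(40)
    paste0(pre, core, post)
  }, "")
  names(frags) <- paste0("f", 1:3)
  al <- all_pairs_matches(frags, k = 7)
  plus <- al[al$strand == "+", ]
  pairs <- unique(plus[, c("query_id", "subject_id")])
  expect_equal(nrow(pairs), 3L)  # all three unordered pairs
  expect_true(all(vapply(seq_len(nrow(pairs)), function(i) {
    sub <- plus[plus$query_id == pairs$query_id[i] &
                  plus$subject_id == pairs$subject_id[i], ]
    any(sub$length >= 15)
  }, TRUE)))
})

test_that("fragments with no shared 7-mer produce no alignments", {
  set.seed(13)
  repeat {
    a <- random_seq(100)
    b <- random_seq(100)
    shared <- intersect(names(index_words(c(x = a), 7)),
                        c(names(index_words(c(y = b), 7)),
                          names(index_words(
                            c(y = rc_string(b)), 7
                          ))))
    if (length(shared) == 0L) break
  }
  al <- all_pairs_matches(c(x = a, y = b), k = 7)
  expect_equal(nrow(al), 0L)
})

test_that("a fragment and its reverse complement align full-length on '-'", {
  set.seed(19)
  a <- random_seq(80)
  al <- all_pairs_matches(c(p = a, q = rc_string(a)), k = 7)
  full <- al[al$length == 80, ]
  expect_gte(nrow(full), 1L)
  expect_true(all(full$strand == "-"))
  expect_equal(full$identities[1], 80L)
  expect_equal(full$qstart[1], 0L)
  expect_equal(full$send[1], 80L)
})

test_that("reported identities recompute from the sequences", {
  set.seed(3)
  frags <- setNames(
    vapply(1:6, function(i) random_seq(sample(60:150, 1), at = 0.65), ""),
    paste0("f", 1:6)
  )
  al <- all_pairs_matches(frags, k = 5)
  skip_if(nrow(al) == 0L)
  for (i in seq_len(nrow(al))) {
    qseg <- substring(frags[al$query_id[i]], al$qstart[i] + 1, al$qend[i])
    sseg <- substring(frags[al$subject_id[i]], al$sstart[i] + 1, al$send[i])
    if (al$strand[i] == "-") sseg <- rc_string(sseg)
    m <- sum(strsplit(qseg, "")[[1]] == strsplit(sseg, "")[[1]])
    expect_equal(al$identities[i], m)
    expect_equal(al$score[i], m - 3 * (al$length[i] - m))
  }
})

test_that("all-pairs results match the exhaustive seedable-segment oracle", {
  set.seed(77)
  for (rep in 1:8) {
    n_frag <- 3L
    frags <- vapply(seq_len(n_frag), function(i) random_seq(60), "")
    if (rep %% 2 == 0) {
      # plant a shared word so matches exist
      w <- random_seq(9)
      for (i in seq_len(n_frag)) {
        at <- sample(60 - 9 + 1, 1)
        substring(frags[i], at, at + 8) <- w
      }
    }
    names(frags) <- paste0("f", seq_len(n_frag))
    al <- all_pairs_matches(frags, k = 7, xdrop = 1e9)
    for (qi in 1:(n_frag - 1)) {
      for (si in (qi + 1):n_frag) {
        for (strand in c("+", "-")) {
          s_seq <- if (strand == "+") frags[si] else rc_string(frags[si])
          want <- oracle_pair_best(frags[qi], s_seq, k = 7)
          sub <- al[al$query_id == names(frags)[qi] &
                      al$subject_id == names(frags)[si] &
                      al$strand == strand, ]
          # every oracle diagonal's best seedable score must be attained
          for (r in seq_len(nrow(want))) {
            expect_true(any(sub$score >= want$best[r]))
          }
          if (nrow(want) == 0L) expect_equal(nrow(sub), 0L)
        }
      }
    }
  }
})

test_that("swapping query and subject yields the same segment pairs", {
  set.seed(31)
  core <- random_seq(18)
  a <- paste0(random_seq(30), core, random_seq(30))
  b <- paste0(random_seq(50), core, random_seq(10))
  al_ab <- all_pairs_matches(c(u = a, v = b), k = 7, xdrop = 1e9)
  al_ba <- all_pairs_matches(c(v = b, u = a), k = 7, xdrop = 1e9)
  key_ab <- sort(paste(al_ab$length, al_ab$identities, al_ab$score,
                       al_ab$strand))
  key_ba <- sort(paste(al_ba$length, al_ba$identities, al_ba$score,
                       al_ba$strand))
  expect_equal(key_ab, key_ba)
})

test_that("segment collection filters by exact length and deduplicates", {
  frags <- c(
    f1 = "GGATCGATCGATTGGCC",
    f2 = "TTATCGATCGATTCCAA"
  )
  al <- all_pairs_matches(frags, k = 7)
  segs11 <- collect_segments(al[al$length == 11, , drop = FALSE], 11, frags)
  expect_true(all(nchar(segs11$segments) == 11))
  expect_equal(segs11$n, length(unique(segs11$segments)))

  # duplicate-producing alignments collapse to one segment
  al_dup <- data.frame(
    query_id = c("f1", "f1"), subject_id = c("f2", "f2"),
    qstart = c(2L, 2L), qend = c(14L, 14L),
    sstart = c(2L, 3L), send = c(14L, 15L),
    strand = "+", length = 12L, identities = 12L, score = 12
  )
  segs <- collect_segments(al_dup, 12, frags)
  expect_equal(segs$n, 1L)

  empty <- collect_segments(al[0, ], 11, frags)
  expect_equal(empty$n, 0L)
  expect_length(empty$segments, 0L)
})
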