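#' AT-content of DNA sequences, in percent
#'
#' `N` bases are excluded from both numerator and denominator, so the value
#' is the AT fraction of the unambiguous part of the sequence. The result
#' is invariant under reversal and under complementation.
#'
#' @param x A character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Numeric vector: `100 * (A + T) / (A + C + G + T)` per sequence.
#' @examples
#' at_content(c("ATAT", "ACGT", "ACGN"))  # 100, 50, 33.33
#' @export
at_content <- function(x) {
  if (is(x, "DNAString")) {
    x <- Biostrings::DNAStringSet(list(x))
  } else if (!is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  }
  if (any(Biostrings::width(x) == 0L)) {
    stop("empty sequence")
  }
  lf <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  unamb <- rowSums(lf)
  if (any(unamb == 0L)) {
    stop("sequence with no unambiguous base: AT-content undefined")
  }
  unname(100 * (lf[, "A"] + lf[, "T"]) / unamb)
}

#' AT-content profile of a genome in fixed non-overlapping windows
#'
#' Each record is tiled left-to-right into non-overlapping windows of
#' `window_size` bp; a trailing remainder shorter than the window is
#' discarded so that all windows are identically sized. Windows whose
#' fraction of unambiguous (non-`N`) bases falls below
#' `min_unambiguous_frac` are excluded and counted in `n_excluded`; for the
#' remaining windows the AT fraction is computed over unambiguous bases
#' only.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param window_size Window size in bp (default 500, the granularity used
#'   for genome-background AT histograms).
#' @param min_unambiguous_frac Minimum fraction of A/C/G/T bases a window
#'   needs to be kept (default 0.5).
#' @return An `at_profile` object: list with `window_size`, `values`
#'   (per-window AT fractions in `[0, 1]`), `n_windows`, `n_excluded`, and
#'   `windows` (data frame of `seqid` and 0-based `start` per kept window).
#' @export
window_profile <- function(genome, window_size = 500L,
                           min_unambiguous_frac = 0.5) {
  window_size <- as.integer(window_size)
  if (window_size < 1L) {
    stop("window_size must be at least 1")
  }
  vals <- numeric(0)
  seqids <- character(0)
  starts <- integer(0)
  n_excluded <- 0L
  for (i in seq_along(genome)) {
    len <- Biostrings::width(genome)[i]
    nw <- len %/% window_size
    if (nw == 0L) next
    w_starts <- seq.int(1L, by = window_size, length.out = nw)
    v <- Biostrings::Views(genome[[i]], start = w_starts,
                           width = window_size)
    lf <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    unamb <- rowSums(lf)
    keep <- unamb / window_size >= min_unambiguous_frac & unamb > 0L
    n_excluded <- n_excluded + sum(!keep)
    if (any(keep)) {
      vals <- c(vals, (lf[keep, "A"] + lf[keep, "T"]) / unamb[keep])
      seqids <- c(seqids, rep(names(genome)[i], sum(keep)))
      starts <- c(starts, w_starts[keep] - 1L)
    }
  }
  structure(
    list(
      window_size = window_size,
      values = unname(vals),
      n_windows = length(vals),
      n_excluded = n_excluded,
      windows = data.frame(seqid = seqids, start = starts,
                           stringsAsFactors = FALSE)
    ),
    class = "at_profile"
  )
}

#' @export
print.at_profile <- function(x, ...) {
  cat(sprintf(
    "<at_profile> %d window(s) of %d bp (%d excluded); mean AT %.3f\n",
    x$n_windows, x$window_size, x$n_excluded,
    if (x$n_windows) mean(x$values) else NA_real_
  ))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic `W` is reported in the Mann-Whitney convention for sample
#' `a`: the number of pairs `(x, y)` with `x > y`, ties counting one half
#' (the convention R's own `wilcox.test` prints). `rank_sum`, the classical
#' Wilcoxon sum of the ranks of sample `a`, equals
#' `W + n1 (n1 + 1) / 2` and is reported alongside.
#'
#' The exact null distribution is used when `max(n1, n2) <= 25` and the
#' pooled data are tie-free; otherwise a normal approximation with midrank
#' tie correction and a 0.5 continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return A `rank_sum_result` object: list with `W`, `rank_sum`, `p`,
#'   `method` (`"exact"` or `"normal"`), `n1`, `n2`, `alternative`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # W = 0, exact p = 0.1
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty")
  }
  if (anyNA(a) || anyNA(b)) {
    stop("samples must not contain NA")
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  rank_sum <- sum(r[seq_len(n1)])
  W <- rank_sum - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)

  if (!has_ties && max(n1, n2) <= 25L) {
    method <- "exact"
    p <- switch(alternative,
      greater = stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(W, n1, n2),
      two.sided = {
        if (W > n1 * n2 / 2) {
          min(1, 2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(W, n1, n2))
        }
      }
    )
  } else {
    method <- "normal"
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      cc <- 0.5
      p <- switch(alternative,
        greater = stats::pnorm((W - mu - cc) / sigma, lower.tail = FALSE),
        less = stats::pnorm((W - mu + cc) / sigma),
        two.sided = min(1, 2 * stats::pnorm(
          (abs(W - mu) - cc) / sigma, lower.tail = FALSE
        ))
      )
    }
    p <- max(p, .Machine$double.xmin)  # a p-value of exactly 0 is never reported
  }
  structure(
    list(
      W = W, rank_sum = rank_sum, p = p, method = method,
      n1 = n1, n2 = n2, alternative = alternative
    ),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf(
    "<rank_sum_result> W = %s (rank sum %s), n1 = %d, n2 = %d\n  %s %s p = %.4g\n",
    format(x$W, big.mark = ","), format(x$rank_sum, big.mark = ","),
    x$n1, x$n2, x$method, x$alternative, x$p
  ))
  invisible(x)
}

#' Compare ChIP-fragment AT-content against a windowed genome background
#'
#' The headline comparison behind the genome AT histogram: fragments are
#' sample `a`, the 500-bp genome windows sample `b`. Because the working
#' hypothesis is AT enrichment of the immunoprecipitated fragments, the
#' one-sided "greater" test is the primary result; the two-sided p-value is
#' emitted alongside. A shared-bin histogram (2 percentage-point bins by
#' default) is returned for plotting parity between the two distributions.
#'
#' @param fragments A [Biostrings::DNAStringSet] of fragment sequences.
#' @param genome A [Biostrings::DNAStringSet] background genome.
#' @param window_size Background window size in bp (default 500).
#' @param bin_width Histogram bin width in percentage points (default 2).
#' @return A list with `fragment_at` (percent per fragment), `profile`
#'   (the genome [window_profile()]), `test` (one-sided "greater"
#'   [rank_sum_test()]), `test_two_sided`, and `histogram` (data frame of
#'   `bin_low`, `bin_high`, `genome_count`, `fragment_count`).
#' @export
compare_fragments_to_genome <- function(fragments, genome,
                                        window_size = 500L, bin_width = 2) {
  if (length(fragments) < 1L) {
    stop("need at least one fragment")
  }
  frag_at <- at_content(fragments)
  prof <- window_profile(genome, window_size = window_size)
  if (prof$n_windows < 1L) {
    stop("genome yielded no usable windows at this window size")
  }
  win_at <- 100 * prof$values
  test <- rank_sum_test(frag_at, win_at, alternative = "greater")
  test2 <- rank_sum_test(frag_at, win_at, alternative = "two.sided")
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  g_cut <- cut(win_at, breaks = breaks, include.lowest = TRUE, right = FALSE)
  f_cut <- cut(frag_at, breaks = breaks, include.lowest = TRUE, right = FALSE)
  hist <- data.frame(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    genome_count = as.integer(table(g_cut)),
    fragment_count = as.integer(table(f_cut))
  )
  list(
    fragment_at = frag_at,
    profile = prof,
    test = test,
    test_two_sided = test2,
    histogram = hist
  )
}

#' Write an AT-content comparison to disk
#'
#' Histogram as TSV, test results as JSON.
#'
#' @param cmp Result of [compare_fragments_to_genome()].
#' @param hist_path,json_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_at_comparison <- function(cmp, hist_path, json_path) {
  write_table(cmp$histogram, hist_path)
  jsonlite::write_json(
    list(
      n_fragments = cmp$test$n1,
      n_windows = cmp$test$n2,
      mean_fragment_at = mean(cmp$fragment_at),
      mean_window_at = 100 * mean(cmp$profile$values),
      W = cmp$test$W,
      rank_sum = cmp$test$rank_sum,
      p_greater = cmp$test$p,
      p_two_sided = cmp$test_two_sided$p,
      method = cmp$test$method
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(NULL)
}
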