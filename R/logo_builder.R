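utils::globalVariables(c("position", "height", "letter"))

#' Build a position frequency matrix from equal-length segments
#'
#' Exact per-column letter counts, no pseudocounts.
#'
#' @param segments A `segment_set` from [collect_segments()], or a
#'   character vector of equal-length ACGT strings.
#' @return A `pfm` object: list with `length`, `counts` (4 x L matrix,
#'   rows A/C/G/T), `frequencies` (columns sum to 1) and `n`.
#' @export
build_pfm <- function(segments) {
  if (inherits(segments, "segment_set")) {
    segments <- segments$segments
  }
  segments <- toupper(as.character(segments))
  if (length(segments) < 1L) {
    stop("empty segment set")
  }
  L <- unique(nchar(segments))
  if (length(L) != 1L) {
    stop("segments must all have the same length")
  }
  if (any(!grepl("^[ACGT]+$", segments))) {
    stop("segments must be plain ACGT")
  }
  counts <- Biostrings::consensusMatrix(
    Biostrings::DNAStringSet(segments)
  )[c("A", "C", "G", "T"), , drop = FALSE]
  n <- length(segments)
  structure(
    list(
      length = L,
      counts = counts,
      frequencies = counts / n,
      n = n
    ),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d position(s) from %d segment(s)\n", x$length, x$n))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Information-content logo matrix from a position frequency matrix
#'
#' Per position `i`, the information content against a uniform background
#' is `ic_i = 2 + sum_b f_ib log2 f_ib` bits (with `0 log 0 = 0`), so a
#' fully conserved column carries 2 bits and a uniform column 0. Letter
#' heights are `f_ib * ic_i`, the standard sequence-logo stacking. The
#' optional small-sample correction subtracts `3 / (2 ln(2) n)` from each
#' column (floored at 0); it is off by default so the matrix is an exact
#' function of the frequencies.
#'
#' @param pfm A `pfm` from [build_pfm()].
#' @param small_sample_correction Apply the correction term? Default
#'   `FALSE`.
#' @return A `logo_matrix` object: list with `ic` (per-position bits) and
#'   `heights` (4 x L matrix of per-letter bit heights), plus `n` and
#'   `small_sample_correction`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  f <- pfm$frequencies
  plogp <- f * log2(f)
  plogp[f == 0] <- 0
  ic <- 2 + colSums(plogp)
  if (small_sample_correction) {
    e_n <- 3 / (2 * log(2) * pfm$n)
    ic <- pmax(ic - e_n, 0)
  }
  heights <- sweep(f, 2, ic, `*`)
  structure(
    list(
      ic = unname(ic),
      heights = heights,
      n = pfm$n,
      small_sample_correction = small_sample_correction
    ),
    class = "logo_matrix"
  )
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf(
    "<logo_matrix> %d position(s); total information %.2f bits%s\n",
    length(x$ic), sum(x$ic),
    if (x$small_sample_correction) " (small-sample corrected)" else ""
  ))
  invisible(x)
}

#' Write a logo matrix as TSV
#'
#' Columns: position (1-based), ic, height_A, height_C, height_G,
#' height_T.
#'
#' @param logo A `logo_matrix` from [information_content()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(
    position = seq_along(logo$ic),
    ic = logo$ic,
    height_A = logo$heights["A", ],
    height_C = logo$heights["C", ],
    height_G = logo$heights["G", ],
    height_T = logo$heights["T", ]
  )
  write_table(df, path)
  invisible(path)
}

#' Plot a sequence logo as stacked information bars
#'
#' A simple ggplot2 rendering: per position, letters stack in increasing
#' height order and the stack totals the position's information content in
#' bits. Requires ggplot2.
#'
#' @param logo A `logo_matrix` from [information_content()].
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_logo requires the ggplot2 package")
  }
  h <- logo$heights
  df <- data.frame(
    position = rep(seq_len(ncol(h)), each = 4L),
    letter = rep(rownames(h), times = ncol(h)),
    height = as.vector(h)
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = position, y = height, fill = letter)
  ) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(
      values = c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
    ) +
    ggplot2::labs(x = "Position", y = "Information (bits)", fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
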