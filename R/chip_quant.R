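#' ChIP-qPCR fold enrichment from threshold-cycle pairs
#'
#' Enrichment of the immunoprecipitated (IP) sample over the no-antibody
#' (NoAb) background control: `delta_ct = ct_noab - ct_ip` and
#' `fold = 2^delta_ct`, the x-fold higher amount of starting template in
#' the IP reaction. A fold of 1 means no enrichment; each additional cycle
#' of separation doubles the fold.
#'
#' @param samples A data frame with columns `id` (or `sample`), `ct_ip`
#'   and `ct_noab`.
#' @return A data frame with `id`, `ct_ip`, `ct_noab`, `delta_ct`, `fold`.
#' @examples
#' fold_enrichment(data.frame(id = "36", ct_ip = 29.49, ct_noab = 36.46))
#' @export
fold_enrichment <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!"id" %in% names(samples) && "sample" %in% names(samples)) {
    samples$id <- samples$sample
  }
  req <- c("id", "ct_ip", "ct_noab")
  if (!all(req %in% names(samples))) {
    stop("samples need columns: ", paste(req, collapse = ", "))
  }
  ct_ip <- as.numeric(samples$ct_ip)
  ct_noab <- as.numeric(samples$ct_noab)
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_noab)) ||
      any(ct_ip <= 0) || any(ct_noab <= 0)) {
    stop("all Ct values must be positive and finite")
  }
  delta <- ct_noab - ct_ip
  data.frame(
    id = as.character(samples$id),
    ct_ip = ct_ip,
    ct_noab = ct_noab,
    delta_ct = delta,
    fold = 2^delta,
    stringsAsFactors = FALSE
  )
}

#' Mean fold enrichment over samples
#'
#' The arithmetic mean is taken over the fold values themselves, not over
#' the Ct differences, so one strongly enriched sample raises the average
#' the way the underlying template amounts do.
#'
#' @param samples A data frame of Ct pairs (see [fold_enrichment()]) or an
#'   already-computed enrichment data frame with a `fold` column.
#' @return Mean fold enrichment (scalar).
#' @export
mean_enrichment <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) < 1L) {
    stop("no samples")
  }
  if (!"fold" %in% names(samples)) {
    samples <- fold_enrichment(samples)
  }
  mean(samples$fold)
}

#' Read a qPCR Ct table
#'
#' TSV with a header; requires columns `ct_ip` and `ct_noab` plus an `id`
#' or `sample` column. Additional columns are preserved.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) {
    stop("qPCR table not found: ", path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab) && "sample" %in% names(tab)) {
    tab$id <- as.character(tab$sample)
  }
  req <- c("id", "ct_ip", "ct_noab")
  if (!all(req %in% names(tab))) {
    stop("qPCR table needs columns: ", paste(req, collapse = ", "))
  }
  tab
}

#' Write an enrichment report
#'
#' Mirrors the conventional ChIP-qPCR table layout: per sample the average
#' Ct of IP and NoAb, their difference, and the x-fold enrichment (two
#' decimals).
#'
#' @param enrichment Data frame from [fold_enrichment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_table <- function(enrichment, path) {
  out <- data.frame(
    sample = enrichment$id,
    ct_ip = enrichment$ct_ip,
    ct_noab = enrichment$ct_noab,
    delta_ct = round(enrichment$delta_ct, 2),
    fold_enrichment = round(enrichment$fold, 2)
  )
  write_table(out, path)
  invisible(path)
}
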