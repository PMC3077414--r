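#' Configuration for the synthetic ChIP-fragment study
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' a genome background whose 500-bp windows average about 59% AT with a
#' right-shifted, skewed distribution (a two-component mixture, since the
#' genome-wide AT distribution is distinctly non-normal), and ~50 cloned
#' fragments of 105-1848 bp whose AT-content is shifted above that
#' background.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param chrom_lengths Named or unnamed integer vector of chromosome
#'   lengths in bp.
#' @param at_mixture Data frame with columns `weight`, `mean`, `sd`: the
#'   per-window AT-fraction mixture. Weights must sum to 1.
#' @param n_fragments Number of ChIP-like fragments to draw.
#' @param fragment_length_range Length range (min, max) in bp, uniform.
#' @param fragment_at_shift Additive AT-fraction bias of fragments over the
#'   genome background (0 = unbiased sampling).
#' @param motif_density Expected planted motif instances per Mbp.
#' @param n_genes Number of gene models to place.
#' @param exon_count_range Range of exons per gene (uniform integer).
#' @param qpcr_n,qpcr_delta_mean,qpcr_delta_sd qPCR table shape: number of
#'   samples and the Normal distribution of `ct_noab - ct_ip` in cycles.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 600000L, chr2 = 400000L),
                       at_mixture = data.frame(
                         weight = c(0.7, 0.3),
                         mean = c(0.56, 0.64),
                         sd = c(0.05, 0.07)
                       ),
                       n_fragments = 49L,
                       fragment_length_range = c(105L, 1848L),
                       fragment_at_shift = 0.06,
                       motif_density = 20,
                       n_genes = 20L,
                       exon_count_range = c(2L, 8L),
                       qpcr_n = 5L,
                       qpcr_delta_mean = 7.64,
                       qpcr_delta_sd = 1.1) {
  stopifnot(
    all(at_mixture$weight > 0),
    abs(sum(at_mixture$weight) - 1) < 1e-8,
    all(at_mixture$sd >= 0),
    all(chrom_lengths > 0),
    n_fragments >= 1L,
    fragment_length_range[1] >= 1L,
    fragment_length_range[2] >= fragment_length_range[1],
    qpcr_delta_sd >= 0
  )
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(
    list(
      seed = as.integer(seed),
      chrom_lengths = chrom_lengths,
      at_mixture = at_mixture,
      n_fragments = as.integer(n_fragments),
      fragment_length_range = as.integer(fragment_length_range),
      fragment_at_shift = fragment_at_shift,
      motif_density = motif_density,
      n_genes = as.integer(n_genes),
      exon_count_range = as.integer(exon_count_range),
      qpcr_n = as.integer(qpcr_n),
      qpcr_delta_mean = qpcr_delta_mean,
      qpcr_delta_sd = qpcr_delta_sd
    ),
    class = "sim_config"
  )
}

# run fn with a deterministic RNG stream derived from (seed, offset),
# restoring the caller's RNG state afterwards
.with_stream <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  fn()
}

#' Simulate a genome with controlled AT composition
#'
#' Per 500-bp block an AT fraction is drawn from the configured mixture
#' (clamped to `[0.05, 0.95]`) and bases are emitted i.i.d. at that
#' composition, A/T and C/G each split evenly. Bit-reproducible under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mix <- config$at_mixture
  block <- 500L
  .with_stream(config$seed, 101L, function() {
    seqs <- vapply(seq_along(config$chrom_lengths), function(ci) {
      len <- config$chrom_lengths[ci]
      nb <- ceiling(len / block)
      comp <- sample.int(nrow(mix), nb, replace = TRUE, prob = mix$weight)
      at <- stats::rnorm(nb, mix$mean[comp], mix$sd[comp])
      at <- pmin(pmax(at, 0.05), 0.95)
      p_at <- rep(at, each = block)[seq_len(len)]
      u1 <- stats::runif(len) < p_at       # AT vs GC
      u2 <- stats::runif(len) < 0.5        # which base of the pair
      base <- ifelse(u1, ifelse(u2, "A", "T"), ifelse(u2, "C", "G"))
      paste(base, collapse = "")
    }, character(1))
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- names(config$chrom_lengths)
    g
  })
}

#' Plant motif instances into a genome
#'
#' Draws `Poisson(density x Mbp)` plant positions uniformly without
#' overlap, overwrites each with a uniformly chosen variant from the
#' pattern set, and returns the ground truth.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param patterns Plain ACGT pattern set (see [expand_iupac()]).
#' @param density Expected plants per Mbp.
#' @param seed Integer seed.
#' @param max_tries Bounded retries per plant before giving up.
#' @return A list with `genome` (modified) and `plants` (data frame of
#'   `seqid`, `start` (0-based), `variant`).
#' @export
plant_motifs <- function(genome, patterns, density, seed,
                         max_tries = 1000L) {
  patterns <- as.character(patterns)
  L <- unique(nchar(patterns))
  stopifnot(length(L) == 1L)
  widths <- Biostrings::width(genome)
  if (any(widths <= L)) {
    stop("pattern length must be smaller than every chromosome")
  }
  G <- genome_length(genome)
  .with_stream(seed, 211L, function() {
    n_plants <- stats::rpois(1L, density * G / 1e6)
    plants <- data.frame(
      seqid = character(), start = integer(), variant = character(),
      stringsAsFactors = FALSE
    )
    if (n_plants == 0L) {
      return(list(genome = genome, plants = plants))
    }
    seqs <- as.character(genome)
    taken <- lapply(seqs, function(x) integer(0))  # occupied starts per chrom
    for (p in seq_len(n_plants)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(length(seqs), 1L, prob = widths)
        pos <- sample.int(widths[ci] - L + 1L, 1L)  # 1-based
        clash <- any(abs(taken[[ci]] - pos) < L)
        if (!clash) {
          variant <- patterns[sample.int(length(patterns), 1L)]
          substr(seqs[ci], pos, pos + L - 1L) <- variant
          taken[[ci]] <- c(taken[[ci]], pos)
          plants[nrow(plants) + 1L, ] <-
            list(names(genome)[ci], pos - 1L, variant)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("motif density too high: could not place plant without overlap")
      }
    }
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- names(genome)
    plants <- plants[order(plants$seqid, plants$start), , drop = FALSE]
    rownames(plants) <- NULL
    list(genome = g, plants = plants)
  })
}

#' Simulate ChIP-like fragments with an AT-content bias
#'
#' Fragment lengths are uniform over the configured range. When
#' `fragment_at_shift > 0`, candidate start positions are weighted by a
#' logistic function of the candidate interval's own AT fraction,
#' `plogis(steepness * (at - c))`, with the center `c` calibrated per
#' fragment so the expected sampled AT equals the candidate mean plus the
#' shift; with shift 0 the start is uniform. Loci are recorded for
#' downstream annotation tests.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param config A [sim_config()].
#' @param n_candidates Candidate starts evaluated per fragment when
#'   tilting (a Monte-Carlo subsample of all starts).
#' @param steepness Logistic steepness on the AT-fraction scale.
#' @return A list with `fragments` (named [Biostrings::DNAStringSet]) and
#'   `loci` (data frame of `fragment_id`, `chrom`, `start`, `end`,
#'   0-based half-open).
#' @export
simulate_fragments <- function(genome, config, n_candidates = 4000L,
                               steepness = 50) {
  stopifnot(inherits(config, "sim_config"))
  widths <- Biostrings::width(genome)
  lo <- config$fragment_length_range[1]
  hi <- config$fragment_length_range[2]
  if (hi > max(widths)) {
    stop("fragment length range exceeds every chromosome")
  }
  seqs <- as.character(genome)
  is_at <- lapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    cumsum(ch == "A" | ch == "T")
  })
  shift <- config$fragment_at_shift
  .with_stream(config$seed, 307L, function() {
    n <- config$n_fragments
    ids <- sprintf("frag%02d", seq_len(n))
    chroms <- character(n)
    starts <- integer(n)
    lens <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        len <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        ok <- widths >= len
        if (any(ok)) break
      }
      ci <- sample.int(length(seqs), 1L, prob = widths * ok)
      npos <- widths[ci] - len + 1L
      if (shift <= 0) {
        pos <- sample.int(npos, 1L)
      } else {
        cand <- if (npos <= n_candidates) {
          seq_len(npos)
        } else {
          sample.int(npos, n_candidates)
        }
        cs <- is_at[[ci]]
        at_cand <- (cs[cand + len - 1L] -
                      ifelse(cand > 1L, cs[cand - 1L], 0L)) / len
        target <- min(mean(at_cand) + shift, max(at_cand))
        w_mean <- function(ctr) {
          w <- stats::plogis(steepness * (at_cand - ctr))
          sum(w * at_cand) / sum(w)
        }
        if (w_mean(max(at_cand) + 1) <= target) {
          ctr <- max(at_cand) + 1  # saturate: even maximal tilt undershoots
        } else {
          ctr <- stats::uniroot(
            function(ctr) w_mean(ctr) - target,
            lower = min(at_cand) - 1, upper = max(at_cand) + 1,
            tol = 1e-6
          )$root
        }
        w <- stats::plogis(steepness * (at_cand - ctr))
        pos <- cand[sample.int(length(cand), 1L, prob = w)]
      }
      chroms[i] <- names(genome)[ci]
      starts[i] <- pos - 1L
      lens[i] <- len
    }
    frags <- Biostrings::DNAStringSet(
      substring(seqs[chroms], starts + 1L, starts + lens)
    )
    names(frags) <- ids
    list(
      fragments = frags,
      loci = data.frame(
        fragment_id = ids, chrom = chroms,
        start = starts, end = starts + lens,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate non-overlapping gene models
#'
#' Genes are placed without overlap on random chromosomes and strands;
#' exon counts are uniform over the configured range and exon/intron
#' lengths are geometric-ish draws bounded to fit.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param config A [sim_config()].
#' @return A named list of [gene_model()] objects (possibly empty).
#' @export
simulate_gene_models <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  widths <- Biostrings::width(genome)
  .with_stream(config$seed, 401L, function() {
    models <- list()
    occupied <- lapply(seq_along(genome), function(i) {
      data.frame(start = integer(), end = integer())
    })
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        ci <- sample.int(length(genome), 1L, prob = widths)
        ne <- sample(config$exon_count_range[1]:config$exon_count_range[2], 1L)
        exon_len <- pmax(30L, stats::rgeom(ne, 1 / 150) + 1L)
        intron_len <- if (ne > 1L) {
          pmax(50L, stats::rgeom(ne - 1L, 1 / 800) + 1L)
        } else {
          integer(0)
        }
        span <- sum(exon_len) + sum(intron_len)
        if (span >= widths[ci]) next
        start <- sample.int(widths[ci] - span, 1L) - 1L  # 0-based
        end <- start + span
        occ <- occupied[[ci]]
        if (nrow(occ) && any(pmin(end, occ$end) > pmax(start, occ$start))) {
          next
        }
        bounds <- start + cumsum(c(0L, as.vector(rbind(
          exon_len, c(intron_len, 0L)
        ))[seq_len(2L * ne - 1L)]))
        exon_starts <- bounds[seq(1L, by = 2L, length.out = ne)]
        exon_ends <- exon_starts + exon_len
        gid <- sprintf("gene%02d", i)
        models[[gid]] <- gene_model(
          gene_id = gid,
          chrom = names(genome)[ci],
          strand = sample(c("+", "-"), 1L),
          exon_starts = exon_starts,
          exon_ends = exon_ends
        )
        occupied[[ci]] <- rbind(occ, data.frame(start = start, end = end))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("gene density infeasible: could not place gene without overlap")
      }
    }
    models
  })
}

#' Simulate a ChIP-qPCR Ct table
#'
#' `ct_noab - ct_ip` is Normal with the configured mean and sd; the IP Ct
#' itself sits at a fixed baseline of 30 cycles.
#'
#' @param config A [sim_config()].
#' @return A data frame with `id`, `ct_ip`, `ct_noab`.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_stream(config$seed, 503L, function() {
    delta <- stats::rnorm(config$qpcr_n, config$qpcr_delta_mean,
                          config$qpcr_delta_sd)
    data.frame(
      id = sprintf("sample%02d", seq_len(config$qpcr_n)),
      ct_ip = rep(30, config$qpcr_n),
      ct_noab = 30 + delta,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper running every generator off one config: genome
#' (optionally with planted motifs), fragments with loci, gene models and
#' a qPCR table.
#'
#' @param config A [sim_config()].
#' @param patterns Optional plain pattern set to plant at
#'   `config$motif_density`.
#' @return A list with `genome`, `plants`, `fragments`, `loci`, `genes`,
#'   `qpcr`, and the `config` itself.
#' @export
simulate_bundle <- function(config, patterns = NULL) {
  genome <- simulate_genome(config)
  plants <- NULL
  if (!is.null(patterns) && config$motif_density > 0) {
    planted <- plant_motifs(genome, patterns, config$motif_density,
                            seed = config$seed)
    genome <- planted$genome
    plants <- planted$plants
  }
  fr <- simulate_fragments(genome, config)
  genes <- simulate_gene_models(genome, config)
  qpcr <- simulate_qpcr(config)
  list(
    genome = genome, plants = plants,
    fragments = fr$fragments, loci = fr$loci,
    genes = genes, qpcr = qpcr, config = config
  )
}
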