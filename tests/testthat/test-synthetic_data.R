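test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 14, chrom_lengths = c(chr1 = 40000L),
                    n_genes = 5L)
  expect_identical(as.character(simulate_genome(cfg)),
                   as.character(simulate_genome(cfg)))
  g <- simulate_genome(cfg)
  pats <- expand_iupac("ATATTCGCGAWWATT")
  p1 <- plant_motifs(g, pats, density = 100, seed = 14)
  p2 <- plant_motifs(g, pats, density = 100, seed = 14)
  expect_identical(p1$plants, p2$plants)
  f1 <- simulate_fragments(g, cfg)
  f2 <- simulate_fragments(g, cfg)
  expect_identical(f1$loci, f2$loci)
  expect_identical(simulate_gene_models(g, cfg),
                   simulate_gene_models(g, cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_genome(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("simulated genome matches its configured AT composition", {
  cfg <- sim_config(
    seed = 2,
    chrom_lengths = c(chr1 = 1000000L),
    at_mixture = data.frame(weight = 1, mean = 0.59, sd = 0)
  )
  g <- simulate_genome(cfg)
  prof <- window_profile(g)
  expect_equal(mean(prof$values), 0.59, tolerance = 0.01 / 0.59)

  # clamping: a mean of 0 still yields AT >= 0.05 per window target
  cfg0 <- sim_config(seed = 3, chrom_lengths = c(chr1 = 100000L),
                     at_mixture = data.frame(weight = 1, mean = 0, sd = 0))
  g0 <- simulate_genome(cfg0)
  prof0 <- window_profile(g0)
  expect_lt(mean(prof0$values), 0.07)
  expect_gt(mean(prof0$values), 0.03)
})

test_that("motif planting respects density zero and non-overlap", {
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 50000L))
  g <- simulate_genome(cfg)
  pats <- expand_iupac("ATATTCGCGAWWATT")
  none <- plant_motifs(g, pats, density = 0, seed = 8)
  expect_identical(as.character(none$genome), as.character(g))
  expect_equal(nrow(none$plants), 0L)

  many <- plant_motifs(g, pats, density = 400, seed = 8)
  pl <- many$plants
  expect_gt(nrow(pl), 0L)
  for (ch in unique(pl$seqid)) {
    st <- sort(pl$start[pl$seqid == ch])
    if (length(st) > 1L) expect_true(all(diff(st) >= 15L))
  }
  # every plant is literally present in the emitted genome
  seqs <- stats::setNames(as.character(many$genome), names(many$genome))
  written <- substring(seqs[pl$seqid], pl$start + 1L, pl$start + 15L)
  expect_identical(unname(written), pl$variant)
  # an impossible density errors out rather than looping forever
  tiny <- Biostrings::DNAStringSet(c(c1 = paste(rep("C", 40), collapse = "")))
  expect_error(
    plant_motifs(tiny, pats, density = 2e6, seed = 1, max_tries = 20L),
    "density"
  )
})

test_that("fragment lengths, counts and loci match the configuration", {
  cfg <- sim_config(seed = 12, chrom_lengths = c(chr1 = 150000L))
  g <- simulate_genome(cfg)
  fr <- simulate_fragments(g, cfg)
  expect_length(fr$fragments, 49L)
  w <- Biostrings::width(fr$fragments)
  expect_true(all(w >= 105L & w <= 1848L))
  expect_equal(fr$loci$end - fr$loci$start, w)
  # recorded loci address the genome: sequences must agree
  seqs <- stats::setNames(as.character(g), names(g))
  cut_out <- substring(seqs[fr$loci$chrom], fr$loci$start + 1L, fr$loci$end)
  expect_identical(unname(cut_out), unname(as.character(fr$fragments)))
})

test_that("AT-shifted fragments are enriched; unshifted ones are not", {
  cfg <- sim_config(seed = 20, chrom_lengths = c(chr1 = 200000L))
  g <- simulate_genome(cfg)
  prof <- window_profile(g)
  shifted <- simulate_fragments(g, cfg)
  expect_gt(mean(at_content(shifted$fragments)) / 100,
            mean(prof$values) + 0.03)
  cfg0 <- sim_config(seed = 20, chrom_lengths = c(chr1 = 200000L),
                     fragment_at_shift = 0)
  null_fr <- simulate_fragments(g, cfg0)
  expect_lt(abs(mean(at_content(null_fr$fragments)) / 100 -
                  mean(prof$values)), 0.03)
})

test_that("simulated gene models satisfy the gene-model invariants", {
  for (seed in c(1, 7, 23)) {
    cfg <- sim_config(seed = seed, chrom_lengths = c(chr1 = 120000L),
                      n_genes = 15L)
    g <- simulate_genome(cfg)
    models <- simulate_gene_models(g, cfg)
    expect_length(models, 15L)
    widths <- stats::setNames(Biostrings::width(g), names(g))
    for (gm in models) {
      expect_s3_class(gm, "gene_model")
      expect_true(all(diff(gm$exon_starts) > 0))
      expect_true(all(gm$exon_ends > gm$exon_starts))
      expect_gte(gm$span_start, 0L)
      expect_lte(gm$span_end, widths[[gm$chrom]])
    }
    # non-overlap within each chromosome
    spans <- data.frame(
      chrom = vapply(models, `[[`, "", "chrom"),
      s = vapply(models, `[[`, integer(1), "span_start"),
      e = vapply(models, `[[`, integer(1), "span_end")
    )
    for (ch in unique(spans$chrom)) {
      sub <- spans[spans$chrom == ch, ]
      sub <- sub[order(sub$s), ]
      if (nrow(sub) > 1L) {
        expect_true(all(sub$s[-1] >= sub$e[-nrow(sub)]))
      }
    }
  }
  cfg0 <- sim_config(seed = 1, n_genes = 0L)
  expect_length(simulate_gene_models(simulate_genome(
    sim_config(seed = 1, chrom_lengths = c(chr1 = 10000L))
  ), cfg0), 0L)
})

test_that("simulated qPCR tables follow the configured dCt model", {
  cfg <- sim_config(seed = 4, qpcr_n = 6L, qpcr_delta_mean = 6.97,
                    qpcr_delta_sd = 0)
  q <- simulate_qpcr(cfg)
  expect_equal(nrow(q), 6L)
  enr <- fold_enrichment(q)
  expect_equal(enr$fold, rep(2^6.97, 6L))
  cfg0 <- sim_config(seed = 4, qpcr_n = 50L, qpcr_delta_mean = 0,
                     qpcr_delta_sd = 0.2)
  f0 <- fold_enrichment(simulate_qpcr(cfg0))$fold
  expect_lt(abs(mean(log2(f0))), 0.15)
})

test_that("density and AT-shift parameters are recoverable from outputs", {
  pats <- expand_iupac("ATATTCGCGAWWATT")
  true_density <- 100
  n_rep <- 60
  est <- numeric(n_rep)
  base_cfg <- sim_config(seed = 1000, chrom_lengths = c(chr1 = 150000L))
  g <- simulate_genome(base_cfg)
  stopifnot(scan_genome(g, pats)$n == 0L)  # spurious-free background
  for (r in seq_len(n_rep)) {
    planted <- plant_motifs(g, pats, density = true_density, seed = 2000 + r)
    n <- scan_genome(planted$genome, pats)$n
    est[r] <- n / (genome_length(g) / 1e6)
  }
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - true_density), 3 * se + 1e-9)

  prof <- window_profile(g)
  shifts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg_r <- sim_config(seed = 3000 + r, chrom_lengths = c(chr1 = 150000L))
    fr <- simulate_fragments(g, cfg_r)
    shifts[r] <- mean(at_content(fr$fragments)) / 100 - mean(prof$values)
  }
  se_s <- sd(shifts) / sqrt(n_rep)
  expect_lt(abs(mean(shifts) - 0.06), 3 * se_s + 0.005)
})
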