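---
title: "Characterizing ChIP-derived DNA fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing ChIP-derived DNA fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipfrag)
```

## The problem

Chromatin immunoprecipitation (ChIP) followed by cloning and sequencing
yields a set of DNA fragments bound in vivo by a protein of interest — here
the archetype is HMGA2, an architectural transcription factor with three
AT-hook domains that bind the minor groove of AT-rich DNA. Once roughly
fifty cloned fragments are in hand, the informative questions are
computational:

1. Do published degenerate consensus binding sites occur in the fragments,
   and how often would they occur in a genome by chance?
2. Is the fragment set AT-enriched relative to the genome background?
3. Do the fragments share conserved short segments with each other, and
   what does their alignment profile look like as a sequence logo?
4. How strong was the immunoprecipitation enrichment (qPCR)?
5. Where do the fragments land relative to gene models?

`chipfrag` implements each of these steps as a small, separately testable
module, plus a synthetic-data generator so the entire pipeline can be
exercised and calibrated without downloading a genome assembly.

## Consensus scanning and occurrence statistics

A degenerate IUPAC pattern such as `ATATTCGCGAWWATT` (`W` = A or T) denotes
a set of plain sequences; `expand_iupac()` enumerates the Cartesian product
of its codes and unions over patterns. Scanning (`scan_genome()`) is exact
multi-pattern matching over a constant-width set, built on Biostrings'
preprocessed dictionary matching: every occurrence of every variant is
reported, overlapping occurrences included, and windows containing `N`
never match. A position matched by several variants counts once per
(position, strand) — the quantity of interest is binding *sites*, not
pattern multiplicity. Forward-only scanning is the default; `strands =
"both"` additionally matches reverse complements and reports them at their
plus-strand coordinate. The contract is defined by equivalence to a naive
sliding-window oracle, which the test suite enforces over a hundred random
genomes.

The occurrence statistics are deliberately simple. Under a uniform i.i.d.
base model a set of $K$ distinct $L$-mers is expected once every $4^L/K$
bp (`expected_spacing()`); the observed spacing is $G/n$ for $n$ matches in
a genome of $G$ bp; and their quotient is the overrepresentation ratio.
For the canonical HMGA2 case — two degenerate 15-mers relaxed to a
4,096-variant set — the expected spacing is $4^{15}/4096 = 262{,}144$ bp,
and an observed spacing of 104,565 bp corresponds to a 2.5-fold
overrepresentation. The derivation of the 4,096-variant set itself (a
lower-constraint relaxation from a SELEX study) is *not* hard-coded: the
expansion of the two published 15-mers alone yields 8 variants, so the
full relaxed set is treated as user-supplied input wherever it matters.

## AT-content versus a windowed genome background

`window_profile()` tiles each genome record left-to-right into
non-overlapping windows (default 500 bp), discarding the trailing
remainder so all windows are identically sized. Windows with fewer than
half their bases unambiguous are excluded and counted; for kept windows
the AT fraction is computed over unambiguous bases only. The exclusion
threshold is our decision — assembly gaps are the realistic source of `N`
runs, and a window that is mostly gap carries no compositional
information. `at_content()` applies the same N-exclusion rule to whole
fragments.

`compare_fragments_to_genome()` runs the Wilcoxon rank-sum test with
fragments as sample 1 and genome windows as sample 2. We report the
Mann–Whitney statistic $W$ (number of fragment-window pairs in which the
fragment is more AT-rich, ties counting one half) together with the
classical rank sum $W + n_1(n_1+1)/2$. Since the scientific hypothesis is
AT *enrichment*, the one-sided "greater" p-value is the primary output,
with the two-sided value emitted alongside. The exact null distribution is
used for tie-free samples with $\max(n_1,n_2)\le 25$; otherwise a normal
approximation with midrank tie correction and a 0.5 continuity
correction. The suite cross-checks both paths against `stats::wilcox.test`
and verifies that the null rejection rate at $\alpha = 0.05$ stays inside
a 99% binomial envelope over 1,000 simulated pairs (allowing for the mild
conservatism of a discrete exact test).

## Conserved short segments and the sequence logo

Cross-fragment similarity search mimics blastn tuned for short sequences:
exact shared words of length 7 seed ungapped X-drop extensions scored
+1/match, −3/mismatch, with extension stopping once the running score
falls 10 below its running maximum and trimming back to the maximum. No
E-value machinery is implemented: the original analysis ran essentially
unfiltered (Expect = 100, low-complexity filter off), and the permissive
limit of that setting is simply "report every extended seed". Self-pairs
are excluded; both subject strands are searched; seeds falling inside an
alignment already produced on the same diagonal are skipped; and distinct
seeds trimming to identical coordinates are merged. With an effectively
infinite X-drop the extension is provably the maximal-scoring segment on
the seed's diagonal, which is how the exhaustive-oracle tests pin the
aligner down on fragments of ≤ 60 bp.

Alignments of exactly 11 or 12 bp are collected (`collect_segments()`),
taken query-side in plus orientation, and deduplicated as exact strings —
our operationalization of "adjusted manually from redundancies", which the
original description leaves unspecified. `build_pfm()` counts letters per
column with no pseudocounts, and `information_content()` computes
$IC_i = 2 + \sum_b f_{ib}\log_2 f_{ib}$ bits against a uniform
background, with letter heights $f_{ib} \cdot IC_i$. The small-sample
correction $e(n) = 3/(2\ln(2)\,n)$ is available but off by default: it
makes the logo a function of $n$ as well as of the frequencies, and
whether the original figure applied it is unknowable.

## qPCR enrichment

`fold_enrichment()` is the standard no-antibody-referenced ChIP
quantification: $\Delta C_t = C_t^{NoAb} - C_t^{IP}$ and fold
$= 2^{\Delta C_t}$. `mean_enrichment()` averages the folds themselves, not
the $\Delta C_t$ values — the published five-sample average of 246-fold is
reproduced only under this convention (averaging cycles first would give
$2^{7.64} \approx 200$).

## Locus classification

`classify_locus()` assigns each fragment exactly one category. A fragment
overlapping any gene span is intragenic and reports the exon or intron
with the largest overlap, numbered strand-awarely in transcript
orientation; exact ties break toward the exon (exonic evidence is rarer
and a unique feature is reported per fragment). A fragment on a
gene-bearing chromosome without overlap is intergenic relative to the
nearest gene by edge-to-edge distance, with upstream/downstream defined
by that gene's transcription direction; distances are kept exact in bp
and only rounded in human-readable reports. A fragment on a contig with
no gene models — or literally on `"unplaced"` — is unplaced. A
mirror-image property test (reflecting all coordinates and flipping all
strands) guards the strand-awareness of the numbering.

## The synthetic-data generator

The generator emulates the study conditions end-to-end:

* **Genome**: per 500-bp block an AT fraction is drawn from a
  two-component Gaussian mixture (weights 0.7/0.3, means 0.56/0.64, sds
  0.05/0.07, clamped to [0.05, 0.95]) and bases are emitted i.i.d. The
  mixture mean is ≈ 0.584, matching the ~59% genome-wide AT average, and
  the two components give the right-shifted, skewed window distribution
  that a single Gaussian cannot — the genome-wide AT distribution is
  distinctly non-normal. These component values are implementation
  defaults chosen once, not empirical claims.
* **Fragments**: 49 fragments, lengths uniform on 105–1848 bp, with
  start positions tilted toward AT-rich intervals by a logistic weight
  $\sigma(50\,(a_j - c))$ on each candidate interval's own AT fraction
  $a_j$; the center $c$ is calibrated per fragment so the expected
  sampled AT equals the background mean plus a configurable shift
  (default +0.06, emulating the observed enrichment). With shift 0 the
  start is uniform, which is the null used for type-I calibration.
  Weighting by the fragment interval's own AT (rather than one window's)
  avoids attenuation for fragments spanning several composition blocks.
* **Planted motifs**: Poisson-distributed counts at a configurable
  density per Mbp, placed without overlap so ground truth is unambiguous.
* **Gene models** and **qPCR tables** with configurable shape; the qPCR
  $\Delta C_t$ default (mean 7.64, sd 1.1) matches the scale of the
  published five-sample table.

All generators derive their randomness from the single config seed (with
fixed per-generator offsets, so adding a stage never perturbs another) and
restore the caller's RNG state.

What the generator does **not** emulate: chromatin structure, nucleosome
positioning, sonication-length biases correlated with composition,
cloning biases, or sequencing error. Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the *computational*
procedure under its stated model, not the biological conclusions one
would draw from real immunoprecipitates.

## Numerical and scale choices

Problem sizes in the test suite were chosen to exercise every code path
at comfortable desk scale: oracle-equivalence scans use random genomes up
to ~25 kb per chromosome over 100 seeds; the Poisson spurious-rate check
uses a 5-Mbp uniform-composition genome where a 16-variant 8-mer set is
expected ~1,200 times; power and null calibration of the AT comparison
use a 200-kb background (400 windows) with 100 and 300 replicates
respectively; the exhaustive alignment oracles run on fragments of ≤ 60
bp where $O(n^2)$ segment enumeration is trivial. The pipeline smoke
tests run a full 12-fragment bundle on a 100-kb two-chromosome genome.

Degenerate inputs are signalled, not silently absorbed: zero matches make
the observed spacing an error (not infinity), an all-`N` sequence has no
AT-content, an empty sample cannot enter the rank-sum test, and a motif
density that cannot be placed without overlap raises after bounded
retries.

## Known limitations

* Genome-build-dependent published values (6 exact consensus matches,
  27,455 relaxed matches, $W = 105{,}561{,}580$, the 134 logo segments)
  require human build 36 plus RefSeq and the original BLAST stack; they
  are out of scope and replaced by the property-based checks above.
* The aligner is ungapped by design; gapped or translated searches are
  non-goals.
* Exact-string deduplication of segments is a stand-in for an
  unspecified manual curation step; near-duplicate collapsing is not
  attempted.
* The scan treats the relaxed variant set as given; no position-weight
  matrix or soft matching is offered because the procedure being
  reproduced is exact-set matching.
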