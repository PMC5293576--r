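---
title: "Differential H3K4me3 analysis between a tumour and its matched control: methods"
author: "histodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histodiff methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`histodiff` implements a paired-sample differential analysis of a
promoter-associated histone mark (H3K4me3) between one case library
(e.g. a glioblastoma specimen) and one matched control (surrounding
tissue).  There are no replicates in this design; every statement the
pipeline makes is descriptive of the pair, plus two classical tests
(a Welch t-test over CpG-island windows and a Poisson test for
copy-number candidates).  The stages are:

1. **Coverage.**  Mapped reads are shifted 50 bp toward the fragment
   midpoint (`+` reads downstream, `-` reads upstream), piled up into
   per-base counts, and normalized by the genome-average per-base count
   so the global mean of each track is exactly 1.  All fold statements
   downstream are on this normalized scale.
2. **Profiles.**  Average signal at each offset around anchor sets
   (TSSs, TTSs, CpG-island midpoints), strand-oriented so negative
   offsets are 5' of the anchor.
3. **Differential peaks.**  Peaks (externally called, or from the
   built-in threshold caller) are counted per gene in three categories:
   the distal promoter window (-5 kb / +1 kb around the TSS), exons,
   and the gene body.  A gene with no peak in any category in one
   sample and at least one peak in the other is *gained* or *lost*;
   category identity is deliberately ignored (presence/absence is the
   classification unit).
4. **Amplification.**  Regions satisfying five read-count criteria are
   reported as copy-number-amplified candidates, scored by
   `P(X >= k)` for `X ~ Poisson(lambda)` with `lambda` the control
   region read count (library-size scaled) and `k` the case count.
5. **Expression linkage.**  Pearson correlation between per-gene
   TSS-vicinity counts (-0.5 kb to +1 kb) and an external mean
   expression table; a rank-sum comparison between two user-supplied
   gene sets.

## Shift direction

The field's standard fragment-shift correction moves each read toward
the fragment center.  Read literally, "shifted in the 5' direction"
would move the two strands apart and split every promoter peak in two.
`shift_params(literal_5prime = TRUE)` implements the literal reading
for comparison; the default is center-ward, which is what reproduces
the canonical TSS enrichment profile.  Reads are used at their mapped
length; `extend_to` resizes them to a fixed fragment length first when
set (no extension by default).

## Normalization

The genome mean is computed over *every* base of every chromosome in
the declared genome, including zero-coverage bases.  An equivalent
normalization by total mapped reads differs only by a constant factor
and therefore changes no fold ratio or correlation; the genome-average
convention is used because it makes "fold over the genome mean" read
directly off the normalized track.  Normalizing an already-normalized
track is an error rather than a silent re-application.

## The five amplification criteria

A region is reported when (1) its width strictly exceeds 1000 bp;
(2) its case density is at least 5-fold the case genome mean; (3) at
least 5-fold the control count in the same region; (4) at least 2-fold
the control genome mean; and (5) duplicate reads were removed by
sequence upstream.  Criterion (4) is read as a condition on the *case*
count against the *control* average: the control-side reading would
make a clean single-copy-control amplification fail the filter, which
cannot be the intent.  On normalized tracks (2) and (4) differ only by
the ratio of the two genome means, and both are reported.

**Candidate delimitation.**  The criteria are region-level predicates;
nothing defines where regions come from.  The scan slides 200-bp
windows at 100-bp steps, admits windows where the fold criteria hold
at 80% of their thresholds (`candidate_frac`), merges admitted windows
across gaps up to 200 bp, and re-tests *every* criterion at full
strength on each merged region's aggregate counts.  The two-threshold
(hysteresis) design is deliberate: a 200-bp window at realistic depth
holds few reads, so single-window Poisson noise would otherwise
truncate or fragment a true region; the aggregate re-test guarantees
that anything emitted satisfies all five criteria.  Window, step, gap
and fraction are all configurable.

**Count scale for the Poisson test.**  The Poisson test needs counts,
not per-base coverage sums (a 36-bp read contributes 36 covered
bases).  Each track records its mean retained read width; region
coverage sums are converted back to estimated read counts by dividing
by it.  `lambda` is additionally scaled by the case/control
library-size ratio (`depth_scaling = FALSE` disables this).  The tail
is inclusive, `P(X >= ceiling(k))`, the standard enrichment
convention; for `lambda = 0` the tail is 1 at `k = 0` and 0 otherwise.

## The stand-in peak caller

`standin_call_peaks()` thresholds the normalized track at `min_value`
(default 5, i.e. 5-fold the genome mean), merges runs separated by at
most `merge_gap` bp (default 50) and keeps runs at least `min_width`
bp wide (default 100).  It exists so the pipeline is testable without
an external caller and is documented as *not* a model-based broad-peak
caller; real analyses should supply MACS-style broadPeak files via the
pipeline's `peaks_control`/`peaks_case` inputs.  The defaults were
fixed against the generator's study conditions: at 0.02 reads/bp,
background stacks of 5+ overlapping reads are rare and never span
100 bp, while the weakest simulated promoter (~105 expected reads)
exceeds the threshold over >100 bp with large margin, so both false
and missed calls have vanishing probability.

# The synthetic study

`simulate_chipseq()` generates the conditions the analysis assumes:

* two 500-kb chromosomes; 60 genes placed in fixed 15.5-kb slots with
  >= 10 kb between gene bodies (placement failure is an error, not a
  retry); 1-4 exons per gene;
* uniform background reads per strand at 0.02 reads/bp/sample
  (Poisson counts, 36-bp reads);
* promoter enrichment: extra reads whose 5' ends sit ~50 bp outside
  the TSS on each strand with 30-bp Gaussian jitter, so the 50-bp
  center-ward shift stacks them on the TSS.  The expected extra-read
  count per gene is `(enriched_fold - 1) * depth * enrichment_span`
  (defaults 8, 0.02, 750 -> 105 reads) times a per-gene log-normal
  factor (sdlog 1.3) floored at 1 and capped at 12.  The floor makes
  every enriched promoter reliably callable (exact gain/loss recovery
  is a design goal of the fixture); the cap keeps single promoters
  from dominating the genome mean of a megabase-scale toy genome; the
  spread gives the ~2-decade dynamic range real promoter marks show;
* 10% of genes enriched only in the case (gained), 10% only in the
  control (lost), the rest in both at the same true level;
* one 2-kb region in which every case read is duplicated fold-1 times
  (default fold 6) with *distinct* synthetic sequence tags -- genuine
  extra molecules, as a copy-number gain produces.  PCR duplicates
  (identical tags) can be injected separately via
  `pcr_duplicate_rate`;
* CpG islands centered on every TSS plus ten intergenic ones;
* expression linearly coupled to the true case promoter intensity
  with Gaussian noise, floored at zero.

Sequence tags live in the BED name column (BED carries no sequence);
`dedup_reads()` keys on coordinates + strand + tag when tags are
present and on coordinates + strand otherwise.

**What the generator does not emulate:** mappability, GC bias,
fragment-length variation, read errors, chromatin input controls,
replicate structure, or broad/dispersed mark domains.  Passing the
recovery tests therefore shows the *algorithms* are correct under the
stated statistical structure, not that the pipeline is robust to the
artefacts of real libraries.

## A scale caveat on the amplification criteria

The toy genome is ~60 genes/Mb, roughly ten times the human gene
density.  Promoter enrichment consequently lifts the genome-average
count by 10-30%, and the default fold-6 amplified region -- 6-fold the
*background* -- sits at only ~4.3-5x the case genome *mean*: criterion
(2) fails and the default study's region is correctly, reproducibly
not reported.  On a real genome promoters are a negligible fraction of
the total length and the two baselines coincide.  The amplification
recovery properties are therefore asserted on uniform-background
fixtures (one 300-kb chromosome at 0.5 reads/bp, where a 2-kb region
holds ~1000 reads and every fold margin is many Poisson standard
deviations wide): there the implanted 2-kb fold-6 region is recovered
at Jaccard >= 0.8 with all criteria true across 20 seeds, and an
800-bp region is never reported.  At the default depth of 0.02
reads/bp a 2-kb region holds ~40 reads, the fold-6 truth is within
about one Poisson standard deviation of the fold-5 threshold, and no
delimitation scheme could recover it reliably -- a statement about the
statistics of shallow coverage, not about the implementation.

# Statistical choices

* **CpG-window test:** per island, the mean normalized count over a
  500-bp window centered on the island midpoint; Welch's t-test by
  default (`pooled = TRUE` for Student's) -- the unequal-variance form
  is the safer default when the two libraries differ in depth and
  signal spread.
* **Gene-set comparison:** two-sided Wilcoxon rank-sum by default,
  because mean-expression tables are heavy-tailed; `test = "t"`
  switches to Welch.
* **Correlation:** Pearson on `log1p`-transformed values by default
  (both axes heavy-tailed); the raw-scale option exists and is what
  the simulation's linear-coupling check uses.
* **Meta-profiles:** windows truncated at chromosome ends contribute
  zeros rather than dropping the anchor, keeping the divisor equal to
  the anchor count at every offset.
* **Overlap rules:** >= 1 bp everywhere (category assignment and peak
  sharing); Venn sharing is counted per peak and per side, so the two
  shared counts may differ and are reported separately.
* **Ties and ordering:** amplified regions are sorted by ascending
  p-value then position; peak and read sorting is by (chrom, start,
  end); all outputs are deterministic given the seed.

# Problem sizes in the test suite

The suite verifies the pileup against brute-force per-base counting on
50 random instances (<= 10 kb genomes, <= 500 reads, shifts 0-100),
the Poisson tail against direct pmf summation on a lambda grid up to
50 with k up to 200 (1e-10 agreement), Welch and rank-sum results
against closed-form and exhaustive-enumeration references on 20 random
small samples (1e-8), exact gained/lost recovery on five seeded
default studies, amplification recovery on 20 uniform-background
fixtures (plus 20 800-bp negatives), and byte-identical pipeline
manifests across two runs of the same seed.  These sizes make every
oracle exactly computable while exercising the same code paths a
full-genome run uses.

# Known limitations

* Single pair, no replicates: no variance model for the gain/loss
  classification; it is a deterministic presence/absence rule over
  peak calls, and inherits all caller instability.
* The Poisson amplification score treats reads as independent; PCR
  and mappability artefacts violate this in real data (criterion 5
  removes only exact duplicates).
* The stand-in caller is a threshold rule; broad domains and
  composite peaks need a real caller.
* Input (chromatin) tracks are not modelled; the control sample plays
  that role in all ratios.
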