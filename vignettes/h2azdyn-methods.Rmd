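---
title: "h2azdyn: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{h2azdyn: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`h2azdyn` implements a desk-scale ChIP-seq analysis pipeline for histone
variant occupancy dynamics across a staged cell-state transition (three
samples: a somatic starting state, an intermediate day, and a fully
reprogrammed state). The genome-scale results of such a study depend on raw
sequencing data; this package instead makes the *methods* concrete,
deterministic, and testable: every algorithm is paired with either an exact
conservation law or a synthetic experiment whose ground truth is known by
construction.

# Data model

All coordinates are 0-based, half-open `[start, end)`. A *tag* is the 5'
position of a mapped read: the leftmost base for plus-strand reads, the
rightmost (`end - 1`) for minus-strand reads. Gene models carry `tss` and
`tes` as half-open boundary anchors: for a minus-strand gene `tss > tes` and
the gene body is `[tes, tss)`. The promoter is the 2 kb upstream of the TSS
(`[tss, tss + 2000)` on the minus strand) and the downstream region the 2 kb
past the TES. Exons must be sorted, non-overlapping, and contained in the
body; these invariants are validated at construction and again when models
are read from GTF or BED12.

# Peak calling

Tags are extended to `extension = 150` bp fragments in the read direction, a
standard surrogate for ChIP fragment size at ~50 bp read length. The
background model is a uniform Poisson process with rate

    lambda_bg = library_size / genome_length.

A window of width `w = 2 * bandwidth` (600 bp at the default
`bandwidth = 300`) slides in steps of `bandwidth / 2` (150 bp); a window
holding `k` fragment starts is significant when
`P(X >= k | X ~ Poisson(lambda_bg * w)) < p_threshold` with
`p_threshold = 1e-4`. Significant windows separated by at most `bandwidth`
are merged into peaks. Each peak's summit is the maximum of the
extended-fragment pileup inside the peak (ties resolved leftmost, so calls
are deterministic), and its score is `-log10` of the best window p-value.

Two numerical points matter here. The Poisson upper tail is evaluated on the
log scale (`ppois(k - 1, mu, lower.tail = FALSE, log.p = TRUE)`), so scores
remain finite and ordered even when the double-precision p-value underflows
to zero. And because roughly `2 * genome_length / bandwidth` windows are
tested, the caller's false-positive behaviour is a property, not an
assumption: on simulated pure noise the significant-window rate must stay
within an order of magnitude of the nominal `1e-4` (the test suite and the
acceptance script both measure it; `call_peaks()` exposes the counts as
attributes `n_windows` and `n_significant`).

The `mfold` argument of `peak_call_params()` is accepted for interface
completeness but unused: model refinement by high-confidence fold enrichment
needs a control library, which this pipeline does not model.

# Genome partition

Every base of the genome receives exactly one of seven classes: promoter,
5'UTR, CDS, intron, 3'UTR, downstream, intergenic. Overlaps between
candidate regions (of the same or different genes) are resolved by priority
painting:

    promoter > utr5 > cds > utr3 > downstream > intron > intergenic

Regulatory and coding annotations outrank intron, so a promoter of one gene
lying inside another gene's intron is labelled promoter. Regions are clipped
at chromosome edges. Exons of non-coding gene models (no CDS) fall in the
CDS bucket rather than a separate class, a deliberate simplification that is
logged when it happens. The construction guarantees — and the tests assert
against an independent per-base oracle — that the class base counts sum
exactly to the genome length.

# Peak-to-feature assignment and relative enrichment

A peak is assigned to the class under its summit, a single point, so the
per-class peak fractions always form a partition of unity. For class `c`,

    RE_c = peak_fraction_c / base_fraction_c,

the ratio of the fraction of peaks in `c` to the fraction of the genome `c`
occupies. `RE_c = 1` means no preference. Because both fraction vectors sum
to one over the same classes, the identity

    sum_c base_fraction_c * RE_c = sum_c peak_fraction_c = 1

holds exactly; the tests enforce it to 1e-12 on random tables, and the
identity case (peak fractions equal to base fractions) yields `RE = 1`
everywhere.

# Composite (metagene) profiles

For an anchor (TSS or TES), coverage of extended fragments is computed over
`[anchor - flank, anchor + flank)` with `flank = 5000`, normalized to reads
per million (`1e6 / library_size`), reversed for minus-strand genes so that
"left" always means upstream in transcription direction, averaged over genes
within `window = 200` bp bins (50 windows), and finally averaged across the
gene cohort. Genes whose anchor region crosses a chromosome end are excluded
and logged, rather than zero-padded, which would bias the cohort mean.

The 200 bp window is a resolution/noise compromise: it divides the 10 kb
span evenly, is close to a mononucleosome footprint plus linker, and at the
default simulated depth (~1M tags over 4 Mb) leaves enough fragments per
window that Monte-Carlo noise stays well below the 20% flatness margin used
in the tests. `profile_anchor_stats()` summarizes bimodality around the
anchor: the *anchor window* is the bin covering `[anchor, anchor + window)`,
and `left_max` / `right_max` are maxima over the strictly flanking bins.

Expression stratification ranks genes by decreasing expression (ties broken
by gene id, so the split is deterministic) and cuts them into four
near-equal classes — high, middle, low, lowest — with remainder genes going
to the higher classes.

# Occupancy and the three-way comparison

A gene is *occupied* when any peak overlaps its promoter-union-body interval
by at least one base, on half-open coordinates. Three samples' occupied sets
are decomposed into the seven Venn regions (three exclusive, three pairwise,
one triple); the region counts tile the union exactly, a conservation
property the tests check by direct membership enumeration.

# Auxiliary statistics

Over-representation analysis uses the hypergeometric upper tail
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)` for a query of size `n`
drawn from a universe of size `N` hitting `k` of a term's `K` genes, with
Benjamini-Hochberg adjustment across terms. The tests verify the p-value
against exhaustive enumeration of all subsets for small universes. qPCR
enrichment follows the delta-Ct rule `fold = 2^(Ct_control - Ct_target)`.

Reported percentages and mean peak lengths use half-up decimal rounding
(`round_half_up()`), not R's banker's rounding, matching how such report
tables are conventionally produced; this is what makes the table arithmetic
reproducible as exact equalities.

# The synthetic generator and its emulation scope

`simulate_experiment()` produces a complete experiment: annotation,
expression, three tag libraries, and ground truth. Its defaults *are* the
study conditions used throughout the tests and the acceptance script.

- **Annotation.** Genes are laid out in equal slots with alternating
  strands, each at least 7.5 kb from slot edges so every ±5 kb anchor region
  and 2 kb promoter fits inside its chromosome; three exons and a CDS from
  mid-first-exon to mid-last-exon populate all seven partition classes.
- **Background.** A uniform Poisson field at `background_rate = 100` tags
  per kb (scaled to the library), emulating nonspecific pulldown.
- **Signal.** Each gene adds a two-Gaussian mixture of fragment centers at
  TSS offsets `peak_offsets = c(-100, 200)` with `peak_sd = 80`,
  representing the well-positioned nucleosomes flanking the TSS. Centers
  falling within `dip_width / 2 = 100` bp of the midpoint of the two modes
  are rejected and redrawn, carving the nucleosome-depleted region between
  them. Centering the depletion on the mode midpoint rather than the TSS
  itself keeps both flanking modes intact while producing a genuine local
  minimum in the anchor window.
- **Dynamics.** Per-gene signal mass is proportional to the gene's
  expression-class amplitude (`4 / 2 / 1 / 0.5`) times a per-sample
  intensity (`Day7 1.3 > MEF 1.0 > iPSC 0.7`), encoding the study's two
  qualitative contrasts: profile height tracks expression, and the
  intermediate stage shows the strongest TSS enrichment.
- **Reads.** Each fragment center yields one read of 5' position
  `center -/+ floor(extension / 2)` with equal strand probability, so that
  extension during analysis reconstructs the fragment.
- **Determinism.** Every sample draws from its own RNG stream seeded by a
  deterministic function of `(seed, sample_id)` kept below `2^31`, so
  adding or reordering samples never perturbs another sample's data, and
  identical seeds give byte-identical tag files.

The generator deliberately does **not** emulate mappability gaps, duplicate
reads, GC bias, fragment-length variance, replicate-to-replicate noise, or
realistic peak-length distributions; genome-scale quantities (absolute peak
counts, occupied-gene totals) are not comparable to any real experiment.
What it supports is qualitative shape and ordering recovery — bimodal TSS
composites with a depleted anchor window, flat TES composites,
expression-ordered profile heights, recall of planted high-fold regions, and
occupancy sets matching truth — each of which the acceptance tests measure.

# Limitations

- Single-end, fixed-length fragments; no control library, so no fold-
  enrichment model refinement and no duplicate filtering.
- One isoform per gene (the longest exonic isoform when reading GTF).
- The uniform background is a simplification; real libraries show
  chromatin-state-dependent background that would require a local lambda
  (e.g. per-window maxima over several background scales).
- ORA treats genes as exchangeable; no gene-length or expression bias
  correction.
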