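---
title: "Benchmarking WGMS library protocols with wgmsQC"
author: "wgmsQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking WGMS library protocols with wgmsQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Whole-genome methylation sequencing (WGMS) converts unmethylated cytosines
to thymines (by bisulfite chemistry or enzymatically) and reads methylation
as the fraction of cytosine observations retained as C. Library-preparation
kits differ in insert-size distributions, PCR duplication, coverage
uniformity around CpG islands, conversion efficiency and read-end
artifacts, and those differences propagate into every downstream
methylation call. wgmsQC implements the metric stack used to compare such
protocols — raw-read and alignment QC, coverage uniformity against a
mappability-weighted expectation, context-stratified cytosine retention,
M-bias, spike-in conversion controls, binned-beta replicate concordance,
smoothed-M-value PCA, and a two-replicate cross-protocol bias test —
together with a synthetic read simulator that plants each artifact with a
known magnitude, so every metric is validated by parameter recovery at desk
scale.

The package does not wrap external aligners, trimmers or duplicate markers;
it re-implements the downstream computations on aligned fragments
(simulated, or read from a plain-text SAM dialect). Human data and
biological conclusions are out of scope.

# The measurement model

For one cytosine site, `M` counts read observations retained as C, `U`
counts conversions to T, and the methylation estimate is
`beta = M / (M + U)`. In CpG context beta estimates methylation; in CpH
contexts (CpA/CpC/CpT) retention mostly measures incomplete conversion,
except for CpA, where true methylation occurs in some tissues. Two
artifact rates act in opposite directions:

* **conversion failure** — an unmethylated C read as C, inflating
  retention; measured on the unmethylated lambda-like spike-in as its mean
  beta;
* **over-conversion** — a methylated C read as T, deflating retention;
  measured on the methylated pUC19-like spike-in as one minus its mean
  beta.

The expected read-averaged CpG retention is then approximately
`m(1 - oc) + (1 - m)cf` for truth mean `m`; with `m = 0.75`,
`cf = 0.005`, `oc = 0.01` that is 74.4% before composition effects (the
unmethylated mitochondria-like contig and island/background differences
pull the genome-wide value slightly lower), comfortably in the >70% regime
expected of a sound WGMS run, with CpH retention at or below 1%.

Read-averaged retention (`sum(M) / sum(M + U)`) is identically the
coverage-weighted mean of site betas; base-averaged retention is the
unweighted mean. Both are reported because they diverge exactly when
coverage and methylation are correlated.

# Coverage uniformity

Coverage comparisons are made at a fixed depth: each library is filtered to
mapped reads with MAPQ >= 40 and pairs are kept with probability
`target / n_mapped_q40` (capped at 1; mates share fate). The default
target of 150 million fragments corresponds to roughly 4.8X over a ~3.1
Gbp genome at 100 bp reads — `approxGenomeCoverage()` is that closed form.

Uniformity is the ratio `Obs / Exp`, where `Obs` is the share of mapped
read bases falling in a region and `Exp` is the region's share of the
genome-wide mappability mass (score x width), both restricted to bases
that carry a mappability score. Over any partition of scored bases both
`Obs` and `Exp` sum to 1, which the tests assert as a conservation
identity. Read bases are counted individually (overlapping mates
double-count), duplicate-flagged reads are excluded by default — covered
"by unique reads" — and both choices are flags.

Percent-of-CpGs-covered uses the *reference* CpG census in the denominator,
not just observed sites, with `min_cov = 1` ("at least one read"). One
upstream formulation prints the coverage cut as "> 1"; the package follows
the at-least-one-read reading and exposes `min_cov` so the stricter variant
is one argument away.

# Methylation extraction

Extraction re-infers conversion states by comparing aligned bases to the
reference, the way bisulfite-aware callers do, rather than trusting
simulator metadata: OT/CTOB-strand reads report top-strand cytosines
(reference C), OB/CTOT reads report bottom-strand cytosines (reference G),
and the retained/converted letters follow the bisulfite strand. This is
what "flipping PBAT strands in silico" amounts to operationally: a CTOT
read shows G (retained) or A (converted) at top-strand C positions, and
the extractor assigns it to the top strand with context taken 3' of the C
on that strand. An earlier design carried conversion states in a per-base
SAM tag with re-inference as a second mode; the package ships re-inference
only, because it is the mode that works on any SAM-dialect input and makes
the round-trip test meaningful.

Defaults: observations within 3 bp of either read end are excluded
(matching common aligner behaviour; M-bias profiles are computed *without*
this exclusion, since M-bias is the diagnostic used to choose it);
duplicate reads and MAPQ < 40 reads are excluded; Swift-like libraries
additionally exclude the first 14 bp of read 2 (`r2_clip`), which removes
the Adaptase low-complexity tail at extraction time rather than at
trimming time — equivalent effect, simpler pipeline. Palindromic CpG
records are merged across strands onto the top-strand anchor; CpH records
are never strand-merged.

Conversion controls follow the coverage rules of the source protocol
comparison: at least 3 reads per CpG on the mitochondria-like contig, at
least 1 on the trace-level spike-ins. An empty control is flagged, not an
error — at low coverage a methylated control can degenerate to all-1.0
betas, which is precisely the failure mode worth surfacing.

# Cross-sample comparison

Betas are averaged, unweighted, in 100-kb bins (undefined where a bin has
no covered CpG). Replicate concordance is the Spearman coefficient over
bins defined in both samples, reported with the bin count because the
correlation is depth-dependent. For PCA, per-bin M and U totals are
transformed to smoothed M-values `logit((M + k) / ((M + k) + (U + k)))`;
the smoothing factor eliminates the logit infinities at 0 and 1, and no
value being prescribed upstream, the default is `k = 0.5` (half-count
smoothing) with `k` exposed. Summing counts within the bin before the
transform was chosen over averaging site-level M-values; both are
consistent readings of "binned average betas transformed to M-values" and
the count-sum version is better behaved at low coverage. Bins undefined in
any sample are dropped listwise for PCA; Spearman uses pairwise deletion
because per-pair bin counts are themselves reported.

The bias test flags CpGs with `|beta_X - beta_Y| > 0.5` in replicate pair
1 AND in replicate pair 2, restricted to CpGs with more than 20 reads in
all four inputs — both inequalities strict, exactly as printed in the
source formulation.

# What the simulator plants, and what it does not

`generateGenome()` builds a CpG-depleted background (GC 0.40, 75% of CG
dinucleotides mutated away, the mammalian-like regime) with planted
GC-rich islands (GC 0.60, undepleted; >= 3x the background CpG density by
construction), gene/exon/repeat annotations, a 6 kb unmethylated
lambda-like contig, a 2.7 kb methylated pUC19-like contig and a 4 kb
circular unmethylated mitochondria-like contig. Mappability defaults to
1.0 with optional planted low-mappability segments.

`assignTruth()` draws per-CpG methylation from a Beta distribution with
mean 0.75 and concentration 2 by default — the scale consistent with >70%
CpG retention, without claiming any real tissue's distribution — shared by
the two strands of a palindromic CpG; CpA truth is a constant optional
level (biological CpH); control contigs are pinned to exactly 0 or 1.

`simulateFragments()` draws insert sizes from a log-normal law truncated
to [35, 1000] bp (the source only shows distribution shapes; log-normal
captures the right skew), weights fragment starts inside islands by
`cgi_bias` (PBAT-like profiles over-cover islands, `cgi_bias > 1`;
directional kits use <= 1 — magnitudes are free parameters, only the
direction is asserted), emits PCR duplicates as re-emissions of an earlier
molecule (identical coordinates and conversion states, fresh qualities;
PBAT presets use rate 0, matching a protocol with no amplification),
applies conversion failure modulated along the read by an M-bias
multiplier curve, over-conversion, a 0.1% substitution error on
non-cytosine bases (not modelled upstream, but needed so base-quality
metrics are non-degenerate), and flags a configurable fraction of reads
unmapped or sub-optimally mapped. The spike-in fragment rates default to
the trace levels at which the controls are added to genomic DNA (0.01%
unmethylated, 0.0005% methylated).

Not emulated: adapter sequence and trimming (the r2 tail is positions to
exclude, not literal adapter bases), SNPs and C/T disambiguation,
5hmC/5fC/5caC chemistry, mitochondrial supercoiling effects on PBAT
(circularity is metadata only), and depth extrapolation beyond the
observed complexity curve. Passing tests therefore demonstrate correctness
of the metric computations and recoverability of planted artifacts — not
that real libraries behave like the generator.

# Numerical and design choices

* Coordinates are 0-based half-open in every file format and 1-based
  closed inside `GRanges`; conversion happens only at the file boundary.
* Methylation BED betas are written with 4 decimals; counts are
  reconstructed by rounding, documented lossy beyond coverage 10,000.
  Zero-coverage sites are never written (undefined beta is an absent
  record, never 0).
* The duplicate identity key is (chrom, leftmost pair position, parent
  strand, insert size) — the conventional key; upstream delegated this to
  an external marker without defining it.
* The complexity curve counts read *pairs* (whether pairs or fragments
  were counted upstream is unstated) and is computed as prefix counts of
  one random permutation: a draw without replacement at every depth,
  monotone by construction, where independent per-point draws could
  violate monotonicity.
* Quality bins are `q < 20`, `20 <= q <= 30`, `q > 30`: 20 and 30 both
  fall in the medium bin.
* Insert draws are clamped (not resampled) to the truncation bounds and to
  at least half the read length; reads never extend past the fragment.
* Sequencing errors are never placed on parent-strand cytosine positions,
  so conversion states are exactly the drawn ones.
* With `k > 0` the M-value is finite for all counts including
  `M = U = 0`, which maps to 0.
* Undefined quantities (empty regions, zero qualifying pairs, fewer than 3
  common bins) return `NA` with a warning rather than erroring, except
  where the input is structurally invalid (unsorted merge input, missing
  @SQ header, non-positive bin width), which errors.

# Problem sizes used in the tests

Test fixtures use 100 kb–1 Mb genomes with a few thousand to 100k read
pairs — sizes at which brute-force per-base oracles are exact and fast.
The retention-regime check runs the full stated configuration (5 Mb,
200k pairs). The PCA separation check uses a 1 Mb genome at 100k pairs
(about 20X), with control-contig bins excluded from the feature matrix
(cross-sample comparison is a genomic question); at materially lower depth
the planted 0.5% vs 3% conversion-failure contrast is within binomial
noise of a 100-kb bin, which is the same depth-dependence the concordance
metric reports.

# Limitations

Parameter recovery for the spike-in controls at the default trace rates
needs billions of fragments; recovery tests therefore raise the spike-in
rates through the exposed arguments and the defaults are exercised for
rate correctness only. The simulator's island bias acts on fragment start
positions, a first-order model of primer/capture bias. The SAM dialect
restricts CIGARs to ungapped matches — there are no indels in the
synthetic genomes.
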