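---
title: "Methods: genome-centric analysis of denitrifying/fermentative enrichments"
author: "chemoguild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-centric analysis of denitrifying/fermentative enrichments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

chemoguild re-implements, as desk-scale, fully tested code, the
computational arc of a genome-centric enrichment study: anoxic chemostat
communities fed nitrite/nitrate and a defined carbon mixture are sequenced
(DNA and RNA), contigs are binned into provisional whole-genome sequences,
per-bin abundances are estimated by read mapping, functional genes
(*nirS*, *nirK*, *nosZ*, *pflB*) are detected on six-frame translations,
per-gene transcriptional activities are normalized within bins, bins are
classified into guilds (denitrifier / fermentative / both), and the
chemostat chemistry is closed with carbon/nitrogen mass balances.

Every stage runs on synthetic communities produced by the package's own
generator, so the whole pipeline is testable without sequencing downloads.
The generator's defaults are the study conditions the package emulates;
they are not tuned per analysis.

# The synthetic community generator

**Genomes.** Each population's genome is sampled from an order-3 Markov
chain over nucleotides. The transition matrix is a GC-consistent base
preference tilted by a population-specific random perturbation (log-normal,
sigma = 0.45) seeded by `signature_seed`. This gives each population a
stable, distinctive tetranucleotide signature — the premise of
composition-based binning — while GC is controlled exactly: after gene
planting, background positions are flipped until the realized GC matches
the target (well within the contracted 1 percentage point).

**Planted genes.** Marker (conserved single-copy), tRNA and background
genes are annotation-only features (their sequence is ordinary genome
background; the census and activity stages consume coordinates, not
sequence). Functional genes are real sequence: the consensus of the
packaged seed alignment is mutated at 10% of residues (so detection is
nontrivial but achievable) and reverse-translated with GC-tilted codon
choice. Coordinates in all truth tables are 1-based inclusive, with
minus-strand genes stored as the reverse complement of their coding
sequence.

**Seed alignments.** The packaged alignments for nirS (540 aa), nirK
(340 aa), nosZ (580 aa) and pflB (740 aa) are *synthetic stand-ins*
(filenames say so): ten members at ~12% divergence from a random ancestor
with realistic residue frequencies and a small gapped region. They have the
statistical shape profile scanning needs, but no biological content —
substitute curated alignments for real analyses.

**Fragmentation.** Assembly is out of scope; genomes are instead cut into
contigs with lengths uniform in [0.5, 1.5] x the N50 target (a remainder no
longer than the target stays whole, pieces below `min_len` merge
leftwards). Cut points are shifted out of planted genes so annotations lift
cleanly onto contigs; real assemblies do break genes, which is exactly the
failure mode the split-frame detector (below) addresses via simulated
homopolymer indels instead.

**Reads.** Single-end reads with normal lengths (default mean 150 bp,
emulating short-read chemistry; the generator also serves ~650 bp
pyrosequencing-like settings), uniform substitution errors (default 1%),
and optional per-homopolymer +/-1 bp indels (off by default). DNA reads are
drawn from population *p* proportional to abundance x genome length; RNA
reads from gene *g* proportional to expression x gene length, unstranded.
Qualities are constant Phred+33 encodings of the error rate. No paired
ends, no position-dependent error profile, no chimeras — so mapping
performance here is an upper bound on real data.

**Chemistry.** Chemostat observations are constructed to conserve C and N
exactly at the stated true yield, then perturbed with relative Gaussian
noise (default 5%; the emulated study states no instrument noise model, so
this is config-exposed). Batch series are linear with Gaussian noise of
standard deviation `noise_sd x c0`; making the noise proportional to the
series scale (not to each point) keeps ordinary least squares exact-nominal
for the 95% confidence intervals the rate estimator reports.

# Binning

Signatures are canonical tetranucleotide frequencies: 256 4-mers merged
with reverse complements into 136, so a contig and its reverse complement
are identical; windows containing ambiguous bases are skipped. A
pseudocount of 1 stabilizes short contigs during clustering (the bare
`tetra_signature()` defaults to 0 so hand-countable examples are exact).

Clustering: PCA on the signature matrix (default 5 components), plus
standardized log10 coverage and GC scaled to the spread of the first
component, then Ward agglomerative clustering; `k` is fixed or chosen by
mean silhouette width over 2..12. The procedure consumes no random numbers
and inputs are sorted by contig id, so assignments are deterministic and
order-invariant. Contigs under `min_contig_len` (default 1000 bp, exposed)
go to `unbinned`: sub-kb contigs destabilize 4-mer signatures.

N50 is the largest member length whose cumulative (descending) sum reaches
half the bin size; ties therefore resolve to the larger length. Summary
tables are emitted in bp and converted to kb only in the display formatter,
since "size (kb)" conventions are ambiguous across published tables.

# Abundance

A deliberately simple mapper stands in for a production aligner (the
quantity of interest is coverage, not alignments): disjoint exact 21-mers
of the read and its reverse complement anchor ungapped candidate
placements, verified by substitution-only identity (default minimum 0.9).
Each read goes to its single best placement; ties break to the smallest
contig id, `+` strand, smallest position. Reads with indels may go
unassigned — acceptable at the default indel rate of 0. On tiny inputs the
mapper is tested against exhaustive alignment over all positions and
strands.

Coverage is assigned bases over contig length; bin abundance is the bin's
share of assigned bases (coverage x length is additive, so splitting a
contig changes nothing). Whether unassigned mass belongs in the denominator
is ambiguous in published abundance figures, so both normalizations are
emitted (`abundance`, `abundance_binned_only`).

# Marker census

Completeness is `distinct marker families / 139` and more than 139 total
hits flags a mixed bin. Detection is annotation-driven (`marker_family=`,
`trna=` attributes in GFF3): the 139 conserved single-copy families are a
pluggable catalogue shipped as placeholder identifiers, because re-deriving
139 protein profiles is out of proportion for this package and the census
logic is independent of the family names.

# Gene detection

Contigs are translated in all six frames (bacterial code, table 11; stops
as `*`, ambiguous codons as `X`). Each family is an ungapped log-odds
profile built from its seed alignment: per column (columns with more than
50% gaps dropped), residue `a` scores
`log2((count_a + 1) / (n + 20) / background_a)` bits against a uniform
background. Ungapped PSSM windows stand in for full profile HMMs: they are
transparent, deterministic, and sufficient at desk scale for four
well-separated families.

Thresholds are calibrated per family on shuffled decoys: the threshold sits
halfway between the maximum score of 1000 residue-shuffled consensus copies
and the consensus score. The decoy maximum alone is *not* a safe cutoff —
scanning millions of genuine-negative windows will eventually exceed the
maximum of 1000 null draws — while true family members at the generator's
10% divergence score far above the halfway point. The margin and the decoy
count are exposed.

Frameshift tolerance: when no full window passes but a strong sub-threshold
signal exists (at least a quarter of the cutoff, which featureless contigs
never reach), the profile is split in half and the best prefix-half and
suffix-half windows are merged when they sit on the same strand in
different frames within 30 bp (small overlaps allowed); the summed score is
then tested against the threshold and the hit flagged `frameshift = TRUE`.
This mirrors how single-base homopolymer errors break one gene into two
adjacent reading frames.

# Transcriptional activity

An RNA read counts toward the gene containing its alignment midpoint (ties
to the smaller gene id, flagged). Activity of gene *g* is its read density
`c_g / L_g` divided by the arithmetic mean density of its bin, so defined
activities average exactly 1 per bin; 1 is "average activity for this
population", not an absolute expression level. Whether the mean should
include silent genes is genuinely open; the default includes them (simplest
reading, and zero-inflation then *raises* the activity of expressed genes),
with `expressed_only = TRUE` as the alternative. Bins with no signal yield
missing activities.

# Guilds

A bin is a denitrifier if any of nirS/nirK/nosZ is detected, fermentative
if pflB is detected, `both` if both, else `unclassified`. Presence means
detection regardless of transcription (activity is reported separately);
`require_transcription = TRUE` gives the stricter variant. Since pflB is
the only unambiguous fermentation marker assessed, aggregation warns that
"denitrifier" bins may still ferment by other routes. Informational
subtypes (`nitrite_reducer`, `n2o_reducer`, `complete`) are emitted for
denitrifiers without further claims.

# Mass balance

With influent nitrite/nitrate as the electron acceptors and organic carbon
in mM-C, the feed C:N ratio is carbon over acceptor nitrogen. Organic
nitrogen missing from the effluent ammonium was assimilated (negative
values warn of DNRA). Biomass follows the standard composition
CH~1.8~O~0.5~N~0.2~: N:C = 0.2 mol/mol and 24.6 g per C-mol. A stated
biomass "C:N ratio of 0.2" is interpreted as N:C = 0.2 — a literal C:N of
0.2 would mean physically impossible nitrogen-rich biomass.

The protein share of biomass is the one constant that standard composition
does not fix. Published bacterial values span roughly 0.40-0.55 g/g; the
package default is 0.47, the midpoint of the narrow range that makes the
standard composition reproduce both conversions the package's worked
examples document (protein predicted from assimilated nitrogen, and growth
yield from measured protein). It was chosen once, from those two published
anchors — which are inputs, not fitted quantities — and all three constants
are config-exposed.

Converted carbon defaults to the full influent carbon (complete consumption
holds for the warm cultures emulated); a partial-conversion override
exists. Batch rates are ordinary least-squares slopes with standard errors
and 95% confidence intervals, in mM/h and (x 24,000) umol L^-1 day^-1.

# Problem sizes and numerical choices

The test and demonstration communities use 3-5 populations of 30-60 kb at
4,000-20,000 reads — deliberately small genomes with the same statistical
structure (GC gaps of 7+ points, log-spread abundances, 25 markers and ~15
background genes per population) as the gigabase-scale original. Property
tests assert: GC within 1 point; fragmentation conserving genomes exactly;
read fractions within binomial 3-sigma of abundance x length; binning ARI
at least 0.95 on well-separated communities; abundance recovery within 0.02
at 100,000 reads; planted-gene recovery at exact coordinates with zero
false positives on 100 decoy trials; per-bin mean activity equal to 1 to
1e-9; noise-free chemostat yield round-trips to 1e-9; batch-rate 95% CI
coverage between 90% and 99% over 200 simulations.

Degenerate inputs are contracts, not accidents: all-ambiguous sequences,
empty contig sets, zero expression, zero assigned bases, zero-length genes,
infeasible yields and non-monotone time series all raise typed warnings or
errors, tested.

# Limitations

Passing on synthetic data shows the machinery is correct under its own
assumptions; it does not validate binning or detection performance on real
metagenomes, where repeats, strain mixtures, uneven error profiles and
cross-assembly dominate. The mapper ignores indels; the detector's PSSMs
have no position-specific gap model; the packaged seed alignments are
synthetic; guild classification assesses a single fermentation pathway; and
the chemostat model is steady-state only (no dynamics, no DNRA
partitioning).
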