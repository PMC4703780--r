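# chemoguild

Genome-centric metagenomics and chemostat mass balance for denitrifying and
fermentative microbial communities.

## The problem

In anoxic habitats such as coastal sediments, organic matter is degraded by
two interlocking guilds: **denitrifiers**, which respire nitrite/nitrate to
N₂ (key genes *nirS*/*nirK*, nitrite reductases, and *nosZ*, nitrous oxide
reductase), and **fermenters** (marker gene *pflB*, pyruvate formate
lyase). Chemostat enrichments of such communities are analyzed
genome-centrically: contigs assembled from metagenomic reads are binned
into provisional whole-genome sequences by tetranucleotide composition,
per-bin abundances are estimated by read mapping, functional genes are
detected on six-frame translations, metatranscriptomic reads give per-gene
activities, and the culture chemistry is closed with carbon/nitrogen mass
balances. chemoguild implements that entire computational arc as a tested R
package, together with a synthetic-community generator so every stage runs
and is verified at desk scale, with no sequencing downloads.

It is aimed at microbial ecologists and bioinformaticians who want a
transparent, seeded, fully reproducible reference implementation of these
standard analyses — and a test bed whose ground truth is known.

## What it computes

* **Binning** — canonical tetranucleotide signatures (136 reverse-complement
  merged 4-mers), GC, PCA + Ward clustering with log-coverage and GC as
  extra features; bin statistics (size, N50, GC, marker/tRNA census) and
  GC-vs-coverage blob tables.
* **Abundance** — a seeded k-mer mapper assigns reads to contigs; coverage
  is assigned bases per bp and bin abundance is the bin's share of assigned
  bases: `A(bin) = Σ_{i∈bin} cov_i·L_i / Σ_i cov_i·L_i`.
* **Completeness** — distinct hits among 139 conserved single-copy gene
  families (`completeness = distinct/139`); >139 total hits flags a mixed
  bin; tRNA counts as a second line of evidence.
* **Gene detection** — per-family ungapped log-odds profiles
  (`log2((n_a+1)/(n+20)/q_a)` bits) slid along all six reading frames,
  thresholds calibrated on shuffled decoys, and split-frame merging that
  recovers genes broken by homopolymer frameshifts.
* **Activity** — per-gene RNA read density `c_g/L_g` normalized by the mean
  density of the gene's bin, so mean activity per bin is exactly 1.
* **Guilds** — a bin is a denitrifier if any of nirS/nirK/nosZ is present,
  fermentative if pflB is present, `both` if both; guild abundances are
  aggregated per sample.
* **Mass balance** — feed C:N ratio `C/(NO₂⁻+NO₃⁻)`; assimilated nitrogen
  `N_org,in − NH₄⁺_out`; protein prediction via standard biomass
  CH₁.₈O₀.₅N₀.₂ (N:C = 0.2, 24.6 g/C-mol, protein share 0.47 g/g); growth
  yield in C-mol assimilated per C-mol converted; OLS batch rates with 95%
  confidence intervals in mM/h and µmol L⁻¹ day⁻¹.

## Worked example

Chemostat stoichiometry of a cold (10 °C) culture fed 37.5 mM-C organic
carbon against 20 mM nitrite + 1 mM nitrate, with 5.3 mM-N organic nitrogen
in and 2.5 mM ammonium out:

```r
library(chemoguild)

cn_ratio(list(influent_organic_carbon = 37.5,
              influent_nitrite = 20, influent_nitrate = 1))
#> [1] 1.785714        # ~1.8 C-mol/N-mol

protein_from_nitrogen(nitrogen_balance(
  list(influent_organic_n = 5.3, effluent_ammonium = 2.5)))
#> [1] 0.1618680       # predicted protein, g/L (2.8 mM-N assimilated)

growth_yield(0.14, 28)
#> [1] 0.4324583       # C-mol assimilated per C-mol converted

medium_recipe(28)
#>    glucose    acetate aminoacids
#>      12.32       2.24      13.44   # mM-C

b <- simulate_batch(-0.25, n_samples = 7, c0 = 1.0, noise_sd = 0.05, seed = 42)
batch_rate(b)
#> Batch rate: -0.2426 mM/h (SE 0.0229, 95% CI [-0.3014, -0.1838])
#>   = -5822.6 umol L^-1 day^-1
```

The predicted protein (0.16 g/L against ~0.12–0.15 measured in such
cultures) says most missing organic nitrogen is in biomass; a yield of
~0.43 means roughly 0.4 C-mol of substrate carbon ends up in cells per
C-mol consumed — at the upper edge of what model denitrifiers achieve on
acetate (~0.3), as expected with sugars and amino acids in the feed.

The full sequencing pipeline on a packaged 5-population synthetic
community:

```r
res <- run_pipeline(default_config(seed = 11), out_dir = "demo_out")
res$bin_stats
#>      bin size_bp n_contigs n50_bp gc_percent mean_coverage cscg_count trna_count
#> 1 bin_01   60000         9   7140         33     24.962417         25         45
#> 2 bin_02   60000         7  10055         41     12.593083         25         35
#> 3 bin_03   60000         8   7661         49      6.262467         25         28
#> 4 bin_04   60000         9   7294         56      3.250617         25         20
#> 5 bin_05   60000         9   6460         63      1.571617         25         13
res$guild_abundance
#>      sample        label  abundance
#> 1 sample_01         both 0.12875084
#> 2 sample_01  denitrifier 0.80441932
#> 3 sample_01 fermentative 0.06682984
```

Five bins are recovered (one per planted population, GC 33–63%, coverage
tracking the log-spread abundances), each with its 25 planted single-copy
markers and tRNAs, and the guild masses match the planted gene layout.
`demo_out/` holds `bins.tsv`, `bin_stats.tsv`, `blobs.tsv`,
`coverage.tsv`, `abundance.tsv`, `gene_hits.tsv`, `activity.tsv`,
`guilds.tsv`, `guild_abundance.tsv`, `mass_balance.csv` and a
`manifest.json` recording the seed and every parameter. A thin command-line
wrapper is installed at `inst/scripts/chemoguild-pipeline.R`.

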