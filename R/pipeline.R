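# End-to-end orchestration: simulate (or load) a community, bin contigs,
# estimate coverage/abundance, run the marker census, detect functional
# genes, compute transcriptional activities, classify guilds and balance the
# chemostat - with one config, one seed, and TSV/JSON outputs.

#' Default pipeline configuration
#'
#' A flat, documented list of every stage parameter.  Flags of the
#' command-line wrapper and arguments of [run_pipeline()] override these.
#'
#' @param seed Integer master seed recorded in the manifest and used by
#'   every stochastic stage.
#' @return A named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # synthetic community
    n_populations = 5L,
    genome_length = 60000L,
    n_dna_reads = 20000L,
    n_rna_reads = 20000L,
    read_length_mean = 150,
    read_length_sd = 25,
    error_rate = 0.01,
    homopolymer_indel_rate = 0,
    # fragmentation ("assembly")
    n50_target = 8000L,
    fragment_min_len = 1000L,
    # binning
    min_contig_len = 1000L,
    n_components = 5L,
    k_bins = NULL, # NULL = silhouette auto-selection
    fragment_length = 500L, # bin-profile diagnostics
    # mapping
    k = 21L,
    min_identity = 0.9,
    # gene detection
    families = c("nirS", "nirK", "nosZ", "pflB"),
    min_score = NULL, # NULL = calibrated per-family thresholds
    # activity
    expressed_only = FALSE,
    skip_rna = FALSE,
    # chemostat mass balance
    influent_nitrite = 20,
    influent_nitrate = 1,
    influent_organic_carbon = 28,
    influent_organic_n = 5.3,
    dilution_rate = 0.36,
    temperature = 25,
    true_yield = 0.4,
    chemostat_noise_sd = 0.05,
    # biomass model
    n_to_c = 0.2,
    formula_mass = 24.6,
    protein_fraction = 0.47
  )
}

pipeline_stage <- function(name, code) {
  message("[chemoguild] stage: ", name)
  tryCatch(force(code), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic community
#'
#' Generates a community from the config, fragments genomes into contigs,
#' simulates and maps DNA reads, bins contigs, estimates abundances, runs
#' the marker/tRNA census, scans for functional genes, computes
#' transcriptional activities from simulated RNA reads (unless `skip_rna`),
#' classifies guilds, aggregates guild abundances, and balances a simulated
#' chemostat.  With `out_dir` set, writes `bins.tsv`, `bin_stats.tsv`,
#' `blobs.tsv`, `coverage.tsv`, `abundance.tsv`, `gene_hits.tsv`,
#' `activity.tsv`, `guilds.tsv`, `guild_abundance.tsv`, `mass_balance.csv`
#' and a `manifest.json` with package version, seed and all parameters.
#' Outputs are byte-identical across reruns with the same config.
#'
#' @param config List from [default_config()] (entries may be overridden).
#' @param out_dir Optional output directory (created if missing).
#' @param community Optional pre-built [community_spec()]; by default one is
#'   constructed from the config via [default_community()].
#' @return Invisibly, a list with all intermediate and final tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         community = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(community)) {
    community <- default_community(
      seed = cfg$seed, genome_length = cfg$genome_length,
      n_dna_reads = cfg$n_dna_reads, n_rna_reads = cfg$n_rna_reads,
      read_length_mean = cfg$read_length_mean,
      read_length_sd = cfg$read_length_sd,
      error_rate = cfg$error_rate,
      homopolymer_indel_rate = cfg$homopolymer_indel_rate
    )
  }

  comm <- pipeline_stage("simulate community", generate_community(community))
  frag <- pipeline_stage(
    "fragment genomes",
    fragment_genomes(comm$genomes, cfg$n50_target, cfg$fragment_min_len,
      seed = cfg$seed, genes = comm$genes
    )
  )
  dna <- pipeline_stage(
    "simulate DNA reads",
    simulate_reads(comm$genomes, comm$abundances, community)
  )
  asg <- pipeline_stage(
    "map DNA reads",
    assign_reads(dna$reads, frag$contigs, k = cfg$k,
      min_identity = cfg$min_identity
    )
  )
  lens <- nchar(frag$contigs)
  cov <- pipeline_stage("coverage", contig_coverage(asg, lens))
  bins <- pipeline_stage(
    "bin contigs",
    cluster_contigs(frag$contigs, cov,
      min_contig_len = cfg$min_contig_len,
      n_components = cfg$n_components, k = cfg$k_bins
    )
  )
  abund <- pipeline_stage(
    "bin abundance",
    bin_abundance(cov, bins, lens)
  )
  cen <- pipeline_stage("marker census", census(frag$genes, bins))
  stats <- pipeline_stage(
    "bin statistics",
    bin_stats(bins, frag$contigs, cov, census = cen)
  )
  blobs <- blob_table(bins, frag$contigs, cov)
  profiles <- pipeline_stage("build profiles", {
    aln <- read_seed_alignments()
    lapply(cfg$families, function(f) build_profile(aln[[f]], family = f))
  })
  hits <- pipeline_stage(
    "detect functional genes",
    scan_profiles(profiles, frag$contigs, min_score = cfg$min_score)
  )
  hits$bin <- bins$bin[match(hits$contig, bins$contig)]

  activity <- NULL
  if (!cfg$skip_rna) {
    rna <- pipeline_stage(
      "simulate RNA reads",
      simulate_transcriptome(comm$genomes, comm$genes, community)
    )
    rasg <- pipeline_stage(
      "map RNA reads",
      assign_reads(rna$reads, frag$contigs, k = cfg$k,
        min_identity = cfg$min_identity
      )
    )
    counts <- pipeline_stage("count RNA per gene", count_rna(rasg, frag$genes))
    gene_len <- setNames(
      frag$genes$end - frag$genes$start + 1L, frag$genes$gene_id
    )
    bin_of_gene <- setNames(
      bins$bin[match(frag$genes$contig, bins$contig)], frag$genes$gene_id
    )
    keep <- !is.na(bin_of_gene) & bin_of_gene != "unbinned"
    activity <- pipeline_stage(
      "normalize activity",
      normalize_activity(
        counts$counts[counts$counts$gene_id %in% names(bin_of_gene)[keep], ],
        gene_len, bin_of_gene,
        expressed_only = cfg$expressed_only
      )
    )
    # attach activities of the planted functional genes to the gene hits
    fg <- frag$genes[frag$genes$class == "functional", , drop = FALSE]
    fg$activity <- activity$activity[match(fg$gene_id, activity$gene_id)]
    key_hit <- paste(hits$contig, hits$family)
    key_fg <- paste(fg$contig, fg$family)
    hits$activity <- fg$activity[match(key_hit, key_fg)]
  } else {
    hits$activity <- NA_real_
  }

  guilds <- pipeline_stage(
    "classify guilds",
    classify_bins(hits, bins = setdiff(unique(bins$bin), "unbinned"))
  )
  guild_ab <- pipeline_stage(
    "aggregate guild abundance",
    suppressWarnings(aggregate_guilds(guilds, abund))
  )
  scenario <- chemostat_scenario(
    influent_nitrite = cfg$influent_nitrite,
    influent_nitrate = cfg$influent_nitrate,
    influent_organic_carbon = cfg$influent_organic_carbon,
    influent_organic_n = cfg$influent_organic_n,
    dilution_rate = cfg$dilution_rate, temperature = cfg$temperature,
    true_yield = cfg$true_yield, noise_sd = cfg$chemostat_noise_sd,
    seed = cfg$seed
  )
  model <- biomass_model(cfg$n_to_c, cfg$formula_mass, cfg$protein_fraction)
  state <- pipeline_stage("simulate chemostat", simulate_chemostat(scenario, model))
  balance <- pipeline_stage("mass balance", mass_balance(state, model))

  result <- list(
    config = cfg, community = comm, fragments = frag, dna_truth = dna$truth,
    assignments = asg, coverage = cov, bins = bins, abundance = abund,
    census = cen, bin_stats = stats, blobs = blobs, gene_hits = hits,
    activity = activity, guilds = guilds, guild_abundance = guild_ab,
    chemostat = state, mass_balance = balance
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  invisible(result)
}

# write the report bundle; every table carries a comment header naming units
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name, header) {
    path <- file.path(out_dir, name)
    writeLines(paste0("# ", header), path)
    suppressWarnings(write.table(x, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, append = TRUE
    ))
  }
  wt(result$bins, "bins.tsv", "contig-to-bin assignment; lengths in bp")
  wt(
    result$bin_stats, "bin_stats.tsv",
    "per-bin statistics; size/N50 in bp, GC in percent, coverage in fold"
  )
  wt(result$blobs, "blobs.tsv", "per-contig GC (%) vs coverage (fold)")
  cov <- data.frame(
    contig = names(result$coverage),
    coverage = unname(result$coverage)
  )
  wt(cov, "coverage.tsv", "mean per-contig coverage (assigned bases / bp)")
  wt(result$abundance, "abundance.tsv", "per-bin relative abundance (fraction)")
  wt(
    result$gene_hits, "gene_hits.tsv",
    "functional gene hits; 1-based inclusive bp coordinates; scores in bits"
  )
  if (!is.null(result$activity)) {
    wt(
      result$activity, "activity.tsv",
      "per-gene activity; density = reads/bp; bin mean activity = 1"
    )
  }
  wt(result$guilds, "guilds.tsv", "per-bin guild classification")
  wt(
    result$guild_abundance, "guild_abundance.tsv",
    "per-sample guild abundance (fraction)"
  )
  mb <- result$mass_balance
  utils::write.csv(
    data.frame(
      quantity = c(
        "cn_ratio_cmol_per_nmol", "assimilated_n_mM",
        "predicted_protein_g_per_l", "measured_protein_g_per_l",
        "yield_cmol_per_cmol"
      ),
      value = c(
        mb$cn_ratio, mb$assimilated_n, mb$predicted_protein,
        mb$measured_protein, mb$yield
      )
    ),
    file.path(out_dir, "mass_balance.csv"),
    row.names = FALSE
  )
  manifest <- list(
    package = "chemoguild",
    version = as.character(utils::packageVersion("chemoguild")),
    seed = result$config$seed,
    parameters = result$config[order(names(result$config))]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(out_dir)
}
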