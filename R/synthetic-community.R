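# Synthetic community generator.
#
# Emulates the statistical structure the downstream stages assume: a small
# (5-15) population community with distinct GC and tetranucleotide
# signatures, log-spread abundances, and planted single-copy marker genes,
# tRNA genes, functional genes (nirS/nirK/nosZ/pflB) and background genes
# with per-gene expression levels.

BASES <- c("A", "C", "G", "T")

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Describe one population of a synthetic community
#'
#' @param id Population label (used as a prefix for contig and gene ids).
#' @param genome_length Genome length in bp.
#' @param gc Target GC content as a fraction in (0, 1); the generated genome
#'   matches it to well within 1 percentage point (absolute).
#' @param signature_seed Integer seed controlling the population-specific
#'   tetranucleotide bias (an order-3 Markov transition tilt).  Populations
#'   with different `signature_seed` acquire distinct 4-mer signatures even
#'   at identical GC.
#' @param abundance Relative abundance (cell fraction); the community-wide
#'   abundances must sum to 1.
#' @param marker_families Character vector of conserved single-copy marker
#'   families to plant (a subset of [marker_catalogue()]).
#' @param trna_count Number of tRNA genes to plant.
#' @param functional_genes A data.frame with columns `family` (one of
#'   `"nirS"`, `"nirK"`, `"nosZ"`, `"pflB"`) and `expression` (>= 0), or
#'   `NULL` for none.
#' @param background_gene_count Number of unlabelled background genes to
#'   plant; their expression levels are drawn log-normally.
#' @param divergence Amino-acid substitution fraction applied to the seed
#'   alignment consensus when planting functional genes (default 0.10, so
#'   detection is nontrivial but achievable).
#' @return A `population_spec` list.
#' @export
population_spec <- function(id, genome_length = 80000L, gc = 0.5,
                            signature_seed = 1L, abundance = NA_real_,
                            marker_families = character(),
                            trna_count = 20L,
                            functional_genes = NULL,
                            background_gene_count = 15L,
                            divergence = 0.10) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0)
  stopifnot(genome_length >= 1000, gc > 0, gc < 1)
  stopifnot(trna_count >= 0, background_gene_count >= 0)
  stopifnot(divergence >= 0, divergence < 1)
  if (!is.null(functional_genes)) {
    stopifnot(
      is.data.frame(functional_genes),
      all(c("family", "expression") %in% names(functional_genes)),
      all(functional_genes$expression >= 0)
    )
  }
  structure(
    list(
      id = id, genome_length = as.integer(genome_length), gc = gc,
      signature_seed = as.integer(signature_seed), abundance = abundance,
      marker_families = marker_families, trna_count = as.integer(trna_count),
      functional_genes = functional_genes,
      background_gene_count = as.integer(background_gene_count),
      divergence = divergence
    ),
    class = "population_spec"
  )
}

#' Describe a synthetic community and its sequencing experiment
#'
#' @param populations List of [population_spec()] objects; their abundances
#'   must be positive and sum to 1 (within 1e-9).
#' @param n_dna_reads,n_rna_reads Numbers of DNA (metagenome) and RNA
#'   (metatranscriptome) reads to simulate.
#' @param read_length_mean,read_length_sd Read length distribution in bp
#'   (normal, truncated below at 50 bp).
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param homopolymer_indel_rate Per-homopolymer probability of a +/-1 bp
#'   indel (emulating difficulties of some sequencing chemistries with
#'   mononucleotide runs); 0 disables, the default.
#' @param seed Integer seed; every generator output is byte-identical for a
#'   fixed spec and seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(populations, n_dna_reads = 20000L,
                           n_rna_reads = 20000L, read_length_mean = 150,
                           read_length_sd = 25, error_rate = 0.01,
                           homopolymer_indel_rate = 0, seed = 1L) {
  stopifnot(length(populations) >= 1)
  stopifnot(all(vapply(populations, inherits, logical(1), "population_spec")))
  ab <- vapply(populations, `[[`, numeric(1), "abundance")
  if (anyNA(ab) || any(ab <= 0)) {
    stop("population abundances must be positive")
  }
  if (abs(sum(ab) - 1) > 1e-9) {
    stop("population abundances must sum to 1 (within 1e-9)")
  }
  ids <- vapply(populations, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("population ids must be unique")
  stopifnot(
    n_dna_reads >= 0, n_rna_reads >= 0,
    error_rate >= 0, error_rate <= 1,
    homopolymer_indel_rate >= 0, homopolymer_indel_rate <= 1,
    read_length_mean >= 50
  )
  structure(
    list(
      populations = populations,
      n_dna_reads = as.integer(n_dna_reads),
      n_rna_reads = as.integer(n_rna_reads),
      read_length_mean = read_length_mean, read_length_sd = read_length_sd,
      error_rate = error_rate,
      homopolymer_indel_rate = homopolymer_indel_rate,
      seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

#' A ready-made small community covering all guild patterns
#'
#' Five populations with GC from 33 to 63% (pairwise gaps >= 7 points),
#' distinct signature seeds, log-spread abundances, planted markers, tRNAs,
#' and functional genes arranged so the community contains denitrifier-only,
#' fermentative-only and combined populations.
#'
#' @param seed Integer seed for the whole community.
#' @param genome_length Genome length per population (bp).
#' @param n_dna_reads,n_rna_reads Read counts, passed to [community_spec()].
#' @param ... Further arguments passed to [community_spec()].
#' @return A `community_spec`.
#' @export
default_community <- function(seed = 1L, genome_length = 60000L,
                              n_dna_reads = 20000L, n_rna_reads = 20000L,
                              ...) {
  gcs <- c(0.33, 0.41, 0.49, 0.56, 0.63)
  # log-spread abundances, most abundant first
  ab <- 2^-(0:4)
  ab <- ab / sum(ab)
  cat139 <- marker_catalogue()
  fams <- list(
    data.frame(family = c("nirS", "nosZ"), expression = c(4, 8)),
    data.frame(family = "nirK", expression = 2),
    data.frame(family = c("nosZ", "pflB"), expression = c(3, 6)),
    data.frame(family = "pflB", expression = 10),
    data.frame(family = "nosZ", expression = 1.5)
  )
  pops <- lapply(1:5, function(i) {
    population_spec(
      id = sprintf("pop%02d", i),
      genome_length = genome_length,
      gc = gcs[i],
      signature_seed = 100L + i,
      abundance = ab[i],
      marker_families = cat139[seq.int(1L + (i - 1L) * 5L, length.out = 25L)],
      trna_count = c(45L, 35L, 28L, 20L, 13L)[i],
      functional_genes = fams[[i]],
      background_gene_count = 15L
    )
  })
  community_spec(pops,
    n_dna_reads = n_dna_reads, n_rna_reads = n_rna_reads,
    seed = seed, ...
  )
}

# order-3 Markov transition matrix (64 contexts x 4 bases) for a population
markov_transitions <- function(gc, signature_seed, sigma = 0.45) {
  pref <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  z <- with_seed(signature_seed, matrix(rnorm(256), nrow = 64, ncol = 4))
  w <- sweep(exp(sigma * z), 2, pref, `*`)
  w / rowSums(w)
}

# sample a genome as an integer vector (1=A, 2=C, 3=G, 4=T); consumes RNG
markov_genome_ints <- function(n, trans) {
  cum1 <- trans[, 1]
  cum2 <- trans[, 1] + trans[, 2]
  cum3 <- cum1 + trans[, 2] + trans[, 3]
  out <- integer(n)
  pref <- colMeans(trans)
  out[1:3] <- sample.int(4L, 3L, replace = TRUE, prob = pref)
  ctx <- (out[1] - 1L) * 16L + (out[2] - 1L) * 4L + (out[3] - 1L)
  u <- runif(n)
  for (i in 4:n) {
    j <- ctx + 1L
    b <- 1L + (u[i] > cum1[j]) + (u[i] > cum2[j]) + (u[i] > cum3[j])
    out[i] <- b
    ctx <- (ctx %% 16L) * 4L + (b - 1L)
  }
  out
}

# place nf features of given lengths without overlap; returns start positions
place_features <- function(genome_length, lengths, max_tries = 2000L) {
  if (length(lengths) == 0) return(integer(0))
  if (sum(lengths) + length(lengths) >= genome_length) {
    stop("genome_length too small for the requested planted genes")
  }
  ord <- order(lengths, decreasing = TRUE)
  placed_start <- integer(0)
  placed_end <- integer(0)
  starts <- integer(length(lengths))
  for (i in ord) {
    len <- lengths[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(genome_length - len + 1L, 1L)
      e <- s + len - 1L
      if (!any(s <= placed_end & e >= placed_start)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place planted genes without overlap; genome too crowded")
    starts[i] <- s
    placed_start <- c(placed_start, s)
    placed_end <- c(placed_end, e)
  }
  starts
}

# reverse-translate a peptide with codon choice tilted toward the target GC;
# consumes RNG
reverse_translate <- function(peptide, gc) {
  code <- Biostrings::getGeneticCode("11")
  aa2codons <- split(names(code), code)
  pref <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codon_w <- vapply(names(code), function(cd) {
    prod(pref[strsplit(cd, "")[[1]]])
  }, numeric(1))
  aas <- strsplit(peptide, "")[[1]]
  codons <- vapply(aas, function(a) {
    cds <- aa2codons[[a]]
    if (is.null(cds)) stop("cannot reverse-translate residue: ", a)
    if (length(cds) == 1L) return(cds)
    sample(cds, 1L, prob = codon_w[cds])
  }, character(1))
  paste(codons, collapse = "")
}

# substitute a fraction of residues with random other residues; consumes RNG
diverge_peptide <- function(peptide, divergence) {
  aas <- strsplit(peptide, "")[[1]]
  n_sub <- round(divergence * length(aas))
  if (n_sub > 0) {
    pos <- sample.int(length(aas), n_sub)
    aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (p in pos) {
      aas[p] <- sample(setdiff(aa20, aas[p]), 1L)
    }
  }
  paste(aas, collapse = "")
}

#' Generate a synthetic community
#'
#' Builds one genome per population from a seeded order-3 Markov chain (the
#' source of the population-specific tetranucleotide signature), plants the
#' requested marker, tRNA, functional and background genes at non-overlapping
#' positions, and corrects the background sequence so the realized GC matches
#' the requested GC to within 1 percentage point (absolute).  Marker, tRNA
#' and background genes are annotation-only features; functional genes carry
#' a real protein-coding sequence derived from the packaged seed-alignment
#' consensus with the requested amino-acid divergence, so profile scanning
#' has something genuine to find.
#'
#' @param spec A [community_spec()].
#' @param seed_alignments Named list of seed alignments as returned by
#'   [read_seed_alignments()]; defaults to the packaged synthetic set.
#' @return A list with elements:
#'   * `genomes`: named character vector of genome sequences;
#'   * `genes`: truth table with columns `population`, `gene_id`, `class`,
#'     `family`, `start`, `end` (1-based inclusive genome coordinates),
#'     `strand`, `expression`;
#'   * `abundances`: data.frame with `population`, `abundance` (cell
#'     fraction), `genome_length` and `dna_fraction` (abundance x length,
#'     normalized -- the fraction of sequenced DNA each population
#'     contributes, which is what read mapping estimates).
#' @export
generate_community <- function(spec, seed_alignments = read_seed_alignments()) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    genomes <- character(0)
    gene_rows <- list()
    for (pop in spec$populations) {
      trans <- markov_transitions(pop$gc, pop$signature_seed)
      ints <- markov_genome_ints(pop$genome_length, trans)

      # assemble the feature roster
      fam <- pop$functional_genes
      n_fun <- if (is.null(fam)) 0L else nrow(fam)
      fun_pep <- character(n_fun)
      fun_len <- integer(n_fun)
      if (n_fun > 0) {
        for (j in seq_len(n_fun)) {
          aln <- seed_alignments[[fam$family[j]]]
          if (is.null(aln)) stop("no seed alignment for family ", fam$family[j])
          cons <- consensus_sequence(aln)
          fun_pep[j] <- diverge_peptide(cons, pop$divergence)
          fun_len[j] <- 3L * nchar(fun_pep[j])
        }
      }
      n_marker <- length(pop$marker_families)
      n_trna <- pop$trna_count
      n_bg <- pop$background_gene_count
      lengths <- c(
        fun_len,
        rep(450L, n_marker),
        rep(76L, n_trna),
        if (n_bg > 0) sample(600:1500, n_bg, replace = TRUE) else integer(0)
      )
      classes <- c(
        rep("functional", n_fun), rep("marker", n_marker),
        rep("trna", n_trna), rep("background", n_bg)
      )
      families <- c(
        if (n_fun > 0) fam$family else character(0),
        pop$marker_families,
        rep(NA_character_, n_trna + n_bg)
      )
      expr <- c(
        if (n_fun > 0) fam$expression else numeric(0),
        rep(NA_real_, n_marker), rep(NA_real_, n_trna),
        if (n_bg > 0) round(exp(rnorm(n_bg, 0, 1)), 4) else numeric(0)
      )
      starts <- place_features(pop$genome_length, lengths)
      strands <- sample(c("+", "-"), length(lengths), replace = TRUE)

      # write functional gene sequences into the genome
      if (n_fun > 0) {
        for (j in seq_len(n_fun)) {
          dna <- reverse_translate(fun_pep[j], pop$gc)
          if (strands[j] == "-") dna <- revcomp(dna)
          ints[starts[j]:(starts[j] + fun_len[j] - 1L)] <-
            match(strsplit(dna, "")[[1]], BASES)
        }
      }

      # correct GC outside functional genes to hit the target exactly
      lock <- rep(FALSE, pop$genome_length)
      if (n_fun > 0) {
        for (j in seq_len(n_fun)) {
          lock[starts[j]:(starts[j] + fun_len[j] - 1L)] <- TRUE
        }
      }
      target <- round(pop$gc * pop$genome_length)
      isgc <- ints == 2L | ints == 3L
      diff <- target - sum(isgc)
      if (diff > 0) {
        cand <- which(!isgc & !lock)
        flip <- sample(cand, min(diff, length(cand)))
        ints[flip] <- sample(c(2L, 3L), length(flip), replace = TRUE)
      } else if (diff < 0) {
        cand <- which(isgc & !lock)
        flip <- sample(cand, min(-diff, length(cand)))
        ints[flip] <- sample(c(1L, 4L), length(flip), replace = TRUE)
      }

      genomes[pop$id] <- paste(BASES[ints], collapse = "")
      if (length(classes) == 0) next
      idx_by_class <- stats::ave(seq_along(classes), classes, FUN = seq_along)
      gene_rows[[pop$id]] <- data.frame(
        population = rep(pop$id, length(classes)),
        gene_id = sprintf("%s_%s_%03d", pop$id, classes, idx_by_class),
        class = classes,
        family = families,
        start = starts,
        end = starts + lengths - 1L,
        strand = strands,
        expression = expr,
        stringsAsFactors = FALSE
      )
    }
    ab <- vapply(spec$populations, `[[`, numeric(1), "abundance")
    len <- vapply(spec$populations, `[[`, integer(1), "genome_length")
    ids <- vapply(spec$populations, `[[`, character(1), "id")
    dnafrac <- ab * len / sum(ab * len)
    genes <- if (length(gene_rows) > 0) {
      do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(
        population = character(0), gene_id = character(0),
        class = character(0), family = character(0), start = integer(0),
        end = integer(0), strand = character(0), expression = numeric(0),
        stringsAsFactors = FALSE
      )
    }
    list(
      genomes = genomes,
      genes = genes,
      abundances = data.frame(
        population = ids, abundance = ab, genome_length = len,
        dna_fraction = dnafrac, stringsAsFactors = FALSE
      )
    )
  })
}

#' Introduce homopolymer indels into sequences
#'
#' Each homopolymer run of at least `min_run` bases receives, with
#' probability `rate`, a one-base insertion (run extended) or deletion (run
#' shortened), emulating the mononucleotide-run errors of some sequencing
#' chemistries that show up as artefactual frameshifts in genes.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param rate Per-homopolymer indel probability.
#' @param seed Integer seed.
#' @param min_run Minimum run length considered a homopolymer (default 3).
#' @return A list with `seqs` (mutated sequences) and `n_indels` (count per
#'   sequence).
#' @export
introduce_homopolymer_indels <- function(seqs, rate, seed = 1L, min_run = 3L) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    n_ind <- integer(length(seqs))
    out <- seqs
    for (i in seq_along(seqs)) {
      chars <- strsplit(seqs[[i]], "")[[1]]
      r <- rle(chars)
      runs <- which(r$lengths >= min_run)
      if (length(runs) == 0) next
      hit <- runs[runif(length(runs)) < rate]
      if (length(hit) == 0) next
      ins <- runif(length(hit)) < 0.5
      r$lengths[hit] <- r$lengths[hit] + ifelse(ins, 1L, -1L)
      out[[i]] <- paste(inverse.rle(r), collapse = "")
      n_ind[i] <- length(hit)
    }
    list(seqs = out, n_indels = n_ind)
  })
}
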