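# Seeded read simulators for DNA (metagenome) and RNA (metatranscriptome)
# libraries.  Single-end reads, substitution errors at a uniform per-base
# rate, optional homopolymer indels, Sanger-offset qualities.

# draw read lengths; normal, truncated to [50, max_len]
draw_read_lengths <- function(n, mean, sd, max_len) {
  len <- round(rnorm(n, mean, sd))
  pmin(pmax(len, 50L), max_len)
}

# apply substitution errors at a uniform rate to a character vector of reads
apply_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  conc <- paste(reads, collapse = "")
  raw <- charToRaw(conc)
  hit <- which(runif(length(raw)) < error_rate)
  if (length(hit) > 0) {
    base_raw <- charToRaw("ACGT")
    cur <- raw[hit]
    # substitute with one of the three other bases, uniformly
    repl <- vapply(seq_along(hit), function(i) {
      sample(base_raw[base_raw != cur[i]], 1L)
    }, raw(1))
    raw[hit] <- repl
  }
  conc <- rawToChar(raw)
  ends <- cumsum(nchar(reads))
  starts <- c(1L, head(ends, -1L) + 1L)
  substring(conc, starts, ends)
}

quality_string <- function(lens, error_rate) {
  q <- if (error_rate > 0) round(-10 * log10(error_rate)) else 40L
  q <- min(max(q, 2L), 40L)
  ch <- rawToChar(as.raw(33L + q))
  vapply(lens, function(l) strrep(ch, l), character(1))
}

#' Simulate a metagenomic (DNA) read set
#'
#' Reads are drawn from population `p` with probability proportional to
#' `abundance_p x genome_length_p` (the DNA mass each population
#' contributes), from uniform positions and random strands, with normal
#' lengths, uniform substitution errors and optional homopolymer indels.
#'
#' @param genomes Named character vector of genome (or contig) sequences.
#' @param abundances data.frame with columns `population` (matching
#'   `names(genomes)`) and `abundance`, summing to 1; typically the
#'   `abundances` element of [generate_community()].
#' @param spec A [community_spec()] providing read number, length
#'   distribution, error rates and the seed.
#' @return A list with `reads` (named character vector), `quals` (matching
#'   Phred+33 quality strings) and `truth` (data.frame `read_id`,
#'   `population`, `start`, `end`, `strand` in genome coordinates).
#' @export
simulate_reads <- function(genomes, abundances, spec) {
  stopifnot(inherits(spec, "community_spec"))
  stopifnot(all(abundances$population %in% names(genomes)))
  if (abs(sum(abundances$abundance) - 1) > 1e-9) {
    stop("abundances must sum to 1")
  }
  glen <- nchar(genomes)[abundances$population]
  w <- abundances$abundance * glen
  with_seed(spec$seed + 1L, {
    n <- spec$n_dna_reads
    pop <- sample(abundances$population, n, replace = TRUE, prob = w / sum(w))
    lens <- draw_read_lengths(
      n, spec$read_length_mean, spec$read_length_sd,
      max_len = min(glen)
    )
    start <- integer(n)
    for (p in unique(pop)) {
      i <- pop == p
      start[i] <- floor(runif(sum(i), 1, nchar(genomes[[p]]) - lens[i] + 1 + 1))
    }
    end <- start + lens - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- substring(genomes[pop], start, end)
    minus <- strand == "-"
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    reads <- apply_substitutions(reads, spec$error_rate)
    if (spec$homopolymer_indel_rate > 0) {
      hp <- introduce_homopolymer_indels(reads, spec$homopolymer_indel_rate,
        seed = spec$seed + 7L
      )
      reads <- hp$seqs
    }
    ids <- sprintf("read%06d", seq_len(n))
    names(reads) <- ids
    list(
      reads = reads,
      quals = setNames(quality_string(nchar(reads), spec$error_rate), ids),
      truth = data.frame(
        read_id = ids, population = pop, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate a metatranscriptomic (RNA) read set
#'
#' Reads are drawn from gene `g` with probability proportional to
#' `expression_g x gene_length_g`; genes with `NA` or zero expression are
#' never sampled.  Read positions are uniform within the gene (read length
#' truncated to the gene length) and read strand is random (unstranded
#' library).
#'
#' @param genomes Named character vector of genome sequences.
#' @param genes Gene truth table in genome coordinates
#'   ([generate_community()] `genes` element).
#' @param spec A [community_spec()].
#' @return As [simulate_reads()], with `truth` columns `read_id`, `gene_id`,
#'   `population`.
#' @export
simulate_transcriptome <- function(genomes, genes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  expressed <- genes[!is.na(genes$expression) & genes$expression > 0, ,
    drop = FALSE
  ]
  if (nrow(expressed) == 0 || sum(expressed$expression) == 0) {
    warning("zero total expression; returning empty read set")
    return(list(
      reads = character(0), quals = character(0),
      truth = data.frame(
        read_id = character(0), gene_id = character(0),
        population = character(0), stringsAsFactors = FALSE
      )
    ))
  }
  glens <- expressed$end - expressed$start + 1L
  w <- expressed$expression * glens
  with_seed(spec$seed + 2L, {
    n <- spec$n_rna_reads
    gi <- sample.int(nrow(expressed), n, replace = TRUE, prob = w / sum(w))
    lens <- pmin(
      draw_read_lengths(n, spec$read_length_mean, spec$read_length_sd,
        max_len = max(glens)
      ),
      glens[gi]
    )
    off <- floor(runif(n, 0, glens[gi] - lens + 1))
    gstart <- expressed$start[gi] + off
    reads <- substring(genomes[expressed$population[gi]], gstart, gstart + lens - 1L)
    # unstranded library: half the reads come out reverse-complemented
    minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    reads <- apply_substitutions(reads, spec$error_rate)
    if (spec$homopolymer_indel_rate > 0) {
      hp <- introduce_homopolymer_indels(reads, spec$homopolymer_indel_rate,
        seed = spec$seed + 8L
      )
      reads <- hp$seqs
    }
    ids <- sprintf("rna%06d", seq_len(n))
    names(reads) <- ids
    list(
      reads = reads,
      quals = setNames(quality_string(nchar(reads), spec$error_rate), ids),
      truth = data.frame(
        read_id = ids, gene_id = expressed$gene_id[gi],
        population = expressed$population[gi], stringsAsFactors = FALSE
      )
    )
  })
}
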