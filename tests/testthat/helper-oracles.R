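# Independent brute-force oracles and small fixture builders shared across
# the test files.

# N50 by definition: the largest member length L such that contigs of at
# least L together hold half the total
brute_force_n50 <- function(lengths) {
  tot <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  }
  min(lengths)
}

# exhaustive read placement over all positions and strands with the same
# scoring and tie-break rules as assign_reads()
brute_force_assign <- function(reads, contigs, min_identity = 0.9) {
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  rows <- lapply(names(reads), function(rid) {
    rd <- reads[[rid]]
    len <- nchar(rd)
    best <- NULL
    for (cid in sort(names(contigs))) {
      ctg <- contigs[[cid]]
      if (nchar(ctg) < len) next
      for (strand in c("+", "-")) {
        q <- if (strand == "+") rd else rc(rd)
        for (s in seq_len(nchar(ctg) - len + 1L)) {
          sub <- substr(ctg, s, s + len - 1L)
          matched <- sum(strsplit(q, "")[[1]] == strsplit(sub, "")[[1]])
          if (matched < ceiling(min_identity * len)) next
          cand <- list(
            contig = cid, position = s, strand = strand, matched = matched
          )
          if (is.null(best) ||
            matched > best$matched ||
            (matched == best$matched && cid < best$contig) ||
            (matched == best$matched && cid == best$contig &&
              strand == "+" && best$strand == "-") ||
            (matched == best$matched && cid == best$contig &&
              strand == best$strand && s < best$position)) {
            best <- cand
          }
        }
      }
    }
    if (is.null(best)) {
      data.frame(
        read_id = rid, contig = NA_character_, position = NA_integer_,
        strand = NA_character_, matched_bases = NA_integer_,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        read_id = rid, contig = best$contig, position = best$position,
        strand = best$strand, matched_bases = best$matched,
        stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, rows)
}

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(
    sample(c("A", "C", "G", "T"), n,
      replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ),
    collapse = ""
  )
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic reverse translation (first codon of each residue)
peptide_to_dna <- function(peptide) {
  code <- Biostrings::getGeneticCode("11")
  aas <- strsplit(peptide, "")[[1]]
  paste(vapply(aas, function(a) names(code)[code == a][1], ""), collapse = "")
}

# a small 3-population community with well-separated GC and coverage
three_pop_spec <- function(seed = 1L, genome_length = 30000L,
                           n_dna_reads = 6000L, n_rna_reads = 6000L, ...) {
  gcs <- c(0.35, 0.50, 0.62)
  ab <- c(5, 20, 80)
  ab <- ab / sum(ab)
  pops <- lapply(1:3, function(i) {
    population_spec(
      id = sprintf("pop%02d", i), genome_length = genome_length,
      gc = gcs[i], signature_seed = 200L + i, abundance = ab[i],
      marker_families = marker_catalogue()[seq.int(1 + (i - 1) * 10, length.out = 10)],
      trna_count = 10L,
      functional_genes = list(
        data.frame(family = c("nirS", "nosZ"), expression = c(3, 6)),
        data.frame(family = "pflB", expression = 8),
        data.frame(family = c("nirK", "pflB"), expression = c(2, 4))
      )[[i]],
      background_gene_count = 10L
    )
  })
  community_spec(pops,
    n_dna_reads = n_dna_reads, n_rna_reads = n_rna_reads,
    seed = seed, ...
  )
}
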