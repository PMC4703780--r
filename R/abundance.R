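# Read assignment, per-contig coverage and per-bin abundance.
#
# The mapper is deliberately simple: exact k-mer seeds anchor ungapped
# candidate placements on either strand, candidates are verified by
# substitution-only identity, and each read goes to its single best
# placement (deterministic tie-breaks).  The quantity of interest downstream
# is coverage, not alignments; reads with indels may go unassigned.

# all k-mers of a set of contigs as a data.table(kmer, contig, pos)
build_kmer_index <- function(contigs, k) {
  parts <- lapply(names(contigs), function(id) {
    len <- nchar(contigs[[id]])
    if (len < k) return(NULL)
    pos <- seq_len(len - k + 1L)
    data.table::data.table(
      kmer = substring(contigs[[id]], pos, pos + k - 1L),
      contig = id, pos = pos
    )
  })
  idx <- data.table::rbindlist(parts)
  if (nrow(idx) > 0) data.table::setkey(idx, kmer)
  idx
}

# mismatches between two equal-length string vectors, by position-wise
# byte comparison of the concatenations
count_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0) return(integer(0))
  la <- nchar(a)
  ra <- charToRaw(paste(a, collapse = ""))
  rb <- charToRaw(paste(b, collapse = ""))
  neq <- ra != rb
  grp <- rep.int(seq_along(a), la)
  as.integer(rowsum(as.integer(neq), grp)[, 1])
}

#' Assign reads to contigs with a k-mer-seeded matcher
#'
#' For each read, disjoint k-mers of the read and of its reverse complement
#' are looked up in an exact k-mer index of the contigs; every hit anchors
#' an ungapped candidate placement, candidates extending past a contig end
#' are dropped, and the rest are verified base-by-base.  The read is
#' assigned to the placement with the most matching bases, provided the
#' identity (matched/length) reaches `min_identity`; ties break to the
#' lexicographically smallest contig id, then `+` strand, then smallest
#' position, so assignment is deterministic.
#'
#' @param reads Named character vector of read sequences.
#' @param contigs Named character vector of contig sequences.
#' @param k Seed length (default 21; must not exceed the read length).
#' @param min_identity Minimum fraction of matching bases (default 0.9).
#' @return data.frame `read_id`, `contig` (`NA` when unassigned), `position`
#'   (1-based start on the contig), `strand`, `matched_bases`,
#'   `read_length`.
#' @export
assign_reads <- function(reads, contigs, k = 21L, min_identity = 0.9) {
  stopifnot(length(reads) >= 1, min_identity >= 0, min_identity <= 1)
  if (any(nchar(reads) < k)) {
    stop("k exceeds the shortest read length")
  }
  unassigned <- data.frame(
    read_id = names(reads), contig = NA_character_, position = NA_integer_,
    strand = NA_character_, matched_bases = NA_integer_,
    read_length = unname(nchar(reads)), stringsAsFactors = FALSE
  )
  if (length(contigs) == 0) {
    warning("empty contig set: all reads unassigned")
    return(unassigned)
  }
  idx <- build_kmer_index(contigs, k)
  if (nrow(idx) == 0) {
    warning("no contig is at least k long: all reads unassigned")
    return(unassigned)
  }
  rlen <- nchar(reads)
  fwd <- unname(reads)
  rev <- revcomp(fwd)

  # disjoint seed k-mers per read and orientation
  seed_tab <- lapply(c("+", "-"), function(s) {
    seqs <- if (s == "+") fwd else rev
    parts <- lapply(seq_along(seqs), function(i) {
      # disjoint k-mers plus the terminal window, so a single substitution
      # can never wipe out every seed
      offs <- unique(c(seq(1L, rlen[i] - k + 1L, by = k), rlen[i] - k + 1L))
      data.table::data.table(
        read = i, strand = s, off = offs,
        kmer = substring(seqs[i], offs, offs + k - 1L)
      )
    })
    data.table::rbindlist(parts)
  })
  seeds <- data.table::rbindlist(seed_tab)
  hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(unassigned)
  hits[, start := pos - off + 1L]
  hits <- unique(hits[, list(read, strand, contig, start)])
  clen <- nchar(contigs)
  hits <- hits[start >= 1L & start + rlen[read] - 1L <= clen[contig]]
  if (nrow(hits) == 0) return(unassigned)

  qry <- ifelse(hits$strand == "+", fwd[hits$read], rev[hits$read])
  sub <- substring(
    contigs[hits$contig], hits$start,
    hits$start + rlen[hits$read] - 1L
  )
  mm <- count_mismatches(qry, sub)
  hits[, matched := rlen[read] - mm]
  hits <- hits[matched >= ceiling(min_identity * rlen[read])]
  if (nrow(hits) == 0) return(unassigned)
  data.table::setorder(hits, read, -matched, contig, strand, start)
  best <- hits[!duplicated(read)]

  out <- unassigned
  out$contig[best$read] <- best$contig
  out$position[best$read] <- best$start
  out$strand[best$read] <- best$strand
  out$matched_bases[best$read] <- best$matched
  out
}

#' Per-contig mean coverage from read assignments
#'
#' Coverage of a contig is the total number of matched bases assigned to it
#' divided by its length.
#'
#' @param assignments data.frame from [assign_reads()].
#' @param contig_lengths Named integer vector of contig lengths (> 0).
#' @return Named numeric vector of coverages, one per contig (0 for contigs
#'   without reads).
#' @export
contig_coverage <- function(assignments, contig_lengths) {
  stopifnot(all(contig_lengths > 0))
  cov <- setNames(numeric(length(contig_lengths)), names(contig_lengths))
  a <- assignments[!is.na(assignments$contig), , drop = FALSE]
  if (nrow(a) > 0) {
    tot <- rowsum(a$matched_bases, a$contig)
    cov[rownames(tot)] <- tot[, 1] / contig_lengths[rownames(tot)]
  }
  cov
}

#' Per-bin relative abundance from coverage and bin size
#'
#' The abundance of a bin is its share of assigned bases:
#' `sum(coverage_i x length_i)` over the bin's contigs divided by the same
#' sum over all contigs.  Mass on contigs not in any bin is reported under
#' `"unbinned"`.  Two normalizations are returned: `abundance` uses all
#' contigs in the denominator (so the bin fractions plus unbinned sum to 1)
#' and `abundance_binned_only` renormalizes over binned contigs only.
#'
#' @param coverage Named numeric vector from [contig_coverage()].
#' @param assignment data.frame `contig`/`bin` ([cluster_contigs()]).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param sample_id Label for the sample column (default `"sample_01"`).
#' @return data.frame `sample`, `bin`, `abundance`, `abundance_binned_only`
#'   (NA for the unbinned row); each abundance column sums to 1 over its
#'   rows.
#' @export
bin_abundance <- function(coverage, assignment, contig_lengths,
                          sample_id = "sample_01") {
  stopifnot(all(assignment$contig %in% names(contig_lengths)))
  mass <- coverage[assignment$contig] * contig_lengths[assignment$contig]
  total <- sum(mass)
  if (total <= 0) stop("no signal: zero assigned bases in total")
  by_bin <- rowsum(unname(mass), assignment$bin)
  bins <- rownames(by_bin)
  ab <- by_bin[, 1] / total
  binned <- bins != "unbinned"
  ab_binned <- rep(NA_real_, length(bins))
  if (any(binned) && sum(by_bin[binned, 1]) > 0) {
    ab_binned[binned] <- by_bin[binned, 1] / sum(by_bin[binned, 1])
  }
  ord <- order(!binned, bins)
  data.frame(
    sample = sample_id, bin = bins[ord], abundance = unname(ab[ord]),
    abundance_binned_only = ab_binned[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
}
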