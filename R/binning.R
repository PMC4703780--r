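# Tetranucleotide binning: canonical 4-mer signatures, GC, PCA +
# agglomerative clustering over signature/coverage/GC features, bin
# statistics (size, N50, GC, marker census) and GC-vs-coverage blob tables.

# the 136 canonical 4-mers (each 4-mer merged with its reverse complement)
canonical_tetramers <- function() {
  kmers <- all_kmer_strings(c("A", "C", "G", "T"), 4L)
  sort(unique(pmin(kmers, revcomp_kmers(kmers))))
}

all_kmer_strings <- function(alphabet, width) {
  grid <- do.call(expand.grid, rep(list(alphabet), width))
  apply(grid[, rev(seq_len(width)), drop = FALSE], 1, paste, collapse = "")
}

revcomp_kmers <- function(kmers) {
  chartr("ACGT", "TGCA", vapply(kmers, function(k) {
    paste(rev(strsplit(k, "")[[1]]), collapse = "")
  }, character(1)))
}

# map each of the 256 4-mers to its canonical representative
tetra_canonical_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      kmers <- all_kmer_strings(c("A", "C", "G", "T"), 4L)
      cache <<- setNames(pmin(kmers, revcomp_kmers(kmers)), kmers)
    }
    cache
  }
})

#' Tetranucleotide signature of a sequence
#'
#' Counts all overlapping 4-mers (windows containing non-ACGT symbols are
#' skipped), merges each 4-mer with its reverse complement into one of 136
#' canonical 4-mers, and normalizes to relative frequencies.  The signature
#' is therefore identical for a sequence and its reverse complement.
#'
#' @param sequence A DNA string.
#' @param pseudocount Count added to every canonical 4-mer before
#'   normalization (default 0; clustering uses 1 to stabilize short
#'   contigs).
#' @return A named numeric vector of length 136 summing to 1, with
#'   attribute `n_kmers` (number of counted 4-mers).
#' @export
tetra_signature <- function(sequence, pseudocount = 0) {
  sig <- tetra_signature_matrix(setNames(sequence, "x"), pseudocount)
  v <- sig$values[1, ]
  attr(v, "n_kmers") <- sig$n_kmers[[1]]
  v
}

#' Tetranucleotide signatures for a set of contigs
#'
#' @param contigs Named character vector of DNA sequences.
#' @param pseudocount As in [tetra_signature()].
#' @return A list with `values` (matrix contigs x 136 canonical 4-mers) and
#'   `n_kmers` (counted 4-mers per contig).
#' @export
tetra_signature_matrix <- function(contigs, pseudocount = 0) {
  stopifnot(length(contigs) >= 1, pseudocount >= 0)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(contigs),
    width = 4L
  )
  canon <- tetra_canonical_map()
  groups <- canon[colnames(counts)]
  ccounts <- t(rowsum(t(counts), group = groups))
  ccounts <- ccounts[, canonical_tetramers(), drop = FALSE]
  n_kmers <- rowSums(ccounts)
  if (any(n_kmers == 0) && pseudocount == 0) {
    stop(
      "no countable 4-mers in contig(s): ",
      paste(names(contigs)[n_kmers == 0], collapse = ", ")
    )
  }
  vals <- ccounts + pseudocount
  vals <- vals / rowSums(vals)
  rownames(vals) <- names(contigs)
  list(values = vals, n_kmers = n_kmers)
}

#' GC content of sequences, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous symbols are excluded from
#' both numerator and denominator.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector of GC percentages.
#' @export
gc_content <- function(sequence) {
  ss <- Biostrings::DNAStringSet(sequence)
  f <- Biostrings::alphabetFrequency(ss)[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(f)
  if (any(tot == 0)) stop("sequence has no unambiguous bases; GC undefined")
  unname(100 * (f[, "C"] + f[, "G"]) / tot)
}

#' Cut contigs into consecutive fixed-length fragments
#'
#' Used for bin-profile diagnostics: each contig is split into consecutive,
#' non-overlapping fragments of `fragment_length` bp; a terminal remainder
#' is kept if it is at least half a fragment long.
#'
#' @param contigs Named character vector.
#' @param fragment_length Fragment length in bp (default 500).
#' @return Named character vector of fragments (`<contig>_f<i>`).
#' @export
fragment_for_profile <- function(contigs, fragment_length = 500L) {
  stopifnot(fragment_length > 0)
  out <- character(0)
  for (id in names(contigs)) {
    len <- nchar(contigs[[id]])
    starts <- seq(1L, len, by = fragment_length)
    ends <- pmin(starts + fragment_length - 1L, len)
    keep <- (ends - starts + 1L) >= fragment_length / 2
    starts <- starts[keep]
    ends <- ends[keep]
    if (length(starts) == 0) next
    frags <- substring(contigs[[id]], starts, ends)
    names(frags) <- sprintf("%s_f%03d", id, seq_along(frags))
    out <- c(out, frags)
  }
  out
}

#' Cluster contigs into bins by tetranucleotide signature, coverage and GC
#'
#' Contigs shorter than `min_contig_len` are set aside as `"unbinned"`.
#' Canonical signatures (pseudocount 1) are reduced by PCA; standardized
#' log10 coverage and GC are appended as extra features (scaled to the
#' spread of the first principal component); contigs are then joined by
#' agglomerative clustering (Ward criterion) and the tree is cut at `k`
#' clusters.  When `k` is `NULL` it is chosen by the mean
#' silhouette width over `2..max_k`.  The procedure uses no random numbers
#' and contigs are sorted by id first, so the assignment is deterministic
#' and invariant to input order.
#'
#' @param contigs Named character vector of contig sequences.
#' @param coverages Named numeric vector of per-contig mean coverages.
#' @param min_contig_len Minimum contig length in bp (default 1000).
#' @param n_components Number of signature principal components (default 5).
#' @param k Number of bins, or `NULL` for silhouette auto-selection.
#' @param max_k Largest k tried during auto-selection (default 12).
#' @param coverage_weight,gc_weight Relative weights of the coverage and GC
#'   features against the signature components.
#' @return data.frame with columns `contig`, `bin` (`bin_01`, ... labelled
#'   in decreasing order of total bin size, or `"unbinned"`) and `length`.
#' @export
cluster_contigs <- function(contigs, coverages, min_contig_len = 1000L,
                            n_components = 5L, k = NULL, max_k = 12L,
                            coverage_weight = 1, gc_weight = 1) {
  stopifnot(length(contigs) >= 1, !is.null(names(contigs)))
  stopifnot(all(names(contigs) %in% names(coverages)) ||
    length(coverages) == length(contigs))
  if (is.null(names(coverages))) names(coverages) <- names(contigs)
  ord <- order(names(contigs))
  contigs <- contigs[ord]
  lens <- nchar(contigs)
  pass <- lens >= min_contig_len
  if (!any(pass)) stop("no contig passes min_contig_len")
  ids <- names(contigs)[pass]
  out <- data.frame(
    contig = names(contigs), bin = "unbinned", length = unname(lens),
    stringsAsFactors = FALSE
  )
  n <- length(ids)
  if (n == 1) {
    out$bin[pass] <- "bin_01"
    return(out)
  }
  if (!is.null(k) && n < k) {
    warning("fewer contigs than requested clusters; one bin per contig")
    cl <- seq_len(n)
  } else {
    sig <- tetra_signature_matrix(contigs[ids], pseudocount = 1)$values
    npc <- min(n_components, n - 1L, ncol(sig))
    pcs <- prcomp(sig, center = TRUE, scale. = FALSE)$x[, seq_len(npc), drop = FALSE]
    s1 <- sd(pcs[, 1])
    if (!is.finite(s1) || s1 == 0) s1 <- 1
    covf <- log10(coverages[ids] + 1)
    gcf <- gc_content(contigs[ids])
    std <- function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    feats <- cbind(
      pcs,
      cov = coverage_weight * std(covf) * s1,
      gc = gc_weight * std(gcf) * s1
    )
    tree <- hclust(dist(feats), method = "ward.D2")
    if (is.null(k)) {
      ks <- seq(2L, min(max_k, n - 1L))
      sil <- vapply(ks, function(kk) {
        cl <- cutree(tree, kk)
        mean(cluster::silhouette(cl, dist(feats))[, "sil_width"])
      }, numeric(1))
      k <- ks[which.max(sil)]
    }
    cl <- cutree(tree, k)
  }
  # label bins in decreasing order of total size
  sizes <- rowsum(lens[pass], cl)[, 1]
  rank <- rank(-sizes, ties.method = "first")
  out$bin[match(ids, out$contig)] <-
    sprintf("bin_%02d", rank[as.character(cl)])
  out
}

# N50: the largest member length L such that contigs of length >= L hold at
# least half the total size
n50 <- function(lengths) {
  if (length(lengths) == 0) return(NA_integer_)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Per-bin summary statistics
#'
#' One row per bin: total size (bp), number of contigs, N50 (bp),
#' length-weighted GC (%), length-weighted mean coverage, and - when a
#' marker census is supplied - conserved single-copy gene and tRNA counts.
#'
#' @param assignment data.frame `contig`/`bin` from [cluster_contigs()].
#' @param contigs Named character vector of contig sequences.
#' @param coverages Named numeric vector of per-contig coverages.
#' @param census Optional data.frame from [census()] with one row per bin.
#' @param include_unbinned Keep the `"unbinned"` pseudo-bin (default FALSE).
#' @return data.frame with columns `bin`, `size_bp`, `n_contigs`, `n50_bp`,
#'   `gc_percent`, `mean_coverage` and, if available, `cscg_count`,
#'   `trna_count`.
#' @export
bin_stats <- function(assignment, contigs, coverages, census = NULL,
                      include_unbinned = FALSE) {
  stopifnot(all(assignment$contig %in% names(contigs)))
  bins <- sort(unique(assignment$bin))
  if (!include_unbinned) bins <- setdiff(bins, "unbinned")
  rows <- lapply(bins, function(b) {
    ids <- assignment$contig[assignment$bin == b]
    lens <- nchar(contigs[ids])
    gcb <- gc_content(contigs[ids])
    data.frame(
      bin = b,
      size_bp = sum(lens),
      n_contigs = length(ids),
      n50_bp = n50(lens),
      gc_percent = sum(gcb * lens) / sum(lens),
      mean_coverage = sum(coverages[ids] * lens) / sum(lens),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  if (!is.null(census)) {
    m <- match(out$bin, census$bin)
    out$cscg_count <- census$total_marker_hits[m]
    out$trna_count <- census$trna_count[m]
  }
  out
}

#' Format bin statistics with conventional table headers
#'
#' Renders [bin_stats()] output with the column labels conventional for
#' draft-genome summary tables ("Size (kb)", "Number of contigs (#)", "N50
#' contig length (kb)", "GC content (%)", "Number of CSCGs (#)", "Number of
#' tRNAs (#)").  Sizes are emitted in kb, converted explicitly from the bp
#' values.
#'
#' @param stats data.frame from [bin_stats()].
#' @return data.frame with display columns.
#' @export
format_bin_table <- function(stats) {
  out <- data.frame(
    Bin = stats$bin,
    `Size (kb)` = round(stats$size_bp / 1000, 2),
    `Number of contigs (#)` = stats$n_contigs,
    `N50 contig length (kb)` = round(stats$n50_bp / 1000, 2),
    `GC content (%)` = round(stats$gc_percent, 1),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if ("cscg_count" %in% names(stats)) {
    out$`Number of CSCGs (#)` <- stats$cscg_count
    out$`Number of tRNAs (#)` <- stats$trna_count
  }
  out
}

#' GC-vs-coverage blob table
#'
#' One record per contig with its GC (%), coverage and bin membership - the
#' data behind the classic GC/coverage blob plot used to inspect binning.
#'
#' @inheritParams bin_stats
#' @return data.frame `contig`, `length`, `gc`, `coverage`, `bin`.
#' @export
blob_table <- function(assignment, contigs, coverages) {
  data.frame(
    contig = assignment$contig,
    length = nchar(contigs[assignment$contig]),
    gc = gc_content(contigs[assignment$contig]),
    coverage = unname(coverages[assignment$contig]),
    bin = assignment$bin,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
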