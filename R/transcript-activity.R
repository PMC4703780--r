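# Per-gene transcriptional activity.
#
# An RNA read counts toward the gene containing its midpoint; per-gene
# read-count densities (count / gene length) are then normalized by the
# mean density of the gene's bin, so the average activity of genes
# belonging to any bin equals 1: values above 1 mark above-average
# transcription within that population.

#' Count RNA reads per gene
#'
#' Each assigned read counts toward the gene (1-based inclusive
#' coordinates) containing its alignment midpoint; reads whose midpoint
#' falls outside every gene are tallied as intergenic.  When genes overlap,
#' the midpoint goes to the gene with the lexicographically smaller id and
#' the count is flagged ambiguous.
#'
#' @param assignments data.frame from [assign_reads()] (RNA reads mapped to
#'   contigs).
#' @param genes Annotation data.frame with `contig`, `start`, `end`,
#'   `gene_id`.
#' @return A list with `counts` (data.frame `gene_id`, `count`, `ambiguous`)
#'   and `intergenic` (number of reads in no gene).
#' @export
count_rna <- function(assignments, genes) {
  stopifnot(all(c("contig", "start", "end", "gene_id") %in% names(genes)))
  a <- assignments[!is.na(assignments$contig), , drop = FALSE]
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  ambig <- setNames(logical(nrow(genes)), genes$gene_id)
  intergenic <- 0L
  if (nrow(a) > 0) {
    mid <- a$position + (a$read_length - 1L) %/% 2L
    go <- genes[order(genes$gene_id), , drop = FALSE]
    for (ct in unique(a$contig)) {
      g <- go[go$contig == ct, , drop = FALSE]
      m <- mid[a$contig == ct]
      if (nrow(g) == 0) {
        intergenic <- intergenic + length(m)
        next
      }
      for (x in m) {
        j <- which(g$start <= x & x <= g$end)
        if (length(j) == 0) {
          intergenic <- intergenic + 1L
        } else {
          gid <- g$gene_id[j[1]]
          counts[gid] <- counts[gid] + 1L
          if (length(j) > 1) ambig[gid] <- TRUE
        }
      }
    }
  }
  list(
    counts = data.frame(
      gene_id = genes$gene_id, count = unname(counts[genes$gene_id]),
      ambiguous = unname(ambig[genes$gene_id]), stringsAsFactors = FALSE
    ),
    intergenic = intergenic
  )
}

#' Normalize per-gene activities within bins
#'
#' The activity of gene `g` is its read-count density `c_g / L_g` divided by
#' the arithmetic mean density of all genes in its bin, so defined
#' activities average exactly 1 per bin.  By default the mean includes
#' zero-count genes; `expressed_only = TRUE` averages over genes with at
#' least one read instead.  Bins with zero total count get missing
#' activities (the analogue of "-" entries in activity tables).
#'
#' @param counts data.frame `gene_id`, `count` (from [count_rna()]).
#' @param lengths Named integer vector of gene lengths in bp (> 0).
#' @param bin_of_gene Named character vector mapping gene_id to bin.
#' @param expressed_only Average over expressed genes only (default FALSE).
#' @return data.frame `gene_id`, `bin`, `length`, `count`, `density`,
#'   `activity` (NA in bins with no signal).
#' @export
normalize_activity <- function(counts, lengths, bin_of_gene,
                               expressed_only = FALSE) {
  stopifnot(all(counts$gene_id %in% names(lengths)))
  stopifnot(all(counts$gene_id %in% names(bin_of_gene)))
  len <- unname(lengths[counts$gene_id])
  if (any(len <= 0)) stop("zero or negative gene length")
  out <- data.frame(
    gene_id = counts$gene_id,
    bin = unname(bin_of_gene[counts$gene_id]),
    length = len,
    count = counts$count,
    density = counts$count / len,
    activity = NA_real_,
    stringsAsFactors = FALSE
  )
  for (b in unique(out$bin)) {
    i <- which(out$bin == b)
    dens <- out$density[i]
    denom_set <- if (expressed_only) dens[dens > 0] else dens
    if (length(denom_set) == 0 || sum(dens) == 0) next
    mu <- mean(denom_set)
    act <- dens / mu
    if (expressed_only) act[dens == 0] <- NA_real_
    out$activity[i] <- act
  }
  out
}
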