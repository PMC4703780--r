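#' Fragment genomes into contigs
#'
#' Stands in for metagenome assembly: each genome is cut into consecutive,
#' non-overlapping contigs whose realized N50 tracks `n50_target` (piece
#' lengths are drawn uniformly between 0.5 and 1.5 times the target).  Pieces
#' shorter than `min_len` are merged into their left neighbour, so no contig
#' is shorter than `min_len`; the union of contigs covers each genome exactly
#' once.  When a gene truth table is supplied, cut points falling inside a
#' planted gene are shifted past the gene, and the gene annotations are
#' lifted onto contig coordinates.
#'
#' @param genomes Named character vector of genome sequences.
#' @param n50_target Target N50 in bp.
#' @param min_len Minimum contig length in bp (`n50_target >= min_len`).
#' @param seed Integer seed (fragmentation is random but reproducible).
#' @param genes Optional gene truth table in genome coordinates, as returned
#'   by [generate_community()].
#' @return A list with:
#'   * `contigs`: named character vector of contig sequences;
#'   * `map`: data.frame `contig`, `population`, `genome_start`,
#'     `genome_end`, `length` (1-based inclusive genome coordinates);
#'   * `genes`: the gene table lifted to contig coordinates (columns
#'     `contig`, `start`, `end`, `strand`, `gene_id`, `class`, `family`,
#'     `expression`), or `NULL` if `genes` was not supplied.
#' @export
fragment_genomes <- function(genomes, n50_target = 8000L, min_len = 1000L,
                             seed = 1L, genes = NULL) {
  stopifnot(n50_target >= min_len, min_len >= 1)
  with_seed(seed, {
    contig_seqs <- character(0)
    maps <- list()
    for (gid in names(genomes)) {
      glen <- nchar(genomes[[gid]])
      if (glen < min_len) {
        warning("genome ", gid, " shorter than min_len; emitting single contig")
        cuts <- glen
      } else {
        cuts <- integer(0)
        pos <- 0L
        while (pos < glen) {
          if (glen - pos <= n50_target) {
            # a remainder no longer than the target stays in one piece
            cuts <- c(cuts, glen)
            break
          }
          step <- round(runif(1, 0.5 * n50_target, 1.5 * n50_target))
          pos <- min(pos + max(step, min_len), glen)
          if (!is.null(genes)) {
            # shift a cut point out of any planted gene
            g <- genes[genes$population == gid, , drop = FALSE]
            repeat {
              inside <- which(g$start <= pos & pos < g$end)
              if (length(inside) == 0 || pos >= glen) break
              pos <- min(max(g$end[inside]), glen)
            }
          }
          cuts <- c(cuts, pos)
        }
        # merge a short terminal piece leftwards
        lens <- diff(c(0L, cuts))
        while (length(lens) > 1 && any(lens < min_len)) {
          i <- which(lens < min_len)[1]
          j <- if (i == 1) 2L else i - 1L
          lens[j] <- lens[j] + lens[i]
          lens <- lens[-i]
        }
        cuts <- cumsum(lens)
      }
      starts <- c(1L, head(cuts, -1L) + 1L)
      ends <- cuts
      ids <- sprintf("%s_c%03d", gid, seq_along(starts))
      contig_seqs[ids] <- substring(genomes[[gid]], starts, ends)
      maps[[gid]] <- data.frame(
        contig = ids, population = gid,
        genome_start = as.integer(starts), genome_end = as.integer(ends),
        length = as.integer(ends - starts + 1L), stringsAsFactors = FALSE
      )
    }
    map <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
    lifted <- NULL
    if (!is.null(genes)) {
      lifted <- lift_genes(genes, map)
    }
    list(contigs = contig_seqs, map = map, genes = lifted)
  })
}

# lift genome-coordinate gene annotations onto contig coordinates; genes
# spanning a cut (possible only when fragmentation was gene-unaware) are
# assigned to the contig holding their midpoint and truncated to it
lift_genes <- function(genes, map) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    m <- map[map$population == g$population, , drop = FALSE]
    mid <- (g$start + g$end) %/% 2L
    j <- which(m$genome_start <= mid & mid <= m$genome_end)
    if (length(j) != 1) next
    s <- max(g$start, m$genome_start[j])
    e <- min(g$end, m$genome_end[j])
    rows[[i]] <- data.frame(
      contig = m$contig[j],
      start = s - m$genome_start[j] + 1L,
      end = e - m$genome_start[j] + 1L,
      strand = g$strand, gene_id = g$gene_id, class = g$class,
      family = g$family, expression = g$expression,
      population = g$population, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
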