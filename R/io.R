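#' Read and write sequence and annotation files
#'
#' Thin wrappers around Biostrings / rtracklayer so the rest of the package
#' deals in plain R objects: named character vectors for sequences and
#' data.frames for annotations and tables.
#'
#' @param path File path.
#' @param seqs Named character vector of DNA sequences.
#' @param x A data.frame.
#' @name io
NULL

#' @rdname io
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname io
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname io
#' @param quals Named character vector of Sanger-offset (Phred+33) quality
#'   strings, same lengths as `seqs`.
#' @export
write_fastq <- function(seqs, quals, path) {
  stopifnot(length(seqs) == length(quals), all(nchar(seqs) == nchar(quals)))
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(unname(quals))
  )
  names(qs) <- names(seqs)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname io
#' @return `read_fastq()`: a list with elements `seq` and `qual`, both named
#'   character vectors.
#' @export
read_fastq <- function(path) {
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(
    seq = setNames(as.character(qs), names(qs)),
    qual = setNames(as.character(Biostrings::quality(qs)), names(qs))
  )
}

#' Read and write gene annotations (GFF3)
#'
#' Annotations are represented as a data.frame with columns `contig`,
#' `start`, `end` (1-based inclusive), `strand`, `gene_id`, `class`
#' (`"marker"`, `"trna"`, `"functional"` or `"background"`), `family`
#' (marker or functional-gene family, `NA` otherwise) and `expression`
#' (simulated expression level, `NA` when unknown).  On disk, marker
#' families are carried in a `marker_family=` attribute and tRNAs are
#' flagged with `trna=1`, so externally produced annotations can use the
#' same vocabulary.
#'
#' @param genes Annotation data.frame as described above.
#' @param path File path.
#' @return `read_gff3()` returns the annotation data.frame.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(c("contig", "start", "end", "strand", "gene_id", "class") %in%
    names(genes)))
  fam <- if ("family" %in% names(genes)) genes$family else rep(NA_character_, nrow(genes))
  expr <- if ("expression" %in% names(genes)) genes$expression else rep(NA_real_, nrow(genes))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  S4Vectors::mcols(gr)$type <- ifelse(genes$class == "trna", "tRNA", "gene")
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$class <- genes$class
  S4Vectors::mcols(gr)$marker_family <-
    ifelse(genes$class == "marker", fam, NA_character_)
  S4Vectors::mcols(gr)$family <-
    ifelse(genes$class == "functional", fam, NA_character_)
  S4Vectors::mcols(gr)$trna <- ifelse(genes$class == "trna", "1", NA_character_)
  S4Vectors::mcols(gr)$expression <- expr
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm, default) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(default, length(gr))
  }
  cls <- getcol("class", NA_character_)
  trna <- getcol("trna", NA_character_)
  marker <- getcol("marker_family", NA_character_)
  fam <- getcol("family", NA_character_)
  # reconstruct the class for annotations written by other tools
  cls[is.na(cls) & !is.na(trna)] <- "trna"
  cls[is.na(cls) & !is.na(marker)] <- "marker"
  cls[is.na(cls) & !is.na(fam)] <- "functional"
  cls[is.na(cls)] <- "background"
  expr <- if ("expression" %in% names(mc)) {
    suppressWarnings(as.numeric(mc$expression))
  } else {
    rep(NA_real_, length(gr))
  }
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = getcol("ID", NA_character_),
    class = cls,
    family = ifelse(cls == "marker", marker, fam),
    expression = expr,
    stringsAsFactors = FALSE
  )
}

#' @rdname io
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# internal: reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
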