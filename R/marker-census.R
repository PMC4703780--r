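# Completeness/contamination census from conserved single-copy genes
# (CSCGs) and tRNA counts.  Detection is annotation-driven: the census
# consumes GFF3-style annotations carrying `marker_family=` and `trna=`
# attributes (from the synthetic generator or an external annotator);
# profile-based marker search is intentionally not re-implemented here.

#' The conserved single-copy marker catalogue
#'
#' A catalogue of 139 distinct marker family identifiers.  The default is a
#' set of placeholder ids (`CSCG_001` ... `CSCG_139`); users with the
#' published 139-gene set can substitute their own identifiers, as the
#' census only matches annotation attributes against this list.
#'
#' @param families Optional character vector of exactly 139 distinct family
#'   ids replacing the placeholders.
#' @return Character vector of 139 family ids.
#' @export
marker_catalogue <- function(families = NULL) {
  if (is.null(families)) {
    return(sprintf("CSCG_%03d", 1:139))
  }
  families <- as.character(families)
  if (length(unique(families)) != 139) {
    stop("the marker catalogue must contain exactly 139 distinct families")
  }
  families
}

#' Marker and tRNA census of bins
#'
#' Counts, over the member contigs of each bin, the distinct and total
#' conserved single-copy marker families and the tRNA genes.  Completeness
#' is `distinct_markers / 139`; more total marker hits than 139 indicates
#' DNA from more than one population in the bin and raises the duplication
#' flag.  Annotations citing marker families outside the catalogue are
#' ignored with a warning.
#'
#' @param genes Annotation data.frame (see [read_gff3()]) with columns
#'   `contig`, `class`, `family`.
#' @param assignment data.frame `contig`/`bin` from [cluster_contigs()].
#' @param catalogue Character vector from [marker_catalogue()].
#' @return data.frame with one row per bin: `bin`, `distinct_markers`,
#'   `total_marker_hits`, `trna_count`, `completeness`, `duplication_flag`.
#' @export
census <- function(genes, assignment, catalogue = marker_catalogue()) {
  stopifnot(all(c("contig", "class", "family") %in% names(genes)))
  bins <- sort(setdiff(unique(assignment$bin), "unbinned"))
  markers <- genes[genes$class == "marker", , drop = FALSE]
  unknown <- setdiff(markers$family, catalogue)
  if (length(unknown) > 0) {
    warning(
      "ignoring annotations with unknown marker families: ",
      paste(head(unknown, 5), collapse = ", ")
    )
    markers <- markers[markers$family %in% catalogue, , drop = FALSE]
  }
  trnas <- genes[genes$class == "trna", , drop = FALSE]
  rows <- lapply(bins, function(b) {
    member <- assignment$contig[assignment$bin == b]
    mk <- markers[markers$contig %in% member, , drop = FALSE]
    data.frame(
      bin = b,
      distinct_markers = length(unique(mk$family)),
      total_marker_hits = nrow(mk),
      trna_count = sum(trnas$contig %in% member),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$completeness <- out$distinct_markers / 139
  out$duplication_flag <- out$total_marker_hits > 139
  out
}
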