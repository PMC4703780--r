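# Guild classification from detected functional genes, and per-sample
# aggregation of guild abundances.
#
# Presence of any nitrite reductase (nirS or nirK) or nitrous oxide
# reductase (nosZ) marks a population as contributing to denitrification;
# presence of pyruvate formate lyase (pflB) marks fermentation.  pflB is the
# only unambiguous fermentation marker here (acetate-cycle genes are
# bidirectional), so "denitrifier" populations may still ferment by other
# routes - the aggregation attaches that caveat as a warning.

DENIT_FAMILIES <- c("nirS", "nirK", "nosZ")
FERM_FAMILIES <- c("pflB")

#' Classify one bin into a functional guild
#'
#' @param families Character vector of functional-gene families detected in
#'   the bin.
#' @return A one-row data.frame: `has_denitrification`, `has_fermentation`,
#'   `label` (`denitrifier`, `fermentative`, `both` or `unclassified`) and
#'   an informational `subtype` for denitrifiers (`complete` when both a
#'   nitrite reductase and nosZ are present, `nitrite_reducer` or
#'   `n2o_reducer` otherwise; `NA` for non-denitrifiers).
#' @export
classify_bin <- function(families) {
  has_den <- any(families %in% DENIT_FAMILIES)
  has_fer <- any(families %in% FERM_FAMILIES)
  label <- if (has_den && has_fer) {
    "both"
  } else if (has_den) {
    "denitrifier"
  } else if (has_fer) {
    "fermentative"
  } else {
    "unclassified"
  }
  has_nir <- any(families %in% c("nirS", "nirK"))
  has_nos <- "nosZ" %in% families
  subtype <- if (!has_den) {
    NA_character_
  } else if (has_nir && has_nos) {
    "complete"
  } else if (has_nir) {
    "nitrite_reducer"
  } else {
    "n2o_reducer"
  }
  data.frame(
    has_denitrification = has_den, has_fermentation = has_fer,
    label = label, subtype = subtype, stringsAsFactors = FALSE
  )
}

#' Classify all bins from a gene-hit table
#'
#' @param hits data.frame with columns `bin` and `family` (e.g.
#'   [scan_profiles()] output joined with a contig-to-bin assignment, or a
#'   transcribed gene inventory).
#' @param bins Optional character vector of bins to classify (defaults to
#'   those present in `hits`); bins without hits label `unclassified`.
#' @param require_transcription If TRUE, only hits with a positive
#'   `activity` column count as presence.
#' @return data.frame with one row per bin: `bin`, `has_denitrification`,
#'   `has_fermentation`, `label`, `subtype`.
#' @export
classify_bins <- function(hits, bins = NULL, require_transcription = FALSE) {
  stopifnot(all(c("bin", "family") %in% names(hits)))
  if (require_transcription) {
    if (!"activity" %in% names(hits)) {
      stop("require_transcription needs an 'activity' column")
    }
    hits <- hits[!is.na(hits$activity) & hits$activity > 0, , drop = FALSE]
  }
  if (is.null(bins)) bins <- sort(unique(hits$bin))
  rows <- lapply(bins, function(b) {
    cbind(
      data.frame(bin = b, stringsAsFactors = FALSE),
      classify_bin(hits$family[hits$bin == b])
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate bin abundances by guild
#'
#' Sums relative abundances per sample over the guild labels; the
#' `"unbinned"` pseudo-bin passes through under its own label, so per sample
#' the guild sums plus unclassified plus unbinned equal the total abundance
#' mass.
#'
#' @param profiles data.frame from [classify_bins()]; every bin appearing in
#'   `abundance` (other than `"unbinned"`) must have a profile row.
#' @param abundance data.frame `sample`, `bin`, `abundance` (from
#'   [bin_abundance()], possibly several samples stacked).
#' @return data.frame `sample`, `label`, `abundance`.
#' @export
aggregate_guilds <- function(profiles, abundance) {
  stopifnot(all(c("sample", "bin", "abundance") %in% names(abundance)))
  need <- setdiff(unique(abundance$bin), "unbinned")
  missing <- setdiff(need, profiles$bin)
  if (length(missing) > 0) {
    stop(
      "no guild profile for bin(s): ", paste(missing, collapse = ", ")
    )
  }
  label <- setNames(profiles$label, profiles$bin)
  lab <- ifelse(abundance$bin == "unbinned", "unbinned",
    unname(label[abundance$bin])
  )
  agg <- aggregate(
    list(abundance = abundance$abundance),
    by = list(sample = abundance$sample, label = lab), FUN = sum
  )
  agg <- agg[order(agg$sample, agg$label), , drop = FALSE]
  row.names(agg) <- NULL
  warning(
    "pflB is the only fermentation marker assessed; populations labelled ",
    "'denitrifier' may still ferment via other pathways",
    call. = FALSE
  )
  agg
}

#' A published 15-bin functional-gene inventory
#'
#' The packaged gene inventory of 15 population bins (A-O) from replicated
#' anoxic chemostat enrichments of tidal-sediment communities at 10 and
#' 25 degrees C, with one row per detected functional gene (nirS, nirK,
#' nosZ, pflB) and its normalized transcriptional activity (NA where no
#' transcription was detected).  Useful as a worked example for
#' [classify_bins()] and [aggregate_guilds()].
#'
#' @return data.frame with columns `bin`, `family`, `activity`.
#' @export
example_gene_inventory <- function() {
  path <- system.file("extdata", "chemostat_bins_gene_inventory.tsv",
    package = "chemoguild"
  )
  read_tsv(path)
}
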