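# Functional gene detection: six-frame translation of contigs and ungapped
# log-odds profile scanning for nirS / nirK / nosZ / pflB (or any family a
# seed alignment is supplied for), with split-frame merging so genes broken
# by homopolymer frameshifts are still recovered.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# bacterial/archaeal genetic code (translation table 11) as a codon lookup
genetic_code_11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("11")
    cache
  }
})

#' Six-frame translation
#'
#' Frames 1-3 translate the forward strand at offsets 0/1/2; frames 4-6
#' translate the reverse complement at offsets 0/1/2.  Translation uses the
#' bacterial genetic code (table 11); stop codons are emitted as `*` and
#' codons containing non-ACGT symbols as `X`.
#'
#' @param sequence A DNA string of length >= 3.
#' @return data.frame with columns `frame` (1-6), `strand` (`+`/`-`),
#'   `offset` (0-2) and `peptide`.
#' @export
six_frame_translate <- function(sequence) {
  if (nchar(sequence) < 3) stop("sequence shorter than one codon")
  code <- genetic_code_11()
  fwd <- sequence
  rev <- revcomp(sequence)
  len <- nchar(sequence)
  peps <- character(6)
  for (f in 1:6) {
    src <- if (f <= 3) fwd else rev
    o <- (f - 1L) %% 3L
    n <- len - o
    n <- n - n %% 3L
    peps[f] <- if (n >= 3) {
      starts <- seq.int(o + 1L, o + n, by = 3L)
      aa <- code[substring(src, starts, starts + 2L)]
      aa[is.na(aa)] <- "X" # codons containing non-ACGT symbols
      paste(aa, collapse = "")
    } else {
      ""
    }
  }
  data.frame(
    frame = 1:6, strand = rep(c("+", "-"), each = 3), offset = rep(0:2, 2),
    peptide = peps, stringsAsFactors = FALSE
  )
}

#' Read seed alignments from a directory
#'
#' Loads one aligned FASTA per protein family (files `<family>_*.afa` or
#' `<family>.afa`).  The packaged defaults are synthetic stand-in
#' alignments for nirS, nirK, nosZ and pflB, constructed with realistic
#' lengths and divergence because curated reference alignments are not
#' shipped; substitute your own alignments for real analyses.
#'
#' @param dir Directory of aligned FASTA files; defaults to the packaged
#'   synthetic set.
#' @return Named list (family -> named character vector of aligned,
#'   equal-length sequences).
#' @export
read_seed_alignments <- function(dir = system.file("extdata", "seed_alignments",
                                   package = "chemoguild"
                                 )) {
  files <- list.files(dir, pattern = "\\.afa$", full.names = TRUE)
  if (length(files) == 0) stop("no .afa alignments found in ", dir)
  out <- list()
  for (f in files) {
    fam <- sub("[_.].*$", "", basename(f))
    ss <- Biostrings::readAAStringSet(f)
    out[[fam]] <- setNames(as.character(ss), names(ss))
  }
  out
}

# columns kept after dropping those with > 50% gaps
profile_columns <- function(alignment) {
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  gapfrac <- colMeans(mat == "-" | mat == ".")
  list(mat = mat, keep = which(gapfrac <= 0.5))
}

#' Consensus sequence of an alignment
#'
#' Majority residue per column (ties break alphabetically), over the
#' columns retained by the profile (those with at most 50% gaps).
#'
#' @param alignment Named character vector of aligned sequences.
#' @return Ungapped consensus peptide string.
#' @export
consensus_sequence <- function(alignment) {
  pc <- profile_columns(alignment)
  cons <- vapply(pc$keep, function(j) {
    col <- pc$mat[, j]
    col <- col[col %in% AA20]
    names(sort(table(col), decreasing = TRUE))[1]
  }, character(1))
  paste(cons, collapse = "")
}

#' Build an ungapped log-odds protein profile
#'
#' Per retained column (<= 50% gaps), the score of residue `a` is
#' `log2((count_a + pseudocount) / (n + 20 * pseudocount) / background_a)`
#' where `n` is the number of non-gap residues in the column.  Unknown
#' residues (`X`) and stops (`*`) score like a zero-count residue.  A
#' detection threshold is calibrated on shuffled decoys (see
#' [calibrate_threshold()]) and stored with the profile.
#'
#' @param alignment Named character vector of >= 2 aligned, equal-length
#'   sequences.
#' @param family Family name carried into hits.
#' @param background Named numeric vector of residue background frequencies
#'   over the 20 amino acids (default uniform).
#' @param pseudocount Pseudocount (default 1).
#' @param calibrate Calibrate and store a score threshold (default TRUE).
#' @return A `protein_profile` list: `family`, `matrix` (22 residues x
#'   width, bits), `length`, `consensus`, `max_score`, `threshold`.
#' @export
build_profile <- function(alignment, family = "profile",
                          background = NULL, pseudocount = 1,
                          calibrate = TRUE) {
  if (length(alignment) < 2) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(alignment))) != 1) {
    stop("ragged alignment: sequences differ in length")
  }
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(all(AA20 %in% names(background)), all(background > 0))
  pc <- profile_columns(alignment)
  if (length(pc$keep) == 0) stop("no alignment columns with <= 50% gaps")
  mat <- matrix(0, nrow = 22, ncol = length(pc$keep),
    dimnames = list(c(AA20, "X", "*"), NULL)
  )
  for (jj in seq_along(pc$keep)) {
    col <- pc$mat[, pc$keep[jj]]
    col <- col[col %in% AA20]
    n <- length(col)
    counts <- table(factor(col, levels = AA20))
    sc <- log2((as.numeric(counts) + pseudocount) /
      (n + 20 * pseudocount) / background[AA20])
    zero <- log2(pseudocount / (n + 20 * pseudocount) / (1 / 20))
    mat[, jj] <- c(sc, zero, zero)
  }
  cons <- consensus_sequence(alignment)
  prof <- structure(
    list(
      family = family, matrix = mat, length = ncol(mat), consensus = cons,
      max_score = sum(apply(mat[AA20, , drop = FALSE], 2, max)),
      threshold = NA_real_
    ),
    class = "protein_profile"
  )
  if (calibrate) prof$threshold <- calibrate_threshold(prof)
  prof
}

RESIDUES <- c(AA20, "X", "*")

# score every window of `width` columns of profile columns `cols` along an
# integer-coded peptide; returns numeric(0) when the peptide is too short
score_windows <- function(pep_idx, mat, cols) {
  w <- length(cols)
  p <- length(pep_idx)
  if (p < w) return(numeric(0))
  if (p == w) {
    return(sum(mat[cbind(pep_idx, cols)]))
  }
  s <- numeric(p - w + 1L)
  for (i in seq_len(w)) {
    s <- s + mat[pep_idx[i:(p - w + i)], cols[i]]
  }
  s
}

encode_peptide <- function(peptide, mat = NULL) {
  idx <- match(strsplit(peptide, "")[[1]], RESIDUES)
  idx[is.na(idx)] <- 21L # X
  idx
}

#' Calibrate a detection threshold on shuffled decoys
#'
#' Scores `n` residue-shuffled copies of the profile consensus against the
#' profile and places the threshold between the best decoy score and the
#' consensus score: `decoy_max + margin * (consensus_score - decoy_max)`.
#' The margin (default 0.5) keeps the threshold far above the decoy maximum
#' - a threshold at the decoy maximum itself would still be crossed
#' occasionally when millions of genuine-negative windows are scanned -
#' while remaining far below the score of true family members at realistic
#' divergence.
#'
#' @param profile A `protein_profile`.
#' @param n Number of shuffled decoys (default 1000).
#' @param margin Fraction of the decoy-to-consensus score gap (default 0.5).
#' @param seed Integer seed (fixed default so packaged profiles are
#'   reproducible).
#' @return Threshold in bits.
#' @export
calibrate_threshold <- function(profile, n = 1000L, margin = 0.5,
                                seed = 421L) {
  mat <- profile$matrix
  cols <- seq_len(profile$length)
  cons_idx <- encode_peptide(profile$consensus, mat)
  cons_score <- score_windows(cons_idx, mat, cols)[1]
  decoy_max <- with_seed(seed, {
    max(vapply(seq_len(n), function(i) {
      score_windows(sample(cons_idx), mat, cols)[1]
    }, numeric(1)))
  })
  unname(decoy_max + margin * (cons_score - decoy_max))
}

# map a peptide window (frame, aa_start, aa_len) to 1-based inclusive DNA
# coordinates on the original contig
window_to_dna <- function(frame, aa_start, aa_len, contig_length) {
  o <- (frame - 1L) %% 3L
  s <- o + 3L * (aa_start - 1L) + 1L
  e <- o + 3L * (aa_start - 1L + aa_len)
  if (frame <= 3) {
    c(start = s, end = e)
  } else {
    c(start = contig_length - e + 1L, end = contig_length - s + 1L)
  }
}

# best window of profile columns `cols` in each frame of a translated
# contig; `frames` carries a list column `encoded` of integer-coded peptides
best_windows <- function(frames, mat, cols) {
  rows <- lapply(seq_len(6), function(f) {
    idx <- frames$encoded[[f]]
    s <- score_windows(idx, mat, cols)
    if (length(s) == 0) return(NULL)
    j <- which.max(s)
    data.frame(
      frame = f, strand = frames$strand[f], aa_start = j,
      score = s[j], stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Scan contigs for functional genes
#'
#' Translates each contig in six frames and slides each family profile along
#' every frame.  The best-scoring ungapped window per (contig, family) is
#' reported when it reaches the family threshold; overlapping windows of the
#' same family collapse onto the highest score by construction.  When no
#' full-length window passes, the profile is split in half and a pair of
#' sub-threshold half-windows in two different frames on the same strand
#' within `frameshift_gap` bp of each other is merged into a single hit
#' (flagged `frameshift = TRUE`) if the summed score passes - recovering
#' genes broken by artefactual homopolymer frameshifts.
#'
#' @param profiles List of `protein_profile`s (e.g. from [build_profile()]
#'   over [read_seed_alignments()]).
#' @param contigs Named character vector of contig sequences.
#' @param min_score Numeric score cutoff in bits, a single value or one per
#'   family; `NULL` (default) uses each profile's calibrated threshold.
#' @param frameshift_gap Maximum DNA gap between merged half-windows
#'   (default 30 bp).
#' @return data.frame of gene hits: `contig`, `family`, `contig_length`,
#'   `start`, `end` (1-based inclusive), `strand`, `frame`, `score`,
#'   `frameshift`.  Empty (zero rows) when nothing passes.
#' @export
scan_profiles <- function(profiles, contigs, min_score = NULL,
                          frameshift_gap = 30L) {
  hits <- list()
  for (cid in names(contigs)) {
    seq <- contigs[[cid]]
    clen <- nchar(seq)
    if (clen < 3) next
    frames <- six_frame_translate(seq)
    frames$encoded <- lapply(frames$peptide, encode_peptide)
    for (prof in profiles) {
      cutoff <- if (is.null(min_score)) {
        prof$threshold
      } else if (length(min_score) > 1) {
        min_score[[prof$family]]
      } else {
        min_score
      }
      w <- prof$length
      cols <- seq_len(w)
      full <- best_windows(frames, prof$matrix, cols)
      hit <- NULL
      best_score <- -Inf
      if (!is.null(full)) {
        best <- full[order(-full$score, full$frame, full$aa_start)[1], ]
        best_score <- best$score
        if (best$score >= cutoff) {
          dna <- window_to_dna(best$frame, best$aa_start, w, clen)
          hit <- data.frame(
            contig = cid, family = prof$family, contig_length = clen,
            start = dna["start"], end = dna["end"], strand = best$strand,
            frame = best$frame, score = best$score, frameshift = FALSE,
            stringsAsFactors = FALSE
          )
        }
      }
      # a frameshift-broken gene still leaves a strong (if sub-threshold)
      # full-window half-signal; only then is split-frame merging worth
      # trying, which spares featureless contigs the extra scans
      if (is.null(hit) && best_score >= 0.25 * cutoff) {
        hit <- merge_split_frames(
          frames, prof, cid, clen, cutoff, frameshift_gap
        )
      }
      if (!is.null(hit)) hits[[length(hits) + 1L]] <- hit
    }
  }
  if (length(hits) == 0) {
    return(data.frame(
      contig = character(0), family = character(0),
      contig_length = integer(0), start = integer(0), end = integer(0),
      strand = character(0), frame = integer(0), score = numeric(0),
      frameshift = logical(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

# attempt split-frame (frameshift-tolerant) detection for one profile on one
# contig: best prefix-half and suffix-half windows in different frames on
# the same strand, adjacent on the DNA, whose summed score passes the cutoff
merge_split_frames <- function(frames, prof, cid, clen, cutoff,
                               frameshift_gap) {
  w <- prof$length
  h <- w %/% 2L
  if (h < 10) return(NULL)
  pre <- best_windows(frames, prof$matrix, seq_len(h))
  suf <- best_windows(frames, prof$matrix, (h + 1L):w)
  if (is.null(pre) || is.null(suf)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(pre))) {
    for (j in seq_len(nrow(suf))) {
      if (pre$frame[i] == suf$frame[j]) next
      if (pre$strand[i] != suf$strand[j]) next
      score <- pre$score[i] + suf$score[j]
      if (score < cutoff) next
      d1 <- window_to_dna(pre$frame[i], pre$aa_start[i], h, clen)
      d2 <- window_to_dna(suf$frame[j], suf$aa_start[j], w - h, clen)
      # on the forward strand the prefix precedes the suffix; on the
      # reverse strand the suffix maps upstream
      left <- if (pre$strand[i] == "+") d1 else d2
      right <- if (pre$strand[i] == "+") d2 else d1
      gap <- right["start"] - left["end"] - 1L
      if (gap > frameshift_gap || gap < -45L) next
      if (is.null(best) || score > best$score) {
        best <- data.frame(
          contig = cid, family = prof$family, contig_length = clen,
          start = min(d1["start"], d2["start"]),
          end = max(d1["end"], d2["end"]),
          strand = pre$strand[i], frame = pre$frame[i], score = score,
          frameshift = TRUE, stringsAsFactors = FALSE
        )
      }
    }
  }
  best
}

#' Format gene hits with conventional table headers
#'
#' Renders hit rows (optionally joined with activities and bin membership)
#' using the column layout conventional for functional-gene tables:
#' "Contig / Gene / Contig length / Gene position / Strand / Affiliation /
#' Activity / Bin".
#'
#' @param hits data.frame from [scan_profiles()].
#' @param activity Optional named numeric vector or data.frame mapping hit
#'   gene (contig-level) to activity.
#' @param assignment Optional `contig`/`bin` data.frame.
#' @param affiliation Optional named character vector (bin -> affiliation).
#' @return data.frame with the display columns.
#' @export
format_gene_table <- function(hits, activity = NULL, assignment = NULL,
                              affiliation = NULL) {
  bin <- rep(NA_character_, nrow(hits))
  if (!is.null(assignment)) {
    bin <- assignment$bin[match(hits$contig, assignment$contig)]
  }
  act <- rep(NA_real_, nrow(hits))
  if (!is.null(activity)) {
    key <- paste(hits$contig, hits$family)
    act <- unname(activity[key])
  }
  data.frame(
    Contig = hits$contig,
    Gene = hits$family,
    `Contig length` = hits$contig_length,
    `Gene position` = sprintf("%d-%d", hits$start, hits$end),
    Strand = hits$strand,
    Affiliation = if (is.null(affiliation)) {
      NA_character_
    } else {
      unname(affiliation[bin])
    },
    Activity = act,
    Bin = bin,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
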