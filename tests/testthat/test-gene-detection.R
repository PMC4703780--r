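# Six-frame translation, profile construction and scanning.

test_that("six-frame translation matches hand translation", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr$peptide[fr$frame == 1], "MK")
  # frame 4 reads the reverse complement TTTCAT: TTT=F, CAT=H
  expect_equal(fr$peptide[fr$frame == 4], "FH")
  expect_equal(fr$strand, rep(c("+", "-"), each = 3))
  expect_error(six_frame_translate("AT"), "codon")
})

test_that("frames of the reverse complement swap blocks 1-3 and 4-6", {
  set.seed(5)
  for (i in 1:5) {
    s <- random_dna(90 + i)
    a <- six_frame_translate(s)
    b <- six_frame_translate(rc_str(s))
    expect_identical(b$peptide[1:3], a$peptide[4:6])
    expect_identical(b$peptide[4:6], a$peptide[1:3])
  }
})

test_that("stops become * and ambiguous codons become X", {
  fr <- six_frame_translate("TAANNGATG")
  expect_equal(substr(fr$peptide[fr$frame == 1], 1, 2), "*X")
})

test_that("profile scores follow the closed form on identical sequences", {
  aln <- setNames(rep("MKVLW", 4), paste0("s", 1:4))
  eps <- 1e-6
  prof <- build_profile(aln, pseudocount = eps, calibrate = FALSE)
  # each consensus residue scores log2(20 (n+eps) / (n+20 eps)) -> log2(20)
  idx <- chemoguild:::encode_peptide("MKVLW")
  sc <- chemoguild:::score_windows(idx, prof$matrix, 1:5)
  expect_equal(sc, 5 * log2(20), tolerance = 1e-4)
})

test_that("the consensus outscores any single-substitution variant", {
  aln <- read_seed_alignments()[["nirK"]]
  prof <- build_profile(aln, family = "nirK", calibrate = FALSE)
  cons <- prof$consensus
  idx <- chemoguild:::encode_peptide(cons)
  base <- chemoguild:::score_windows(idx, prof$matrix, seq_len(prof$length))
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in sample.int(nchar(cons), 10)) {
    v <- strsplit(cons, "")[[1]]
    v[i] <- sample(setdiff(aa, v[i]), 1)
    sc <- chemoguild:::score_windows(
      chemoguild:::encode_peptide(paste(v, collapse = "")),
      prof$matrix, seq_len(prof$length)
    )
    expect_lte(sc, base)
  }
})

test_that("profiles are invariant to sequence order and reject ragged input", {
  aln <- read_seed_alignments()[["pflB"]]
  p1 <- build_profile(aln, family = "pflB", calibrate = FALSE)
  p2 <- build_profile(rev(aln), family = "pflB", calibrate = FALSE)
  expect_identical(p1$matrix, p2$matrix)
  bad <- c(a = "MKV", b = "MK")
  expect_error(build_profile(bad), "ragged")
  expect_error(build_profile(aln[1]), "at least 2")
})

test_that("a planted minus-strand gene is found at the exact coordinates", {
  aln <- read_seed_alignments()[["pflB"]]
  prof <- build_profile(aln, family = "pflB")
  cons <- prof$consensus
  dna <- peptide_to_dna(cons)
  left <- random_dna(1500, seed = 61)
  right <- random_dna(1200, seed = 62)
  ctg <- c(planted = paste0(left, rc_str(dna), right))
  hits <- scan_profiles(list(prof), ctg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$family, "pflB")
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 1501L)
  expect_equal(hits$end, 1500L + nchar(dna))
  expect_false(hits$frameshift)

  # coordinate round trip: the addressed DNA re-translates to the peptide
  sub <- substr(ctg[["planted"]], hits$start, hits$end)
  pep <- six_frame_translate(rc_str(sub))$peptide[1]
  expect_identical(pep, cons)
})

test_that("hits are strand-symmetric with identical scores", {
  aln <- read_seed_alignments()[["nirK"]]
  prof <- build_profile(aln, family = "nirK")
  dna <- peptide_to_dna(prof$consensus)
  ctg <- c(fwd = paste0(random_dna(600, seed = 63), dna, random_dna(400, seed = 64)))
  rcv <- c(fwd = rc_str(ctg[["fwd"]]))
  h1 <- scan_profiles(list(prof), ctg)
  h2 <- scan_profiles(list(prof), rcv)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$strand, "+")
  expect_equal(h2$strand, "-")
  L <- nchar(ctg[["fwd"]])
  expect_equal(h2$start, L - h1$end + 1L)
  expect_equal(h2$end, L - h1$start + 1L)
})

test_that("random sequences of matched length and GC yield no hits", {
  aln <- read_seed_alignments()
  profs <- lapply(names(aln), function(f) build_profile(aln[[f]], family = f))
  set.seed(71)
  decoys <- setNames(
    vapply(1:15, function(i) random_dna(2400, gc = runif(1, 0.3, 0.65)), ""),
    paste0("decoy", 1:15)
  )
  expect_equal(nrow(scan_profiles(profs, decoys)), 0L)
})

test_that("a homopolymer frameshift is recovered by split-frame merging", {
  aln <- read_seed_alignments()[["nosZ"]]
  prof <- build_profile(aln, family = "nosZ")
  recovered <- 0L
  trials <- 10L
  for (t in seq_len(trials)) {
    dna <- chemoguild:::with_seed(900 + t, {
      # GC-tilted codons create homopolymers like real coding sequence
      chemoguild:::reverse_translate(prof$consensus, 0.5)
    })
    # delete one base inside a homopolymer run near the gene middle
    ch <- strsplit(dna, "")[[1]]
    r <- rle(ch)
    runstart <- cumsum(r$lengths) - r$lengths + 1L
    cand <- which(r$lengths >= 3L)
    if (length(cand) == 0) next
    pick <- cand[which.min(abs(runstart[cand] - nchar(dna) / 2))]
    dna_fs <- paste0(
      substr(dna, 1, runstart[pick] - 1),
      substr(dna, runstart[pick] + 1, nchar(dna))
    )
    ctg <- c(x = paste0(
      random_dna(700, seed = 910 + t), dna_fs,
      random_dna(500, seed = 930 + t)
    ))
    h <- scan_profiles(list(prof), ctg)
    if (nrow(h) == 1 && h$frameshift &&
      h$start < 700 + nchar(dna_fs) && h$end > 700) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered / trials, 0.8)
})

test_that("gene hit tables render the conventional columns", {
  hits <- data.frame(
    contig = "c1", family = "nosZ", contig_length = 5000L,
    start = 10L, end = 1809L, strand = "-", frame = 4L, score = 900,
    frameshift = FALSE
  )
  tab <- format_gene_table(hits)
  expect_identical(
    names(tab),
    c(
      "Contig", "Gene", "Contig length", "Gene position", "Strand",
      "Affiliation", "Activity", "Bin"
    )
  )
  expect_equal(tab$`Gene position`, "10-1809")
})
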