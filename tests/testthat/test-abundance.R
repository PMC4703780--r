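# Read mapping, coverage and abundance estimation.

test_that("an exact substring read maps to the right place", {
  ctg <- c(cA = random_dna(2000, seed = 1), cB = random_dna(2000, seed = 2))
  rd <- c(r1 = substr(ctg[["cA"]], 501, 600))
  asg <- assign_reads(rd, ctg)
  expect_equal(asg$contig, "cA")
  expect_equal(asg$position, 501L)
  expect_equal(asg$strand, "+")
  expect_equal(asg$matched_bases, 100L)

  rd2 <- c(r2 = rc_str(substr(ctg[["cB"]], 301, 400)))
  asg2 <- assign_reads(rd2, ctg)
  expect_equal(asg2$contig, "cB")
  expect_equal(asg2$position, 301L)
  expect_equal(asg2$strand, "-")
})

test_that("the seeded mapper agrees with exhaustive alignment on tiny inputs", {
  set.seed(33)
  ctg <- c(
    c1 = random_dna(400, seed = 10), c2 = random_dna(400, seed = 11),
    c3 = random_dna(400, seed = 12)
  )
  reads <- character(0)
  n_subs <- integer(0)
  for (i in 1:15) {
    src <- sample(names(ctg), 1)
    s <- sample(1:340, 1)
    r <- substr(ctg[[src]], s, s + 59)
    # sprinkle up to 2 substitutions
    ns <- sample(0:2, 1)
    ch <- strsplit(r, "")[[1]]
    for (j in sample(1:60, ns)) {
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    }
    r <- paste(ch, collapse = "")
    if (runif(1) < 0.5) r <- rc_str(r)
    reads[sprintf("r%02d", i)] <- r
    n_subs[i] <- ns
  }
  # plus 5 random reads that should mostly go unassigned
  for (i in 16:20) reads[sprintf("r%02d", i)] <- random_dna(60)
  asg <- assign_reads(reads, ctg, k = 21L, min_identity = 0.9)
  oracle <- brute_force_assign(reads, ctg, min_identity = 0.9)
  # the seeded mapper can only miss placements with no exact 21-mer seed;
  # wherever it assigns, it must match the oracle exactly
  for (i in seq_along(reads)) {
    if (is.na(asg$contig[i])) next
    expect_identical(asg$contig[i], oracle$contig[i])
    expect_identical(asg$position[i], oracle$position[i])
    expect_identical(asg$strand[i], oracle$strand[i])
    expect_identical(asg$matched_bases[i], oracle$matched_bases[i])
  }
  # reads with at most one substitution always keep a clean seed k-mer,
  # so the seeded mapper must find exactly what the oracle finds
  low <- which(n_subs <= 1)
  expect_identical(is.na(asg$contig[low]), is.na(oracle$contig[low]))
})

test_that("at 1% error nearly all reads map to their true contig", {
  comm <- generate_community(three_pop_spec(seed = 31L, n_dna_reads = 3000L))
  spec <- three_pop_spec(seed = 31L, n_dna_reads = 3000L)
  fr <- fragment_genomes(comm$genomes, 5000L, 1000L, seed = 31L)
  sim <- simulate_reads(comm$genomes, comm$abundances, spec)
  asg <- assign_reads(sim$reads, fr$contigs)
  # true contig: the one containing the read midpoint
  mid <- (sim$truth$start + sim$truth$end) %/% 2
  truec <- vapply(seq_len(nrow(sim$truth)), function(i) {
    m <- fr$map[fr$map$population == sim$truth$population[i], ]
    m$contig[m$genome_start <= mid[i] & mid[i] <= m$genome_end]
  }, character(1))
  ok <- !is.na(asg$contig) & asg$contig == truec
  expect_gte(mean(ok), 0.95)
})

test_that("empty contig set warns and leaves reads unassigned", {
  rd <- c(r1 = random_dna(60, seed = 1))
  expect_warning(asg <- assign_reads(rd, character(0)), "unassigned")
  expect_true(is.na(asg$contig))
})

test_that("coverage is assigned bases over contig length", {
  asg <- data.frame(
    read_id = sprintf("r%d", 1:10), contig = "c1", position = 1L,
    strand = "+", matched_bases = 100L, read_length = 100L
  )
  cov <- contig_coverage(asg, c(c1 = 1000L, c2 = 500L))
  expect_equal(unname(cov["c1"]), 1.0)
  expect_equal(unname(cov["c2"]), 0.0)
})

test_that("bin abundance is the assigned-base fraction", {
  lens <- c(a = 100L, b = 100L, c = 100L)
  cov <- c(a = 3, b = 1, c = 1)
  asg <- data.frame(contig = c("a", "b", "c"), bin = c("b1", "b2", "b3"))
  ab <- bin_abundance(cov, asg, lens)
  expect_equal(ab$abundance, c(0.6, 0.2, 0.2))
  expect_equal(sum(ab$abundance), 1, tolerance = 1e-9)

  # splitting a contig changes nothing (coverage x length is additive)
  lens2 <- c(a1 = 40L, a2 = 60L, b = 100L, c = 100L)
  cov2 <- c(a1 = 3, a2 = 3, b = 1, c = 1)
  asg2 <- data.frame(
    contig = c("a1", "a2", "b", "c"), bin = c("b1", "b1", "b2", "b3")
  )
  ab2 <- bin_abundance(cov2, asg2, lens2)
  expect_equal(ab2$abundance, ab$abundance)

  expect_error(
    bin_abundance(c(a = 0, b = 0, c = 0), asg, lens),
    "no signal"
  )
})

test_that("unbinned mass is reported and both normalizations sum to 1", {
  lens <- c(a = 100L, b = 100L, u = 100L)
  cov <- c(a = 2, b = 2, u = 1)
  asg <- data.frame(contig = c("a", "b", "u"), bin = c("b1", "b2", "unbinned"))
  ab <- bin_abundance(cov, asg, lens)
  expect_equal(ab$abundance[ab$bin == "unbinned"], 0.2)
  expect_equal(sum(ab$abundance), 1, tolerance = 1e-9)
  expect_equal(
    sum(ab$abundance_binned_only[ab$bin != "unbinned"]), 1,
    tolerance = 1e-9
  )
})
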