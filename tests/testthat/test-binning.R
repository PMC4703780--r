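# Tetranucleotide signatures, GC, profile fragments, N50, clustering and
# bin statistics.

test_that("tetra_signature handles hand-countable cases", {
  s <- tetra_signature("AAAA")
  expect_equal(sum(s), 1)
  expect_equal(unname(s["AAAA"]), 1)
  expect_equal(attr(s, "n_kmers"), 1)

  # ACGTACGT: 5 overlapping 4-mers; ACGT occurs at positions 1, 5 and is
  # self-complementary; CGTA/TACG merge, GTAC is self-complementary
  s2 <- tetra_signature("ACGTACGT")
  expect_equal(attr(s2, "n_kmers"), 5)
  expect_equal(unname(s2["ACGT"]), 2 / 5)

  # windows containing ambiguous symbols are skipped
  s3 <- tetra_signature("ACGTNACGT")
  expect_equal(attr(s3, "n_kmers"), 2)
  expect_error(tetra_signature("NNNNNN"), "no countable 4-mers")
})

test_that("signatures are reverse-complement invariant", {
  set.seed(42)
  for (i in 1:10) {
    s <- random_dna(500, gc = runif(1, 0.3, 0.7))
    expect_equal(tetra_signature(s), tetra_signature(rc_str(s)))
  }
})

test_that("gc_content matches hand computation and ignores ambiguity", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AATGC"), 40)
  expect_equal(gc_content("AANNTGC"), 40)
  expect_error(gc_content("NNN"), "GC undefined")
})

test_that("fragment_for_profile keeps remainders of at least half length", {
  ctg <- c(c1 = random_dna(1250, seed = 1))
  fr <- fragment_for_profile(ctg, 500L)
  expect_equal(unname(nchar(fr)), c(500L, 500L, 250L))
  fr2 <- fragment_for_profile(c(c2 = random_dna(999, seed = 2)), 500L)
  expect_equal(unname(nchar(fr2)), c(500L, 499L))
  # a 1249 bp contig drops its 249 bp remainder
  fr3 <- fragment_for_profile(c(c3 = random_dna(1249, seed = 3)), 500L)
  expect_equal(unname(nchar(fr3)), c(500L, 500L))
  expect_true(all(vapply(
    list(fr, fr2, fr3), function(x) sum(nchar(x)),
    numeric(1)
  ) <= c(1250, 999, 1249)))
})

test_that("N50 agrees with the brute-force oracle", {
  expect_equal(chemoguild:::n50(c(40, 30, 20, 10)), 30)
  expect_equal(chemoguild:::n50(77), 77)
  set.seed(7)
  for (i in 1:25) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    expect_equal(chemoguild:::n50(lens), brute_force_n50(lens))
  }
})

test_that("contigs from one genome land in one bin", {
  g <- generate_community(
    community_spec(
      list(population_spec("solo",
        genome_length = 30000L, gc = 0.45,
        abundance = 1, background_gene_count = 0L, trna_count = 0L
      )),
      seed = 3L
    )
  )
  fr <- fragment_genomes(g$genomes, 4000L, 1000L, seed = 3L)
  cov <- setNames(rep(10, length(fr$contigs)), names(fr$contigs))
  bins <- cluster_contigs(fr$contigs, cov, k = 1L)
  expect_true(all(bins$bin == "bin_01"))
})

test_that("well-separated synthetic populations are recovered (ARI >= 0.95)", {
  comm <- generate_community(three_pop_spec(seed = 21L))
  fr <- fragment_genomes(comm$genomes, 5000L, 1000L, seed = 21L)
  # coverage from truth proportions (5/20/80x), no mapping needed here
  covmap <- c(pop01 = 5, pop02 = 20, pop03 = 80)
  cov <- setNames(
    covmap[fr$map$population[match(names(fr$contigs), fr$map$contig)]],
    names(fr$contigs)
  )
  bins <- cluster_contigs(fr$contigs, cov)
  truth <- fr$map$population[match(bins$contig, fr$map$contig)]
  ari <- mclust::adjustedRandIndex(bins$bin, truth)
  expect_gte(ari, 0.95)
})

test_that("clustering is invariant to contig input order", {
  comm <- generate_community(three_pop_spec(seed = 22L))
  fr <- fragment_genomes(comm$genomes, 5000L, 1000L, seed = 22L)
  covmap <- c(pop01 = 5, pop02 = 20, pop03 = 80)
  cov <- setNames(
    covmap[fr$map$population[match(names(fr$contigs), fr$map$contig)]],
    names(fr$contigs)
  )
  bins1 <- cluster_contigs(fr$contigs, cov, k = 3L)
  set.seed(1)
  perm <- sample(length(fr$contigs))
  bins2 <- cluster_contigs(fr$contigs[perm], cov[perm], k = 3L)
  bins2 <- bins2[match(bins1$contig, bins2$contig), ]
  expect_identical(bins1$bin, bins2$bin)
})

test_that("short contigs stay unbinned and the partition is complete", {
  contigs <- c(
    a = random_dna(3000, seed = 1), b = random_dna(3000, seed = 2),
    c = random_dna(500, seed = 3)
  )
  cov <- c(a = 10, b = 10, c = 10)
  bins <- cluster_contigs(contigs, cov, min_contig_len = 1000L, k = 2L)
  expect_equal(bins$bin[bins$contig == "c"], "unbinned")
  expect_setequal(bins$contig, names(contigs))
  st <- bin_stats(bins, contigs, cov, include_unbinned = TRUE)
  expect_equal(sum(st$size_bp), sum(nchar(contigs)))
})

test_that("bin statistics and display headers are correct", {
  contigs <- c(
    a = random_dna(4000, gc = 0.6, seed = 4), b = random_dna(3000, gc = 0.6, seed = 5),
    c = random_dna(2000, gc = 0.6, seed = 6), d = random_dna(1000, gc = 0.6, seed = 7)
  )
  asg <- data.frame(contig = letters[1:4], bin = "bin_01")
  cov <- setNames(c(2, 4, 6, 8), letters[1:4])
  st <- bin_stats(asg, contigs, cov)
  expect_equal(st$size_bp, 10000L)
  expect_equal(st$n_contigs, 4L)
  expect_equal(st$n50_bp, brute_force_n50(nchar(contigs)))
  expect_equal(
    st$mean_coverage,
    sum(cov * nchar(contigs)) / sum(nchar(contigs))
  )
  tab <- format_bin_table(st)
  expect_identical(
    names(tab)[1:5],
    c(
      "Bin", "Size (kb)", "Number of contigs (#)",
      "N50 contig length (kb)", "GC content (%)"
    )
  )
  blob <- blob_table(asg, contigs, cov)
  expect_equal(nrow(blob), 4L)
  expect_true(all(blob$gc > 0 & blob$gc < 100))
})
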