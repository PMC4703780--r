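# RNA counting and the per-bin activity normalization contract.

mk_asg <- function(contig, position, read_length = 100L) {
  data.frame(
    read_id = sprintf("r%03d", seq_along(position)), contig = contig,
    position = position, strand = "+", matched_bases = read_length,
    read_length = read_length, stringsAsFactors = FALSE
  )
}

mk_genes <- function(ids, starts, ends, contig = "c1") {
  data.frame(
    contig = contig, start = starts, end = ends, strand = "+",
    gene_id = ids, class = "background", family = NA_character_,
    expression = NA_real_, stringsAsFactors = FALSE
  )
}

test_that("reads count toward the gene containing their midpoint", {
  genes <- mk_genes(c("gA", "gB"), c(101L, 1001L), c(600L, 1500L))
  # 10 reads with midpoints inside gA
  asg <- mk_asg("c1", rep(151L, 10))
  out <- count_rna(asg, genes)
  expect_equal(out$counts$count[out$counts$gene_id == "gA"], 10L)
  expect_equal(out$intergenic, 0L)

  # a read whose midpoint lands exactly on the gene start base counts in
  # (position 52, length 100 -> midpoint 101)
  out2 <- count_rna(mk_asg("c1", 52L), genes)
  expect_equal(out2$counts$count[out2$counts$gene_id == "gA"], 1L)

  # midpoint just before the gene is intergenic
  out3 <- count_rna(mk_asg("c1", 51L), genes)
  expect_equal(sum(out3$counts$count), 0L)
  expect_equal(out3$intergenic, 1L)
})

test_that("overlapping genes resolve to the smaller id and are flagged", {
  genes <- mk_genes(c("gB", "gA"), c(100L, 150L), c(400L, 450L))
  out <- count_rna(mk_asg("c1", 151L), genes) # midpoint 200: inside both
  expect_equal(out$counts$count[out$counts$gene_id == "gA"], 1L)
  expect_equal(out$counts$count[out$counts$gene_id == "gB"], 0L)
  expect_true(out$counts$ambiguous[out$counts$gene_id == "gA"])
})

test_that("activities are densities over the bin mean density", {
  counts <- data.frame(gene_id = c("g1", "g2"), count = c(20L, 10L))
  lens <- c(g1 = 1000L, g2 = 1000L)
  bins <- c(g1 = "A", g2 = "A")
  act <- normalize_activity(counts, lens, bins)
  expect_equal(act$activity, c(4 / 3, 2 / 3))
  expect_equal(mean(act$activity), 1, tolerance = 1e-9)

  eq <- normalize_activity(
    data.frame(gene_id = c("g1", "g2"), count = c(5L, 5L)), lens, bins
  )
  expect_equal(eq$activity, c(1, 1))
})

test_that("the per-bin mean of defined activities is exactly 1", {
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    counts <- data.frame(
      gene_id = sprintf("g%03d", 1:n),
      count = rpois(n, lambda = sample(c(0.5, 3, 20), 1))
    )
    lens <- setNames(sample(300:3000, n), counts$gene_id)
    bins <- setNames(sample(c("A", "B", "C"), n, TRUE), counts$gene_id)
    act <- normalize_activity(counts, lens, bins)
    for (b in unique(bins)) {
      a <- act$activity[act$bin == b]
      if (all(is.na(a))) next
      expect_equal(mean(a), 1, tolerance = 1e-9)
    }
    # scale invariance: multiplying counts in one bin leaves activities put
    counts2 <- counts
    sel <- bins[counts$gene_id] == "A"
    counts2$count[sel] <- counts2$count[sel] * 7L
    act2 <- normalize_activity(counts2, lens, bins)
    expect_equal(
      act2$activity[act2$bin == "A"], act$activity[act$bin == "A"],
      tolerance = 1e-12
    )
  }
})

test_that("bins without signal give missing activities", {
  counts <- data.frame(gene_id = c("g1", "g2"), count = c(0L, 0L))
  act <- normalize_activity(
    counts, c(g1 = 500L, g2 = 800L), c(g1 = "A", g2 = "A")
  )
  expect_true(all(is.na(act$activity)))
  expect_error(
    normalize_activity(counts, c(g1 = 0L, g2 = 800L), c(g1 = "A", g2 = "A")),
    "length"
  )
})

test_that("expressed-only averaging gives NA to silent genes", {
  counts <- data.frame(gene_id = c("g1", "g2", "g3"), count = c(10L, 10L, 0L))
  lens <- c(g1 = 1000L, g2 = 1000L, g3 = 1000L)
  bins <- c(g1 = "A", g2 = "A", g3 = "A")
  act <- normalize_activity(counts, lens, bins, expressed_only = TRUE)
  expect_equal(act$activity[1:2], c(1, 1))
  expect_true(is.na(act$activity[3]))
})

test_that("simulated transcription is recovered (Spearman >= 0.9)", {
  spec <- three_pop_spec(seed = 51L, n_rna_reads = 8000L)
  comm <- generate_community(spec)
  fr <- fragment_genomes(comm$genomes, 5000L, 1000L, seed = 51L, genes = comm$genes)
  rna <- simulate_transcriptome(comm$genomes, comm$genes, spec)
  asg <- assign_reads(rna$reads, fr$contigs)
  counts <- count_rna(asg, fr$genes)
  lens <- setNames(fr$genes$end - fr$genes$start + 1L, fr$genes$gene_id)
  expressed <- fr$genes[!is.na(fr$genes$expression), ]
  dens <- counts$counts$count[match(expressed$gene_id, counts$counts$gene_id)] /
    lens[expressed$gene_id]
  expect_gte(cor(dens, expressed$expression, method = "spearman"), 0.9)
})
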