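test_that("classify_window returns the deepest node on the path", {
  tr <- family_tree()
  expect_equal(classify_window(c(20, 30, 30), tr), 30)
  expect_equal(classify_window(c(1, 1, 1), tr), 1)
  expect_equal(classify_window(c(10, 20, 41), tr), 41)
  expect_equal(classify_window(42, tr), 42)  # single k-mer -> its taxid
  expect_error(classify_window(c(30, 31), tr), "single root-to-leaf")
  expect_error(classify_window(integer(0), tr), "at least one")
})

test_that("classify_read follows the maximal-weight root-to-leaf path", {
  tr <- toy_tree()
  # hits {S1 x3, S2 x1, G x2}: path through S1 weighs 5 > 3
  expect_equal(classify_read(c(3, 3, 3, 4, 2, 2), tr), 3)
  # tie between the two species paths resolves to their LCA
  expect_equal(classify_read(c(3, 4), tr), 2)
  expect_equal(classify_read(c(3, 3, 4, 4, 2), tr), 2)
  expect_equal(classify_read(integer(0), tr), 0L)
  # single-path hit lists reduce to classify_window
  expect_equal(classify_read(c(2, 3, 3), tr), classify_window(c(2, 3, 3), tr))
  # swapping the sister hit counts swaps the answer symmetrically
  expect_equal(classify_read(c(4, 4, 4, 3, 2, 2), tr), 4)
})

test_that("classify_read agrees with brute-force path enumeration", {
  tr <- family_tree()
  set.seed(9)
  for (i in 1:200) {
    hits <- sample(tr$taxid, sample(0:6, 1), replace = TRUE)
    expect_equal(classify_read(hits, tr), oracle_classify_read(hits, tr),
                 info = paste(hits, collapse = ","))
  }
})

test_that("window sliding reproduces the worked toy distribution", {
  tr <- toy_tree()
  gA <- genome_record(3, "AAACC")
  idx <- build_kmer_index(list(gA, genome_record(4, "AAAGG")), k = 3, tr)
  d <- compute_genome_distribution(gA, idx, tr, r = 3)
  expect_equal(d$num_windows, 3L)
  expect_equal(d$node_counts, c(`2` = 1L, `3` = 2L))
  expect_equal(d$node_fractions[["2"]], 1 / 3)
  expect_equal(d$unique_fraction, 2 / 3)
  # genomes fully unique to themselves have U = 1
  dB <- compute_genome_distribution(
    genome_record(4, "AAAGG"), idx, tr, r = 3)
  expect_equal(dB$node_counts[["2"]], 1L)
  expect_equal(dB$unique_fraction, 2 / 3)
})

test_that("distribution fractions always sum to one over integer counts", {
  tr <- family_tree()
  set.seed(41)
  shared <- random_dna(120)
  gs <- list(genome_record(41, paste0(random_dna(100), shared)),
             genome_record(42, paste0(shared, random_dna(100))),
             genome_record(32, random_dna(200)))
  idx <- build_kmer_index(gs, k = 7, tr)
  for (r in c(7, 12, 31)) {
    dist <- build_distribution(gs, idx, tr, r = r)
    for (g in dist$per_genome) {
      expect_identical(sum(g$node_counts), g$num_windows)
      expect_equal(sum(g$node_fractions), 1, tolerance = 1e-12)
      expect_true(all(names(g$node_counts) %in%
                        as.character(ancestor_path(tr, g$taxid))))
      expect_equal(g$unique_fraction,
                   unname(g$node_fractions[as.character(g$taxid)]))
    }
  }
})

test_that("self-classification matches the window-by-window oracle", {
  tr <- family_tree()
  set.seed(43)
  shared_fam <- random_dna(40)   # present in all three genomes
  shared_sg <- random_dna(40)    # present in the two sister strains
  gs <- list(
    genome_record(41, paste0(shared_fam, random_dna(60), shared_sg)),
    genome_record(42, paste0(shared_sg, random_dna(60), shared_fam)),
    genome_record(32, paste0(random_dna(50), shared_fam, random_dna(30))))
  k <- 6; r <- 10
  idx <- build_kmer_index(gs, k = k, tr)
  for (g in gs) {
    mine <- compute_genome_distribution(g, idx, tr, r = r)
    ora <- oracle_distribution(g, gs, k, r, tr)
    expect_equal(mine$num_windows, ora$num_windows)
    expect_equal(mine$node_counts[order(names(mine$node_counts))],
                 ora$node_counts[order(names(ora$node_counts))])
  }
})

test_that("at r = k the unique fraction equals the unique k-mer fraction", {
  tr <- toy_tree()
  set.seed(47)
  shared <- random_dna(50)
  gA <- genome_record(3, paste0(shared, random_dna(50)))
  gB <- genome_record(4, paste0(random_dna(50), shared))
  k <- 8
  idx <- build_kmer_index(list(gA, gB), k = k, tr)
  d <- compute_genome_distribution(gA, idx, tr, r = k)
  kms <- canonicalize(substring(gA$sequences, 1:(100 - k + 1), k:100))
  expect_equal(d$unique_fraction, mean(lookup_kmers(idx, kms) == 3L))
})

test_that("multi-contig genomes never slide windows across contigs", {
  tr <- toy_tree()
  g2 <- genome_record(3, c("ACGTACGTAC", "TTTTTTT", "ACG"))
  idx <- build_kmer_index(list(g2), k = 3, tr)
  d <- compute_genome_distribution(g2, idx, tr, r = 5)
  # contigs of length 10 and 7 give (10-5+1) + (7-5+1) windows; the 3 bp
  # contig contributes none
  expect_equal(d$num_windows, 9L)
  expect_error(compute_genome_distribution(
    genome_record(4, "ACGT"), idx, tr, r = 5), "exceeds")
  expect_error(compute_genome_distribution(g2, idx, tr, r = 2), "smaller")
})

test_that("a single-genome database is fully unique to its genome", {
  tr <- toy_tree()
  g <- genome_record(3, random_dna(400))
  idx <- build_kmer_index(list(g), k = 9, tr)
  dist <- build_distribution(list(g), idx, tr, r = 50)
  expect_equal(dist$per_genome[["3"]]$unique_fraction, 1)
  expect_equal(dist$per_genome[["3"]]$node_counts,
               c(`3` = 400L - 50L + 1L))
})

test_that("the sister-genome toy gives the symmetric genus fraction", {
  tr <- toy_tree()
  gA <- genome_record(3, "AAACC")
  gB <- genome_record(4, "AAAGG")
  idx <- build_kmer_index(list(gA, gB), k = 3, tr)
  dist <- build_distribution(list(gA, gB), idx, tr, r = 3)
  expect_equal(dist$per_genome[["3"]]$node_fractions[["2"]], 1 / 3)
  expect_equal(dist$per_genome[["4"]]$node_fractions[["2"]], 1 / 3)
})

test_that("unique_fraction reproduces the window-count arithmetic", {
  expect_equal(round(unique_fraction(250000, 1e6, 75), 2), 0.25)
  expect_equal(unique_fraction(5, 10, 6), 1)
  expect_error(unique_fraction(1, 10, 20), "exceeds")
})
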