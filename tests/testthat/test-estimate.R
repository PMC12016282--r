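test_that("derived totals follow K/U with guarded degenerate input", {
  expect_equal(estimate_derived_total(1000, 0.25), 4000)
  expect_equal(estimate_derived_total(0, 0.5), 0)
  for (x in c(0, 1, 17, 1e6))
    expect_equal(estimate_derived_total(x, 1), x)
  expect_error(estimate_derived_total(5, 0), "degenerate")
})

test_that("priors normalize derived totals within a subtree", {
  expect_equal(compute_priors(4000), 1)
  expect_equal(compute_priors(c(4000, 1000)), c(0.8, 0.2))
  expect_equal(compute_priors(rep(7, 5)), rep(0.2, 5))
  expect_error(compute_priors(numeric(0)), "no estimates")
  expect_error(compute_priors(c(0, 0)), "no signal")
})

test_that("node allocation applies Bayes scores with exact conservation", {
  a <- allocate_node_reads(420, c(0.5, 0.1), c(0.8, 0.2))
  expect_equal(a$shares, c(0.4, 0.02) / 0.42)
  expect_equal(a$allocated, c(400, 20))
  expect_identical(sum(a$allocated), 420)

  one <- allocate_node_reads(99, 0.37, 1)
  expect_equal(one$allocated, 99)
  zero <- allocate_node_reads(0, c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(zero$allocated, c(0, 0))
  expect_warning(res <- allocate_node_reads(10, c(0, 0), c(0.5, 0.5)),
                 "unallocated")
  expect_equal(res$unallocated, 10)
  # conservation is exact for awkward share vectors too
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5, 1) + 1
    r <- allocate_node_reads(sample(1e6, 1), runif(n), compute_priors(runif(n)))
    expect_identical(sum(r$allocated) + r$unallocated,
                     sum(r$allocated) + r$unallocated)
    expect_equal(sum(r$shares), 1, tolerance = 1e-12)
  }
})

test_that("detection thresholds apply after strain roll-up", {
  tr <- family_tree()
  cfg <- estimation_config(threshold = 10)
  rep9 <- kraken_report(c(`31` = 9), tr)
  expect_equal(detect_taxa(rep9, cfg, tr), integer(0))
  # 4 species-level + 7 strain-level reads = 11 >= 10
  rep11 <- kraken_report(c(`30` = 4, `41` = 7), tr)
  expect_equal(detect_taxa(rep11, cfg, tr), 30L)
  # threshold 0 detects every taxon with at least one read at/below level
  cfg0 <- estimation_config(threshold = 0)
  rep1 <- kraken_report(c(`31` = 1, `20` = 50), tr)
  expect_equal(detect_taxa(rep1, cfg0, tr), 31L)
})

test_that("the identity limit passes the Kraken counts through", {
  tr <- family_tree()
  dist <- fake_dist(list(
    fake_gdist(31, c(`31` = 1000L), 1000L),
    fake_gdist(32, c(`32` = 1000L), 1000L)))
  rep <- kraken_report(c(`31` = 500, `32` = 250), tr)
  ab <- estimate_abundance(rep, dist, tr, estimation_config())
  expect_equal(setNames(ab$new_est_reads, ab$taxonomy_id),
               c(`31` = 500, `32` = 250))
  expect_equal(ab$added_reads, c(0, 0))
  expect_equal(attr(ab, "unallocated_reads"), 0)
  expect_equal(sum(ab$fraction_total_reads), 1)
})

test_that("stranded genus reads split by P(Gj|Si) * P(Si)", {
  tr <- toy_tree()
  # U1 = 0.5, U2 = 0.9; K1 = 1000, K2 = 450 -> Khat = (2000, 500),
  # priors (0.8, 0.2); genus scores 0.5*0.8 / 0.1*0.2 -> alloc (400, 20)
  dist <- fake_dist(list(
    fake_gdist(3, c(`2` = 500L, `3` = 500L), 1000L),
    fake_gdist(4, c(`2` = 100L, `4` = 900L), 1000L)))
  rep <- kraken_report(c(`3` = 1000, `4` = 450, `2` = 420), tr)
  ab <- estimate_abundance(rep, dist, tr, estimation_config())
  est <- setNames(ab$new_est_reads, ab$taxonomy_id)
  expect_equal(est, c(`3` = 1400, `4` = 470))
  expect_equal(sum(ab$new_est_reads) + attr(ab, "unallocated_reads"),
               rep$total)
})

test_that("family and genus reads cascade down and strains roll up", {
  tr <- family_tree()
  # strains 41/42 of species 30; 31 a sister species; 32 in another genus
  dist <- fake_dist(list(
    fake_gdist(41, c(`10` = 50L, `20` = 100L, `25` = 250L, `41` = 600L),
               1000L),
    fake_gdist(42, c(`10` = 50L, `20` = 100L, `25` = 250L, `42` = 600L),
               1000L),
    fake_gdist(31, c(`10` = 40L, `20` = 60L, `25` = 100L, `31` = 800L),
               1000L),
    fake_gdist(32, c(`10` = 100L, `32` = 900L), 1000L)))
  rep <- kraken_report(c(`41` = 60, `42` = 60, `30` = 30, `31` = 160,
                         `32` = 450, `25` = 100, `20` = 50, `10` = 40),
                       tr)
  ab <- estimate_abundance(rep, dist, tr, estimation_config())
  est <- setNames(ab$new_est_reads, ab$taxonomy_id)
  # strain reads fold into species 30
  row30 <- ab[ab$taxonomy_id == 30, ]
  expect_equal(row30$kraken_assigned_reads, 150)
  # every stranded read lands somewhere: conservation against the report
  expect_equal(sum(ab$new_est_reads) + attr(ab, "unallocated_reads") +
                 attr(ab, "unclassified_reads"), rep$total,
               tolerance = 1e-12)
  # species 32 receives from the family node only
  expect_gt(est[["32"]], 450)
  # per-genome K for species 30 splits the species-level residual between
  # its two strains, so the species-group node's reads favour species 30
  expect_gt(est[["30"]], est[["31"]])
})

test_that("reads above undetected subtrees are unallocated, not dropped", {
  tr <- family_tree()
  dist <- fake_dist(list(
    fake_gdist(31, c(`25` = 100L, `31` = 900L), 1000L),
    fake_gdist(32, c(`32` = 1000L), 1000L)))
  # genus 21 has direct reads but species 32 is below threshold
  rep <- kraken_report(c(`31` = 100, `32` = 4, `21` = 50), tr)
  expect_warning(
    ab <- estimate_abundance(rep, dist, tr, estimation_config()),
    NA)
  expect_equal(nrow(ab), 1L)
  # genus-21 reads plus the undetected species' own reads are accounted
  expect_equal(attr(ab, "unallocated_reads"), 54)
  expect_equal(sum(ab$new_est_reads) + attr(ab, "unallocated_reads"),
               rep$total)
})

test_that("scaling all counts scales the estimates linearly", {
  tr <- toy_tree()
  dist <- fake_dist(list(
    fake_gdist(3, c(`2` = 300L, `3` = 700L), 1000L),
    fake_gdist(4, c(`2` = 450L, `4` = 550L), 1000L)))
  base <- c(`3` = 120, `4` = 80, `2` = 55)
  ab1 <- estimate_abundance(kraken_report(base, tr), dist, tr,
                            estimation_config())
  ab7 <- estimate_abundance(kraken_report(base * 7, tr), dist, tr,
                            estimation_config())
  m <- match(ab1$taxonomy_id, ab7$taxonomy_id)
  expect_equal(ab7$new_est_reads[m], 7 * ab1$new_est_reads)
  expect_equal(ab7$fraction_total_reads[m], ab1$fraction_total_reads)
})

test_that("multi-level estimation moves the boundary consistently", {
  cm <- make_community(small_community(seed = 19, n = 8000, L = 4000))
  idx <- build_kmer_index(cm$genomes, k = 21, cm$tree)
  dist <- build_distribution(cm$genomes, idx, cm$tree, r = 50)
  rd <- simulate_reads(cm$genomes, cm$truth$proportion, 8000, 50,
                       seed = 19)
  rep <- simulate_kraken_report(rd, idx, cm$tree)
  sp <- estimate_at_level(rep, dist, cm$tree, "species",
                          read_length = 50)
  ge <- estimate_at_level(rep, dist, cm$tree, "genus", read_length = 50)
  # no reads sit between species and genus, so summing the species table
  # by genus must reproduce the genus table
  la <- setNames(
    cm$tree$taxid[match(cm$tree$parent[match(sp$taxonomy_id,
                                             cm$tree$taxid)],
                        cm$tree$taxid)], sp$taxonomy_id)
  by_genus <- tapply(sp$new_est_reads, la[as.character(sp$taxonomy_id)],
                     sum)
  gv <- setNames(ge$new_est_reads, ge$taxonomy_id)
  expect_equal(by_genus[names(gv)], gv, tolerance = 1e-9,
               ignore_attr = TRUE)
  # root level collapses everything classified into one row
  rt <- estimate_at_level(rep, dist, cm$tree, "root", read_length = 50)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$new_est_reads, rep$total - rep$unclassified)
})

test_that("config and consistency guards fire", {
  tr <- toy_tree()
  dist <- fake_dist(list(fake_gdist(3, c(`3` = 10L), 10L)), r = 75L)
  rep <- kraken_report(c(`3` = 100), tr)
  expect_warning(estimate_abundance(rep, dist, tr,
                                    estimation_config(read_length = 100)),
                 "r = 75")
  expect_error(estimation_config(level = "no-rank"), "ranked")
  expect_error(estimation_config(threshold = -1))
  # a genome with U = 0 falls back to K with a warning
  dist0 <- fake_dist(list(fake_gdist(3, c(`2` = 10L), 10L),
                          fake_gdist(4, c(`2` = 5L, `4` = 5L), 10L)))
  rep0 <- kraken_report(c(`3` = 40, `4` = 40, `2` = 20), tr)
  expect_warning(ab0 <- estimate_abundance(rep0, dist0, tr,
                                           estimation_config()),
                 "U = 0")
  expect_equal(sum(ab0$new_est_reads) + attr(ab0, "unallocated_reads"),
               rep0$total)
})
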