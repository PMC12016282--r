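# Fixtures built in code: tiny taxonomies, toy genomes, and hand-made
# distribution objects used across the test files.

# root -> genus(2) -> species 3, 4     (the minimal two-sister tree)
toy_tree <- function() {
  load_taxonomy(c("1 | 1 | root |",
                  "2 | 1 | genus |",
                  "3 | 2 | species |",
                  "4 | 2 | species |"))
}

# A Mycobacteriaceae-like shape: family with two genera, a species group,
# three species, and two strain leaves under species 30.
family_tree <- function() {
  load_taxonomy(c(
    "1 | 1 | root |",
    "10 | 1 | family |",
    "20 | 10 | genus |",
    "21 | 10 | genus |",
    "25 | 20 | species group |",
    "30 | 25 | species |",
    "31 | 25 | species |",
    "32 | 21 | species |",
    "41 | 30 | strain |",
    "42 | 30 | strain |"),
    c("1 | root |", "10 | Mycofam |", "20 | Mycogenus |",
      "21 | Altgenus |", "25 | tuberculosis complex |",
      "30 | species thirty |", "31 | species thirtyone |",
      "32 | species thirtytwo |", "41 | strain fortyone |",
      "42 | strain fortytwo |"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-built genome_distribution (fields per the documented contract)
fake_gdist <- function(taxid, node_counts, num_windows) {
  structure(list(taxid = taxid, num_windows = num_windows,
                 node_counts = node_counts,
                 node_fractions = node_counts / num_windows,
                 unique_fraction = {
                   x <- node_counts[as.character(taxid)]
                   if (is.na(x)) 0 else unname(x / num_windows)
                 }),
            class = "genome_distribution")
}

fake_dist <- function(per_genome, k = 31L, r = 75L) {
  names(per_genome) <- vapply(per_genome, function(g)
    as.character(g$taxid), "")
  structure(list(k = k, read_length = r, per_genome = per_genome),
            class = "kmer_distribution")
}

# small community used by several tests: 5 species, one 99.9%-identical
# sister pair stranding reads at the genus (no species-group node)
small_community <- function(seed = 11, n = 20000L, L = 8000L,
                            shared = 0.999, group = FALSE) {
  sp <- data.frame(
    name = c("sis a", "sis b", "solo c", "solo d", "solo e"),
    genus = c("G1", "G1", "G2", "G3", "G4"),
    length = L, proportion = rep(0.2, 5), stringsAsFactors = FALSE)
  community_spec(sp,
                 sisters = list(c(list(a = "sis a", b = "sis b",
                                       shared_fraction = shared,
                                       block_length = 1L),
                                  if (group) list(group_name = "ab group"))),
                 total_reads = n, read_length = 75L, error_rate = 0,
                 seed = seed)
}

realized_truth <- function(reads) {
  tab <- table(reads$taxid)
  data.frame(taxid = as.integer(names(tab)), reads = as.numeric(tab))
}
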