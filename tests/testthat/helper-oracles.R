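# Independent brute-force oracles.  These re-derive every quantity from
# first principles (string scanning, path enumeration) and share no code
# with the package internals they check.

oracle_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# path from root to t by following parent links upward
oracle_path <- function(tree, t) {
  p <- t
  while (TRUE) {
    i <- match(p[1L], tree$taxid)
    par <- tree$parent[i]
    if (par == p[1L]) break
    p <- c(par, p)
  }
  p
}

oracle_lca <- function(tree, taxids) {
  paths <- lapply(taxids, oracle_path, tree = tree)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# does any strand of any contig of `genome` contain k-mer w?
oracle_occurs <- function(w, genome) {
  any(vapply(genome$sequences, function(s)
    grepl(w, s, fixed = TRUE) ||
      grepl(oracle_revcomp(w), s, fixed = TRUE), NA))
}

# brute-force index: canonical k-mer -> LCA of all genomes containing it
oracle_index <- function(genomes, k, tree) {
  all_km <- unique(unlist(lapply(genomes, function(g)
    unlist(lapply(g$sequences, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      km <- substring(s, 1:(n - k + 1L), k:n)
      oracle_canonical(km[!grepl("[^ACGT]", km)])
    })))))
  tax <- vapply(all_km, function(w) {
    hit <- vapply(genomes, oracle_occurs, NA, w = w)
    oracle_lca(tree, vapply(genomes[hit], `[[`, 0L, "taxid"))
  }, 0L)
  setNames(tax, all_km)
}

# brute-force self-classification of every window of one genome: re-derive
# each window's k-mer set from scratch and take the deepest assigned node
oracle_distribution <- function(genome, genomes, k, r, tree) {
  oi <- oracle_index(genomes, k, tree)
  counts <- list()
  total <- 0L
  for (s in genome$sequences) {
    n <- nchar(s)
    if (n < r) next
    for (w in 1:(n - r + 1L)) {
      win <- substr(s, w, w + r - 1L)
      km <- substring(win, 1:(r - k + 1L), k:r)
      km <- oracle_canonical(km[!grepl("[^ACGT]", km)])
      tax <- unname(oi[km])
      node <- if (!length(tax)) tree$root else {
        depths <- vapply(tax, function(t) length(oracle_path(tree, t)), 0L)
        tax[which.max(depths)]
      }
      key <- as.character(node)
      counts[[key]] <- (counts[[key]] %||0% 0L) + 1L
      total <- total + 1L
    }
  }
  list(node_counts = unlist(counts), num_windows = total)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# brute-force read classification: enumerate every root-to-leaf path,
# weight it by the hits it contains, return the deepest hit on the best
# path(s), ties resolved to the LCA of the tied answers
oracle_classify_read <- function(kmer_taxids, tree) {
  kmer_taxids <- kmer_taxids[!is.na(kmer_taxids)]
  if (!length(kmer_taxids)) return(0L)
  leaves <- tree$taxid[vapply(tree$children, length, 0L) == 0L]
  best_w <- -1L
  answers <- integer(0)
  for (lf in leaves) {
    path <- oracle_path(tree, lf)
    on <- kmer_taxids[kmer_taxids %in% path]
    if (!length(on)) next
    w <- length(on)
    deepest <- on[which.max(vapply(on, function(t)
      length(oracle_path(tree, t)), 0L))]
    if (w > best_w) { best_w <- w; answers <- deepest }
    else if (w == best_w) answers <- union(answers, deepest)
  }
  if (!length(answers)) return(0L)
  if (length(answers) == 1L) answers else oracle_lca(tree, answers)
}
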