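# Self-classification of database genomes: slide a window of length r
# (a pseudo-read) across every genome, classify each window against the
# index built from those same genomes, and record where reads from each
# genome end up in the taxonomy.  The resulting per-genome fractions
# P(Gj|Si) and unique fractions U_Si are everything the redistribution
# engine needs, and are reusable across samples.

#' Classify a window drawn from a database genome
#'
#' For a window of a genome that is itself in the database, every k-mer is
#' assigned somewhere on the path from the genome's taxid to the root, so
#' the highest-weighted root-to-leaf path ends at the deepest assigned
#' node; that node is the classification.
#'
#' @param kmer_taxids non-empty integer vector of the window's k-mer
#'   assignments; all must lie on a single root-to-leaf path.
#' @param tree a `taxonomy_tree`.
#' @return The deepest taxid in the list.
#' @export
classify_window <- function(kmer_taxids, tree) {
  if (!length(kmer_taxids)) stop("classify_window needs at least one k-mer")
  idx <- .ti(tree, kmer_taxids)
  deepest <- kmer_taxids[which.max(tree$depth[idx])]
  if (!all(kmer_taxids %in% ancestor_path(tree, deepest)))
    stop("k-mer taxids do not lie on a single root-to-leaf path; ",
         "use classify_read()")
  deepest
}

#' Classify an arbitrary read from its k-mer hits
#'
#' General Kraken-style classification: each root-to-leaf path is weighted
#' by the number of k-mer hits lying on it, and the read is assigned to the
#' deepest hit node of the maximal-weight path.  Ties between paths resolve
#' to the LCA of the tied deepest nodes; an empty hit list is unclassified.
#'
#' @param kmer_taxids integer vector of k-mer assignments (may be empty or
#'   span multiple paths, as happens for reads with sequencing errors).
#' @param tree a `taxonomy_tree`.
#' @return A taxid, or `0L` for unclassified.
#' @export
classify_read <- function(kmer_taxids, tree) {
  kmer_taxids <- kmer_taxids[!is.na(kmer_taxids)]
  if (!length(kmer_taxids)) return(0L)
  tab <- table(kmer_taxids)
  hits <- as.integer(names(tab))
  wts <- as.integer(tab)
  # weight of the best path through hit t = hits on t's ancestor path
  pw <- vapply(hits, function(t)
    sum(wts[hits %in% ancestor_path(tree, t)]), 0L)
  best <- hits[pw == max(pw)]
  # drop tied candidates that are ancestors of other tied candidates
  if (length(best) > 1L) {
    keep <- vapply(best, function(t)
      !any(best != t & vapply(best, function(o)
        t %in% ancestor_path(tree, o) && o != t, NA)), NA)
    best <- best[keep]
  }
  if (length(best) == 1L) best else Reduce(function(a, b) lca(tree, a, b), best)
}

#' Unique fraction of a genome
#'
#' The proportion of a genome's length-r windows classified to the genome's
#' own node rather than to an ancestor: `n_unique / (L - r + 1)`.
#'
#' @param n_unique number of windows classified to the genome's own taxid.
#' @param genome_length genome length L in bases.
#' @param read_length window/read length r.
#' @return Fraction in `[0, 1]`.
#' @examples
#' unique_fraction(250000, 1e6, 75)  # ~0.25
#' @export
unique_fraction <- function(n_unique, genome_length, read_length) {
  w <- genome_length - read_length + 1
  if (w <= 0) stop("read length exceeds genome length")
  n_unique / w
}

#' Self-classify all length-r windows of one genome
#'
#' Slides every window of length `r` across the genome (windows never span
#' contig boundaries), classifies each with [classify_window()] semantics,
#' and tallies how many windows land on each node of the genome's
#' root-to-leaf path.
#'
#' @param genome a [genome_record()] present in the index build set.
#' @param index the `kmer_index` built from the same genomes.
#' @param tree a `taxonomy_tree`.
#' @param r window (read) length; must satisfy `k <= r <= contig length`
#'   for at least one contig.
#' @return A `genome_distribution`: fields `taxid`, `num_windows`,
#'   `node_counts` (windows per ancestor node), `node_fractions`
#'   (`P(Gj|Si)`), and `unique_fraction` (`U_Si`).
#' @export
compute_genome_distribution <- function(genome, index, tree, r = 75L) {
  k <- index$k
  r <- as.integer(r)
  if (r < k) stop("window length r = ", r, " is smaller than k = ", k)
  contigs <- genome$sequences[nchar(genome$sequences) >= r]
  if (!length(contigs))
    stop("window length r = ", r, " exceeds every contig of genome taxid ",
         genome$taxid, " (", genome$name, ")")
  li <- .ti(tree, genome$taxid)
  path <- tree$paths[[li]]
  counts <- integer(length(path))
  total_w <- 0L
  m <- r - k + 1L  # k-mers per window
  for (seq in contigs) {
    km <- .contig_kmers(seq, k, keep_na = TRUE)
    tax <- rep(NA_integer_, length(km))
    ok <- !is.na(km)
    tax[ok] <- lookup_kmers(index, km[ok])
    off <- !is.na(tax) & !(tax %in% path)
    if (any(off))
      stop("index assigns a k-mer of genome ", genome$taxid,
           " off its root-to-leaf path; was the index built from ",
           "these genomes?")
    # on a single path, depth identifies the node: sliding max of depths
    d <- rep(NA_integer_, length(km))
    d[!is.na(tax)] <- tree$depth[match(tax[!is.na(tax)], tree$taxid)]
    w <- nchar(seq) - r + 1L
    shifts <- lapply(seq_len(m) - 1L, function(s) d[(1L + s):(w + s)])
    wd <- suppressWarnings(do.call(pmax, c(shifts, list(na.rm = TRUE))))
    wd[!is.finite(wd)] <- 0L  # windows with no usable k-mer fall to the root
    counts <- counts + tabulate(wd + 1L, nbins = length(path))
    total_w <- total_w + w
  }
  nz <- counts > 0L
  structure(list(taxid = genome$taxid,
                 num_windows = total_w,
                 node_counts = stats::setNames(counts[nz], path[nz]),
                 node_fractions = stats::setNames(counts[nz] / total_w,
                                                  path[nz]),
                 unique_fraction = counts[length(path)] / total_w),
            class = "genome_distribution")
}

#' Build the k-mer distribution for a whole database
#'
#' Runs [compute_genome_distribution()] for every genome used to build the
#' index (self-classification), producing the distribution consumed by
#' [estimate_abundance()].  Computed once per (database, r) and reusable
#' for any sample.
#'
#' @inheritParams compute_genome_distribution
#' @param genomes list of [genome_record()] objects, the index build set.
#' @return A `kmer_distribution`: fields `k`, `read_length`, and
#'   `per_genome` (named list of `genome_distribution` keyed by taxid).
#' @export
build_distribution <- function(genomes, index, tree, r = 75L) {
  per <- lapply(genomes, compute_genome_distribution,
                index = index, tree = tree, r = r)
  names(per) <- vapply(per, function(g) as.character(g$taxid), "")
  structure(list(k = index$k, read_length = as.integer(r),
                 per_genome = per),
            class = "kmer_distribution")
}

#' @export
print.kmer_distribution <- function(x, ...) {
  u <- vapply(x$per_genome, `[[`, 0, "unique_fraction")
  cat("kmer_distribution: k =", x$k, "| r =", x$read_length, "|",
      length(x$per_genome), "genomes\n")
  if (length(u))
    cat(sprintf("  unique fractions: min %.4f, median %.4f, max %.4f\n",
                min(u), stats::median(u), max(u)))
  invisible(x)
}

#' @export
print.genome_distribution <- function(x, ...) {
  cat("genome_distribution: taxid", x$taxid, "|", x$num_windows,
      "windows | U =", sprintf("%.4f", x$unique_fraction), "\n")
  for (i in seq_along(x$node_counts))
    cat(sprintf("  node %s: %d windows (%.4f)\n", names(x$node_counts)[i],
                x$node_counts[i], x$node_fractions[i]))
  invisible(x)
}
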