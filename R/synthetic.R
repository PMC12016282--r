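# Seeded mock communities with known truth: a small taxonomy, genomes with
# controlled sharing between designated sister species, simulated reads,
# and the Kraken-style report a k-mer LCA classifier would produce.

# evaluate `code` under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specify a mock community
#'
#' @param species data frame with columns `name`, `genus`, `length`
#'   (genome length in bases) and `proportion` (mixture proportions,
#'   summing to 1).
#' @param sisters list of sister-pair specs, each a list with elements
#'   `a`, `b` (species names), `shared_fraction` in `[0, 1)` (fraction of
#'   the genome copied verbatim between the pair), optional `block_length`
#'   (length of each unique block, default 1: scattered SNP-like
#'   divergence) and optional `group_name` (adds a species-group node
#'   above the pair, as taxonomies do for near-identical complexes).
#' @param total_reads number of reads to simulate.
#' @param read_length read length r.
#' @param error_rate per-base substitution rate in `[0, 1)`.
#' @param seed integer seed fixing all randomness.
#' @return A `community_spec`.
#' @export
community_spec <- function(species, sisters = list(), total_reads = 1e5,
                           read_length = 75L, error_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(species),
            all(c("name", "genus", "length", "proportion") %in%
                  names(species)),
            abs(sum(species$proportion) - 1) < 1e-8,
            error_rate >= 0, error_rate < 1,
            all(species$length >= read_length))
  for (s in sisters) {
    stopifnot(all(c(s$a, s$b) %in% species$name),
              s$shared_fraction >= 0, s$shared_fraction < 1)
  }
  structure(list(species = species, sisters = sisters,
                 total_reads = as.integer(total_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' The default nine-species mock community
#'
#' Emulates a skin-like mock community: nine species in six genera, one
#' genus holding four species, mixed in equal proportions, with one sister
#' pair sharing 99.9% of its sequence (divergence scattered as single-base
#' unique sites, the SNP-like structure of real near-identical species
#' pairs) under a species-group node.
#'
#' @param total_reads,read_length,error_rate,seed see [community_spec()].
#' @param genome_length per-species genome length (default 50 kb).
#' @return A `community_spec`.
#' @export
mock_community_spec <- function(total_reads = 1e5, read_length = 75L,
                                error_rate = 0, seed = 1L,
                                genome_length = 50000L) {
  genera <- c("Staphyloform", "Staphyloform", "Staphyloform", "Staphyloform",
              "Acinoform", "Corynoform", "Micrococcoform", "Rhodoform",
              "Propioniform")
  sp <- data.frame(
    name = c("Staphyloform alpha", "Staphyloform beta",
             "Staphyloform gamma", "Staphyloform delta",
             "Acinoform resistens", "Corynoform amycolatum",
             "Micrococcoform luteus", "Rhodoform erythropolis",
             "Propioniform acnes"),
    genus = genera,
    length = genome_length,
    proportion = rep(1 / 9, 9),
    stringsAsFactors = FALSE)
  community_spec(
    sp,
    sisters = list(list(a = "Staphyloform alpha", b = "Staphyloform beta",
                        shared_fraction = 0.999, block_length = 1L,
                        group_name = "Staphyloform alpha complex")),
    total_reads = total_reads, read_length = read_length,
    error_rate = error_rate, seed = seed)
}

#' Materialize a mock community
#'
#' Builds the taxonomy (root, genera, optional species groups, species
#' leaves), the genome sequences (sister genomes share
#' `shared_fraction` of their sequence verbatim; unique blocks are drawn
#' uniformly over ACGT), and the truth table of expected read counts.
#'
#' @param spec a [community_spec()].
#' @return `list(tree, genomes, truth)`, where `genomes` is a list of
#'   [genome_record()] named by taxid and `truth` is a data frame with
#'   `name`, `taxid`, `proportion` and `expected_reads`.
#' @export
make_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  sp <- spec$species
  genera <- unique(sp$genus)
  taxid <- 1L
  rows <- data.frame(taxid = 1L, parent = 1L, rank = "root", name = "root",
                     stringsAsFactors = FALSE)
  gid <- stats::setNames(seq_along(genera) + 1L, genera)
  rows <- rbind(rows, data.frame(taxid = unname(gid), parent = 1L,
                                 rank = "genus", name = genera,
                                 stringsAsFactors = FALSE))
  next_id <- max(gid) + 1L
  # species-group nodes above designated sister pairs
  group_of <- stats::setNames(rep(NA_integer_, nrow(sp)), sp$name)
  for (s in spec$sisters) {
    if (is.null(s$group_name)) next
    g <- sp$genus[sp$name == s$a][1L]
    rows <- rbind(rows, data.frame(taxid = next_id, parent = gid[[g]],
                                   rank = "species-group",
                                   name = s$group_name,
                                   stringsAsFactors = FALSE))
    group_of[c(s$a, s$b)] <- next_id
    next_id <- next_id + 1L
  }
  sp_id <- stats::setNames(seq_len(nrow(sp)) + next_id - 1L, sp$name)
  rows <- rbind(rows, data.frame(
    taxid = unname(sp_id),
    parent = ifelse(is.na(group_of[sp$name]), gid[sp$genus],
                    group_of[sp$name]),
    rank = "species", name = sp$name, stringsAsFactors = FALSE))
  tree <- .new_taxonomy(rows$taxid, rows$parent, rows$rank, rows$name)

  genomes <- .with_seed(spec$seed, {
    seqs <- stats::setNames(vector("list", nrow(sp)), sp$name)
    done <- character(0)
    for (s in spec$sisters) {
      a <- .random_dna(sp$length[sp$name == s$a])
      b_len <- sp$length[sp$name == s$b]
      stopifnot(b_len == nchar(a))  # sisters share a coordinate system
      bl <- as.integer(s$block_length %||% 1L)
      n_unique <- max(1L, round((1 - s$shared_fraction) * b_len / bl))
      starts <- sort(sample(seq_len(b_len - bl + 1L), n_unique))
      # keep blocks disjoint so the realized shared fraction is honest
      keep <- c(TRUE, diff(starts) >= bl)
      starts <- starts[keep]
      bvec <- strsplit(a, "", fixed = TRUE)[[1L]]
      for (st in starts)
        bvec[st:(st + bl - 1L)] <-
          sample(c("A", "C", "G", "T"), bl, replace = TRUE)
      seqs[[s$a]] <- a
      seqs[[s$b]] <- paste(bvec, collapse = "")
      done <- c(done, s$a, s$b)
    }
    for (nm in setdiff(sp$name, done))
      seqs[[nm]] <- .random_dna(sp$length[sp$name == nm])
    lapply(sp$name, function(nm)
      genome_record(sp_id[[nm]], seqs[[nm]], name = nm))
  })
  names(genomes) <- as.character(sp_id[sp$name])

  truth <- data.frame(name = sp$name, taxid = unname(sp_id[sp$name]),
                      proportion = sp$proportion,
                      expected_reads = sp$proportion * spec$total_reads,
                      stringsAsFactors = FALSE)
  list(tree = tree, genomes = genomes, truth = truth)
}

#' Simulate shotgun reads from a community
#'
#' Per-species read counts are multinomial in the mixture proportions;
#' start positions are uniform within contigs; sequencing error is an
#' i.i.d. per-base substitution to a uniformly chosen different base.
#'
#' @param genomes list of [genome_record()] objects.
#' @param proportions mixture proportions (parallel to `genomes`).
#' @param n total number of reads.
#' @param r read length.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed; identical inputs and seed give identical
#'   reads.
#' @return Data frame with columns `sequence` and `taxid` (the true source
#'   species of each read).
#' @export
simulate_reads <- function(genomes, proportions, n, r, error_rate = 0,
                           seed = 1L) {
  stopifnot(length(genomes) == length(proportions), n >= 0,
            error_rate >= 0, error_rate < 1)
  if (n == 0)
    return(data.frame(sequence = character(0), taxid = integer(0)))
  .with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, proportions))
    out <- vector("list", length(genomes))
    for (i in seq_along(genomes)) {
      if (counts[i] == 0) next
      g <- genomes[[i]]
      contigs <- g$sequences[nchar(g$sequences) >= r]
      if (!length(contigs))
        stop("genome taxid ", g$taxid, " shorter than read length ", r)
      wts <- nchar(contigs) - r + 1L
      ci <- sample.int(length(contigs), counts[i], replace = TRUE,
                       prob = wts)
      starts <- floor(stats::runif(counts[i]) * wts[ci]) + 1L
      reads <- substring(contigs[ci], starts, starts + r - 1L)
      if (error_rate > 0) {
        mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                      nrow = r)
        hit <- which(stats::runif(length(mat)) < error_rate)
        hit <- hit[mat[hit] %in% c("A", "C", "G", "T")]  # leave N alone
        if (length(hit)) {
          # substitute with a uniformly chosen *different* base
          alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                          "A", "C", "G"), nrow = 3)
          ci <- match(mat[hit], c("A", "C", "G", "T"))
          mat[hit] <- alt[cbind(sample.int(3, length(hit), replace = TRUE),
                                ci)]
          reads <- apply(mat, 2, paste, collapse = "")
        }
      }
      out[[i]] <- data.frame(sequence = reads, taxid = g$taxid,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# Bulk Kraken-style classification of reads (0 = unclassified), chunked to
# bound the memory held by the per-read k-mer matrices.
.classify_reads_bulk <- function(seqs, index, tree, chunk = 20000L) {
  n <- length(seqs)
  out <- integer(n)
  k <- index$k
  tt <- tree$taxid
  # ancestor-or-self membership matrix (small trees only)
  nn <- length(tt)
  anc <- matrix(FALSE, nn, nn)
  for (j in seq_len(nn)) anc[match(tree$paths[[j]], tt), j] <- TRUE
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    ss <- seqs[lo:hi]
    L <- unique(nchar(ss))
    for (len in L) {
      sel <- which(nchar(ss) == len)
      if (len < k) { out[lo - 1L + sel] <- 0L; next }
      m <- len - k + 1L
      sub <- ss[sel]
      kvec <- unlist(lapply(seq_len(m), function(s)
        substring(sub, s, s + k - 1L)), use.names = FALSE)
      ok <- !grepl("[^ACGT]", kvec)
      tax <- rep(NA_integer_, length(kvec))
      if (any(ok)) {
        uk <- unique(kvec[ok])
        ut <- lookup_kmers(index, canonicalize(uk))
        tax[ok] <- ut[match(kvec[ok], uk)]
      }
      tmat <- matrix(tax, nrow = length(sub))  # reads x kmer positions
      dmat <- matrix(tree$depth[match(tax, tt)], nrow = length(sub))
      maxd <- suppressWarnings(
        do.call(pmax, c(lapply(seq_len(m), function(j) dmat[, j]),
                        list(na.rm = TRUE))))
      res <- integer(length(sub))
      unhit <- !is.finite(maxd)
      res[unhit] <- 0L
      if (any(!unhit)) {
        pickable <- !is.na(dmat) & dmat == maxd
        pickable[is.na(pickable)] <- FALSE
        col1 <- max.col(pickable, ties.method = "first")
        deepest <- tmat[cbind(seq_along(sub), col1)]
        # single-path fast path: all hits are ancestors of the deepest
        di <- match(deepest, tt)
        onpath <- matrix(anc[cbind(match(as.vector(tmat), tt),
                                   rep(di, m))], nrow = length(sub))
        onpath[is.na(tmat)] <- TRUE
        simple <- rowSums(!onpath) == 0L & !unhit
        res[simple] <- deepest[simple]
        for (i in which(!simple & !unhit))
          res[i] <- classify_read(tmat[i, ], tree)
      }
      out[lo - 1L + sel] <- res
    }
  }
  out
}

#' Simulate the Kraken report for a read set
#'
#' Classifies every read against the index with the weighted
#' root-to-leaf-path rule of [classify_read()] and tallies the results
#' into a valid report (clade sums hold by construction).
#'
#' @param reads data frame from [simulate_reads()] (only `sequence` is
#'   used).
#' @param index a `kmer_index` built over the community genomes.
#' @param tree a `taxonomy_tree`.
#' @return A `kraken_report` including the unclassified count.
#' @export
simulate_kraken_report <- function(reads, index, tree) {
  cls <- .classify_reads_bulk(reads$sequence, index, tree)
  uncl <- sum(cls == 0L)
  direct <- table(cls[cls != 0L])
  kraken_report(stats::setNames(as.numeric(direct),
                                names(direct)), tree,
                unclassified = uncl)
}
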