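# The Bayesian redistribution engine.  Reads stranded above the target
# level are pushed down to detected target-level taxa with Bayes' theorem
# (score of genome Si at node Gj = P(Gj|Si) * P(Si), renormalized over the
# detected genomes in Gj's subtree, with P(Gj) = 1 since we condition on
# the read being classified at Gj); reads at or below the target level
# roll up into their target-level ancestor.

#' Estimation settings
#'
#' @param level target rank (default `"species"`).
#' @param threshold minimum rolled-up read count for a taxon to count as
#'   detected (default 10 reads, the customary false-positive guard).
#' @param read_length read length r used to pick/validate the distribution.
#' @return An `estimation_config` list.
#' @export
estimation_config <- function(level = "species", threshold = 10L,
                              read_length = 75L) {
  level <- .normalize_rank(level)
  if (identical(level, "no-rank")) stop("level must be a ranked level")
  stopifnot(threshold >= 0)
  structure(list(level = level, threshold = as.integer(threshold),
                 read_length = as.integer(read_length)),
            class = "estimation_config")
}

# rolled-up direct counts per target-level taxon: the taxon's own direct
# reads plus direct reads of everything below it (strains, unranked nodes)
.rolled_counts <- function(report, tree, level) {
  la <- .level_ancestors(tree, level)
  lv <- tree$taxid[tree$rank == level]
  rolled <- stats::setNames(numeric(length(lv)), lv)
  has <- !is.na(la) & report$direct > 0
  if (any(has)) {
    agg <- tapply(report$direct[has], la[has], sum)
    rolled[names(agg)] <- agg
  }
  rolled
}

#' Detected taxa at the target level
#'
#' A target-level taxon is detected iff its own direct reads plus the
#' direct reads of its sub-level descendants reach the threshold (the
#' threshold is applied after strain roll-up).
#'
#' @param report a `kraken_report`.
#' @param config an [estimation_config()].
#' @param tree a `taxonomy_tree`.
#' @return Integer vector of detected taxids.
#' @export
detect_taxa <- function(report, config, tree) {
  rolled <- .rolled_counts(report, tree, config$level)
  as.integer(names(rolled)[rolled >= max(config$threshold, 1L)])
}

#' Estimated total reads deriving from a genome
#'
#' If Kraken assigns `kraken_count` reads directly to a genome of which a
#' fraction `unique_fraction` is classifiable to its own node, the genome
#' likely contributed `kraken_count / unique_fraction` reads in total.
#'
#' @param kraken_count reads assigned directly to the genome.
#' @param unique_fraction the genome's unique fraction `U` in `(0, 1]`.
#' @return Estimated total reads (fractional).
#' @examples
#' estimate_derived_total(1000, 0.25)  # 4000
#' @export
estimate_derived_total <- function(kraken_count, unique_fraction) {
  if (any(unique_fraction <= 0))
    stop("degenerate genome: unique fraction must be > 0 ",
         "(no window classifies to the genome's own node)")
  kraken_count / unique_fraction
}

#' Priors over the genomes of one distributing subtree
#'
#' Normalizes estimated derived totals into the prior `P(Si)` used by the
#' Bayes redistribution: each genome's share of all reads attributable to
#' the subtree's genomes.
#'
#' @param derived_totals non-negative numeric vector of estimated totals.
#' @return Numeric priors summing to 1.
#' @export
compute_priors <- function(derived_totals) {
  if (!length(derived_totals)) stop("no estimates to normalize")
  if (any(derived_totals < 0)) stop("derived totals must be >= 0")
  s <- sum(derived_totals)
  if (s == 0)
    stop("no signal: all derived totals are zero")
  derived_totals / s
}

#' Allocate one node's stranded reads to candidate genomes
#'
#' Raw score of candidate i is `P(Gj|Si) * P(Si)`; shares are the scores
#' renormalized, and allocations are `shares * node_reads` with exact
#' conservation (the last allocation absorbs the floating-point remainder).
#'
#' @param node_reads direct read count at the distributing node.
#' @param cond_prob numeric vector `P(Gj|Si)` per candidate.
#' @param prior numeric vector `P(Si)` per candidate.
#' @return `list(shares, allocated, unallocated)`; when every score is
#'   zero the reads are returned as `unallocated` with a warning.
#' @export
allocate_node_reads <- function(node_reads, cond_prob, prior) {
  stopifnot(length(cond_prob) == length(prior), node_reads >= 0)
  score <- cond_prob * prior
  if (!length(score) || sum(score) == 0) {
    if (length(score) && node_reads > 0)
      warning("all allocation scores are zero; ", node_reads,
              " reads left unallocated")
    return(list(shares = numeric(length(score)) * NA_real_,
                allocated = numeric(length(score)),
                unallocated = node_reads))
  }
  shares <- score / sum(score)
  allocated <- shares * node_reads
  allocated[length(allocated)] <-
    node_reads - sum(allocated[-length(allocated)])
  list(shares = shares, allocated = allocated, unallocated = 0)
}

# Per-genome Kraken-assigned counts: each genome's own strain-level reads
# plus a share of the reads sitting at its species node (or at unranked
# nodes between).  The residual splits in proportion to strain-derived
# totals when strain reads exist, else to per-genome unique window counts.
.genome_kraken_counts <- function(report, dist, tree, level) {
  gtax <- as.integer(names(dist$per_genome))
  la <- .level_ancestors(tree, level)
  s_of_g <- la[match(gtax, tree$taxid)]
  own <- report$direct[match(gtax, tree$taxid)]
  u <- vapply(dist$per_genome, `[[`, 0, "unique_fraction")
  nuniq <- vapply(dist$per_genome, function(g) {
    x <- g$node_counts[as.character(g$taxid)]
    if (is.na(x)) 0 else as.numeric(x)
  }, 0)
  rolled <- .rolled_counts(report, tree, level)
  kg <- own
  for (s in unique(s_of_g[!is.na(s_of_g)])) {
    gi <- which(s_of_g == s)
    resid <- rolled[as.character(s)] - sum(own[gi])
    if (is.na(resid) || resid <= 0) next
    w <- if (sum(own[gi]) > 0)
      ifelse(u[gi] > 0, own[gi] / u[gi], own[gi]) else nuniq[gi]
    if (sum(w) == 0) w <- rep(1, length(gi))
    kg[gi] <- kg[gi] + resid * w / sum(w)
  }
  list(taxid = gtax, species = s_of_g, kraken = kg, unique_fraction = u)
}

#' Estimate abundance at a taxonomic level
#'
#' The full redistribution pipeline: (1) roll strain/sub-level reads up
#' into their target-level ancestor and detect taxa against the threshold;
#' (2) estimate each genome's derived total `K/U` and, for every node
#' strictly above the target level holding direct reads, allocate those
#' reads among the detected genomes of its subtree by `P(node|Si) * P(Si)`;
#' (3) sum roll-ups and allocations into the final per-taxon estimates.
#' Reads at nodes whose subtree holds no detected target-level taxon are
#' reported as unallocated, never dropped silently.
#'
#' @param report a `kraken_report`.
#' @param dist a `kmer_distribution` from [build_distribution()].
#' @param tree a `taxonomy_tree`.
#' @param config an [estimation_config()].
#' @return An `abundance_table` data frame with columns `name`,
#'   `taxonomy_id`, `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`,
#'   `new_est_reads` (full precision; rounded only on output) and
#'   `fraction_total_reads`, plus attributes `total_reads`,
#'   `unclassified_reads` and `unallocated_reads`.
#' @export
estimate_abundance <- function(report, dist, tree,
                               config = estimation_config()) {
  stopifnot(inherits(report, "kraken_report"),
            inherits(dist, "kmer_distribution"),
            inherits(tree, "taxonomy_tree"),
            inherits(config, "estimation_config"))
  if (!is.null(config$read_length) &&
      config$read_length != dist$read_length)
    warning("distribution was built for r = ", dist$read_length,
            " but config asks for r = ", config$read_length,
            "; proceeding with the existing distribution")
  .ti(tree, as.integer(names(dist$per_genome)))  # hard error if missing

  level <- config$level
  la <- .level_ancestors(tree, level)
  rolled <- .rolled_counts(report, tree, level)
  detected <- detect_taxa(report, config, tree)

  gk <- .genome_kraken_counts(report, dist, tree, level)
  zero_u <- gk$unique_fraction == 0 & gk$kraken > 0
  if (any(zero_u))
    warning("genome(s) ", paste(gk$taxid[zero_u], collapse = ", "),
            " have no unique windows (U = 0); using K as the derived total")
  khat <- ifelse(gk$unique_fraction > 0,
                 gk$kraken / gk$unique_fraction, gk$kraken)
  candidate <- gk$species %in% detected

  no_dist <- setdiff(detected, gk$species[candidate])
  if (length(no_dist))
    warning("detected taxa with no genome in the distribution file ",
            "cannot receive redistributed reads: ",
            paste(no_dist, collapse = ", "))

  gpaths <- lapply(gk$taxid, function(t) ancestor_path(tree, t))
  alloc <- numeric(length(gk$taxid))
  unallocated <- 0

  # nodes strictly above the target level (no target-rank ancestor-or-self)
  distributing <- which(is.na(la) & report$direct > 0)
  for (i in distributing) {
    node <- tree$taxid[i]
    nd <- report$direct[i]
    cand <- which(candidate &
                    vapply(gpaths, function(p) node %in% p, NA))
    if (!length(cand) || sum(khat[cand]) == 0) {
      unallocated <- unallocated + nd
      next
    }
    pc <- vapply(gk$taxid[cand], function(g)
      as.numeric(dist$per_genome[[as.character(g)]]$node_fractions[
        as.character(node)] %|NA|% 0), 0)
    pr <- compute_priors(khat[cand])
    res <- allocate_node_reads(nd, pc, pr)
    alloc[cand] <- alloc[cand] + res$allocated
    unallocated <- unallocated + res$unallocated
  }

  # undetected taxa keep their reads out of the table, accounted for
  undet <- rolled[!(as.integer(names(rolled)) %in% detected)]
  unallocated <- unallocated + sum(undet)

  added <- vapply(detected, function(s)
    sum(alloc[gk$species == s & !is.na(gk$species)]), 0)
  kra <- as.numeric(rolled[as.character(detected)])
  est <- kra + added
  total <- report$total
  lvl_code <- if (level %in% names(.RANK_LETTERS))
    unname(.RANK_LETTERS[level]) else level
  out <- data.frame(
    name = tree$name[match(detected, tree$taxid)],
    taxonomy_id = detected,
    taxonomy_lvl = lvl_code,
    kraken_assigned_reads = kra,
    added_reads = added,
    new_est_reads = est,
    fraction_total_reads = if (total > 0) est / total else 0,
    stringsAsFactors = FALSE)
  out <- out[order(-out$new_est_reads, out$taxonomy_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("abundance_table", "data.frame"),
            level = level, threshold = config$threshold,
            total_reads = total,
            unclassified_reads = report$unclassified,
            unallocated_reads = unallocated)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Estimate abundance at an arbitrary level
#'
#' Convenience wrapper around [estimate_abundance()] with the level
#' boundary moved: reads at or below the level roll up, reads above
#' redistribute down.  `level = "root"` collapses the whole report into a
#' single row of all classified reads.
#'
#' @inheritParams estimate_abundance
#' @param level target rank (e.g. `"genus"`, `"family"`, `"phylum"`).
#' @param threshold,read_length see [estimation_config()].
#' @return An `abundance_table`.
#' @export
estimate_at_level <- function(report, dist, tree, level,
                              threshold = 10L, read_length = 75L) {
  estimate_abundance(report, dist, tree,
                     estimation_config(level = level, threshold = threshold,
                                       read_length = read_length))
}

#' @export
print.abundance_table <- function(x, digits = 1, ...) {
  cat("abundance_table: level =", attr(x, "level"),
      "| threshold =", attr(x, "threshold"), "reads\n")
  cat("  total reads:", format(attr(x, "total_reads"), big.mark = ","),
      "| unclassified:", format(attr(x, "unclassified_reads"),
                                big.mark = ","),
      "| unallocated:", format(round(attr(x, "unallocated_reads"), 1),
                               big.mark = ","), "\n\n")
  y <- as.data.frame(x)
  y$new_est_reads <- round(y$new_est_reads)
  y$added_reads <- round(y$added_reads, digits)
  y$kraken_assigned_reads <- round(y$kraken_assigned_reads, digits)
  y$fraction_total_reads <- sprintf("%.5f", y$fraction_total_reads)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.abundance_table <- function(object, ...) {
  est <- sum(object$new_est_reads)
  out <- list(level = attr(object, "level"),
              n_taxa = nrow(object),
              total_reads = attr(object, "total_reads"),
              estimated_reads = est,
              unclassified_reads = attr(object, "unclassified_reads"),
              unallocated_reads = attr(object, "unallocated_reads"),
              conserved = isTRUE(all.equal(
                est + attr(object, "unclassified_reads") +
                  attr(object, "unallocated_reads"),
                as.numeric(attr(object, "total_reads")))))
  class(out) <- "summary.abundance_table"
  out
}

#' @export
print.summary.abundance_table <- function(x, ...) {
  cat("Abundance estimate at level:", x$level, "\n")
  cat(sprintf("  taxa reported:      %d\n", x$n_taxa))
  cat(sprintf("  total reads:        %s\n",
              format(x$total_reads, big.mark = ",")))
  cat(sprintf("  estimated reads:    %s\n",
              format(round(x$estimated_reads, 1), big.mark = ",")))
  cat(sprintf("  unclassified reads: %s\n",
              format(x$unclassified_reads, big.mark = ",")))
  cat(sprintf("  unallocated reads:  %s\n",
              format(round(x$unallocated_reads, 1), big.mark = ",")))
  cat(sprintf("  reads conserved:    %s\n",
              if (x$conserved) "yes" else "NO"))
  invisible(x)
}
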