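# Readers and writers for every file the tool touches: FASTA references,
# Kraken-style 6-column reports, the k-mer distribution TSV, and the final
# abundance TSV.  Readers reject malformed input rather than repairing it;
# every writer/reader composition is the identity on valid data.

#' Construct a Kraken-style classification report
#'
#' Clade counts are derived from the direct counts (clade of a node = its
#' direct reads plus the clade counts of its children), so the clade-sum
#' invariant holds by construction.
#'
#' @param direct named numeric vector of per-taxon direct read counts
#'   (names are taxids), or a vector parallel to `tree$taxid`.
#' @param tree a `taxonomy_tree`.
#' @param unclassified number of reads with no assignment.
#' @return A `kraken_report` with fields `taxid`, `direct`, `clade`
#'   (parallel to `tree$taxid`), `unclassified` and `total`.
#' @export
kraken_report <- function(direct, tree, unclassified = 0) {
  n <- length(tree$taxid)
  if (!is.null(names(direct))) {
    full <- numeric(n)
    idx <- .ti(tree, as.integer(names(direct)))
    full[idx] <- as.numeric(direct)
    direct <- full
  }
  stopifnot(length(direct) == n, all(direct >= 0), unclassified >= 0)
  clade <- as.numeric(direct)
  for (i in rev(tree$bfs)) {
    if (tree$taxid[i] == tree$root) next
    p <- match(tree$parent[i], tree$taxid)
    clade[p] <- clade[p] + clade[i]
  }
  structure(list(taxid = tree$taxid, direct = as.numeric(direct),
                 clade = clade, unclassified = as.numeric(unclassified),
                 total = sum(direct) + as.numeric(unclassified)),
            class = "kraken_report")
}

#' @export
print.kraken_report <- function(x, ...) {
  cat("kraken_report:", format(x$total, big.mark = ","), "reads |",
      format(x$unclassified, big.mark = ","), "unclassified |",
      sum(x$direct > 0), "taxa with direct reads\n")
  invisible(x)
}

#' Read a Kraken report
#'
#' Parses the 6-column dialect (percent, clade count, direct count, rank
#' code, taxid, indented name; an optional leading `unclassified` row with
#' taxid 0) and validates the clade-sum invariant against the tree.
#'
#' @param source path or character vector of report lines.
#' @param tree a `taxonomy_tree`.
#' @return A `kraken_report`.
#' @export
read_kraken_report <- function(source, tree) {
  lines <- .as_lines(source)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty report")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 6L)
  if (length(bad))
    stop("report line ", bad[1L], " does not have 6 tab-separated columns")
  clade_in <- as.numeric(vapply(parts, `[`, "", 2L))
  direct_in <- as.numeric(vapply(parts, `[`, "", 3L))
  taxid_in <- as.integer(vapply(parts, `[`, "", 5L))
  if (anyNA(clade_in) || anyNA(direct_in) || anyNA(taxid_in))
    stop("non-numeric count or taxid in report")
  uncl <- 0
  is_u <- taxid_in == 0L
  if (any(is_u)) {
    uncl <- sum(direct_in[is_u])
    clade_in <- clade_in[!is_u]; direct_in <- direct_in[!is_u]
    taxid_in <- taxid_in[!is_u]
  }
  if (anyDuplicated(taxid_in))
    stop("duplicate taxid in report: ", taxid_in[duplicated(taxid_in)][1L])
  .ti(tree, taxid_in)  # unknown taxid -> error
  rep <- kraken_report(stats::setNames(direct_in, taxid_in), tree,
                       unclassified = uncl)
  chk <- rep$clade[match(taxid_in, tree$taxid)]
  off <- which(abs(chk - clade_in) > 1e-9)
  if (length(off))
    stop("clade-sum violation at taxid ", taxid_in[off[1L]],
         ": reported ", clade_in[off[1L]], ", children + direct give ",
         chk[off[1L]])
  rep
}

#' Write a Kraken report
#'
#' Depth-first emission of every node with a non-zero clade count,
#' children ordered by descending clade count then ascending taxid;
#' `read_kraken_report(write_kraken_report(x))` is the identity.
#'
#' @param report a `kraken_report`.
#' @param tree a `taxonomy_tree`.
#' @param path optional output file.
#' @return Invisibly, the report lines.
#' @export
write_kraken_report <- function(report, tree, path = NULL) {
  total <- report$total
  pct <- function(x) sprintf("%6.2f", if (total > 0) 100 * x / total else 0)
  codes <- .rank_codes(tree)
  lines <- character(0)
  if (report$unclassified > 0)
    lines <- sprintf("%s\t%d\t%d\tU\t0\tunclassified",
                     pct(report$unclassified),
                     as.integer(report$unclassified),
                     as.integer(report$unclassified))
  emit <- function(i) {
    lines <<- c(lines, sprintf("%s\t%d\t%d\t%s\t%d\t%s%s",
                               pct(report$clade[i]),
                               as.integer(report$clade[i]),
                               as.integer(report$direct[i]),
                               codes[i], tree$taxid[i],
                               strrep("  ", tree$depth[i]), tree$name[i]))
    kt <- tree$children[[i]]
    if (!length(kt)) return(invisible())
    ki <- match(kt, tree$taxid)
    ki <- ki[report$clade[ki] > 0]
    ki <- ki[order(-report$clade[ki], tree$taxid[ki])]
    for (j in ki) emit(j)
  }
  ri <- match(tree$root, tree$taxid)
  if (report$clade[ri] > 0) emit(ri)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a k-mer distribution file
#'
#' TSV with a `# k=<k> r=<r>` header and one row per (genome, ancestor
#' node): `genome_taxid node_taxid node_rank window_count total_windows
#' fraction`.  Counts are the source of truth; fractions are serialized at
#' full precision and must round-trip bit-exactly.
#'
#' @param dist a `kmer_distribution`.
#' @param path optional output file.
#' @param tree a `taxonomy_tree` (for the informational rank column).
#' @return Invisibly, the file lines.
#' @export
write_distribution <- function(dist, tree, path = NULL) {
  lines <- c(sprintf("# k=%d r=%d", dist$k, dist$read_length),
             paste("genome_taxid", "node_taxid", "node_rank",
                   "window_count", "total_windows", "fraction", sep = "\t"))
  for (g in dist$per_genome) {
    nodes <- as.integer(names(g$node_counts))
    lines <- c(lines, sprintf("%d\t%d\t%s\t%d\t%d\t%s",
                              g$taxid, nodes,
                              tree$rank[match(nodes, tree$taxid)],
                              as.integer(g$node_counts), g$num_windows,
                              sprintf("%.17g", g$node_counts /
                                        g$num_windows)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a k-mer distribution file
#'
#' @param source path or lines of a file written by [write_distribution()].
#' @param tree a `taxonomy_tree`.
#' @return A `kmer_distribution`.
#' @export
read_distribution <- function(source, tree) {
  lines <- .as_lines(source)
  if (!length(lines) || !grepl("^#", lines[1L]))
    stop("distribution format error: missing '# k=... r=...' header")
  m <- regmatches(lines[1L],
                  regexec("#\\s*k=(\\d+)\\s+r=(\\d+)", lines[1L]))[[1L]]
  if (length(m) != 3L)
    stop("distribution format error: header must carry k and r")
  k <- as.integer(m[2L]); r <- as.integer(m[3L])
  body <- lines[-1L]
  body <- body[nzchar(body) & !grepl("^(#|genome_taxid)", body)]
  per <- list()
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(vapply(parts, length, 0L) != 6L))
      stop("distribution format error: rows must have 6 columns")
    gt <- as.integer(vapply(parts, `[`, "", 1L))
    nt <- as.integer(vapply(parts, `[`, "", 2L))
    ct <- as.integer(vapply(parts, `[`, "", 4L))
    tw <- as.integer(vapply(parts, `[`, "", 5L))
    fr <- as.numeric(vapply(parts, `[`, "", 6L))
    .ti(tree, unique(c(gt, nt)))
    bad <- which(abs(fr - ct / tw) > 1e-12)
    if (length(bad))
      stop("distribution format error: fraction column disagrees with ",
           "count/total at genome ", gt[bad[1L]], ", node ", nt[bad[1L]])
    for (g in unique(gt)) {
      sel <- gt == g
      if (length(unique(tw[sel])) != 1L)
        stop("distribution format error: inconsistent total_windows for ",
             "genome ", g)
      w <- tw[sel][1L]
      nm <- as.character(nt[sel])
      uf <- if (as.character(g) %in% nm) ct[sel][nm == as.character(g)] / w
            else 0
      per[[as.character(g)]] <- structure(
        list(taxid = g, num_windows = w,
             node_counts = stats::setNames(ct[sel], nm),
             node_fractions = stats::setNames(ct[sel] / w, nm),
             unique_fraction = uf),
        class = "genome_distribution")
    }
  }
  structure(list(k = k, read_length = r, per_genome = per),
            class = "kmer_distribution")
}

#' Read a FASTA file
#'
#' Records are returned in file order; ids are the first
#' whitespace-delimited header token; sequences are uppercased with
#' `U -> T`.
#'
#' @param source path or character vector of FASTA lines.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(source) {
  lines <- .as_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA input")
  if (!startsWith(trimws(lines[1L]), ">"))
    stop("FASTA format error: sequence data before the first header")
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  set <- Biostrings::readBStringSet(tf)
  if (!length(set)) stop("empty FASTA input")
  seqs <- chartr("U", "T", toupper(as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write an abundance table
#'
#' Bracken-style TSV.  Estimated read counts are rounded half-to-even to
#' integers at output only; `added_reads` is emitted as the difference so
#' each written row satisfies `new_est = kraken_assigned + added` exactly;
#' fractions are reported to 5 decimals.
#'
#' @param x an `abundance_table`.
#' @param path optional output file.
#' @return Invisibly, the file lines.
#' @export
write_abundance <- function(x, path = NULL) {
  est <- round(x$new_est_reads)
  kra <- round(x$kraken_assigned_reads)
  lines <- c(paste("name", "taxonomy_id", "taxonomy_lvl",
                   "kraken_assigned_reads", "added_reads", "new_est_reads",
                   "fraction_total_reads", sep = "\t"),
             sprintf("%s\t%d\t%s\t%d\t%d\t%d\t%.5f",
                     x$name, x$taxonomy_id, x$taxonomy_lvl,
                     as.integer(kra), as.integer(est - kra),
                     as.integer(est), x$fraction_total_reads))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read an abundance table written by [write_abundance()]
#'
#' @param source path or lines.
#' @return A data frame with the written columns.
#' @export
read_abundance <- function(source) {
  lines <- .as_lines(source)
  utils::read.table(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", quote = "", stringsAsFactors = FALSE)
}
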