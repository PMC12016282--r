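# Minimal Kraken-style database: an exact map from canonical k-mer to the
# LCA of all genomes containing it.  No minimizers, no compression -- the
# classification semantics at desk scale, not the engineering.

#' A reference genome with its leaf taxon
#'
#' @param taxid leaf taxid of the genome in the taxonomy (a node with no
#'   children).
#' @param sequences character vector of contig sequences over `A,C,G,T,N`
#'   (lowercase accepted; `U` converted to `T`).
#' @param name optional display name.
#' @return A `genome_record` with fields `taxid`, `sequences`, `length`
#'   (total bases) and `name`.
#' @export
genome_record <- function(taxid, sequences, name = NULL) {
  stopifnot(is.numeric(taxid), length(taxid) == 1L, taxid > 0,
            is.character(sequences), length(sequences) >= 1L)
  sequences <- chartr("U", "T", toupper(sequences))
  if (any(grepl("[^ACGTN]", sequences)))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  structure(list(taxid = as.integer(taxid), sequences = sequences,
                 length = sum(nchar(sequences)),
                 name = name %||% paste0("taxid:", taxid)),
            class = "genome_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized reverse complement over plain character k-mers
.revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonicalize k-mers
#'
#' Returns, for each k-mer, the lexicographically smaller of the k-mer and
#' its reverse complement -- the strand-neutral key convention of Kraken-type
#' databases.
#'
#' @param kmers character vector over `{A,C,G,T}` (k-mers containing `N`
#'   are skipped upstream and are an error here).
#' @return Character vector of canonical forms, same length and order.
#' @examples
#' canonicalize(c("AAA", "TTT", "ACG"))  # "AAA" "AAA" "ACG"
#' @export
canonicalize <- function(kmers) {
  if (!length(kmers)) return(character(0))
  if (!is.character(kmers) || any(nchar(kmers) < 1L))
    stop("k-mers must be non-empty strings")
  if (any(grepl("[^ACGT]", kmers)))
    stop("k-mers must be over {A,C,G,T}")
  rc <- .revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# all valid canonical k-mers of one contig (positions overlapping N or any
# non-ACGT character contribute nothing); NA at skipped positions when
# keep_na is set, so callers can keep positional alignment
.contig_kmers <- function(seq, k, keep_na = FALSE) {
  n <- nchar(seq)
  if (n < k) return(if (keep_na) rep(NA_character_, 0L) else character(0))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  ok <- !grepl("[^ACGT]", km)
  if (keep_na) {
    out <- rep(NA_character_, length(km))
    out[ok] <- canonicalize(km[ok])
    out
  } else canonicalize(km[ok])
}

#' Build an exact canonical k-mer to LCA index
#'
#' Every canonical k-mer occurring in at least one genome is mapped to the
#' lowest common ancestor of the taxids of all genomes containing it.
#' K-mers overlapping an `N` are omitted.
#'
#' @param genomes list of [genome_record()] objects; all taxids must be
#'   leaves of `tree`.
#' @param k k-mer length in bases (default 31).
#' @param tree a `taxonomy_tree`.
#' @return A `kmer_index` (fields `k` and a keyed `data.table` map).
#' @export
build_kmer_index <- function(genomes, k = 31L, tree) {
  if (!length(genomes)) stop("empty genome list")
  k <- as.integer(k)
  stopifnot(k >= 1L)
  for (g in genomes) {
    i <- .ti(tree, g$taxid)
    if (length(tree$children[[i]]))
      stop("genome taxid ", g$taxid, " is not a leaf of the taxonomy")
  }
  pieces <- lapply(genomes, function(g) {
    if (k > max(nchar(g$sequences)))
      stop("k = ", k, " yields no k-mers for genome taxid ", g$taxid,
           " (longest contig: ", max(nchar(g$sequences)), " bp)")
    km <- unique(unlist(lapply(g$sequences, .contig_kmers, k = k),
                        use.names = FALSE))
    data.table::data.table(kmer = km, taxid = rep(g$taxid, length(km)))
  })
  dt <- unique(data.table::rbindlist(pieces))
  taxid <- NULL; kmer <- NULL  # NSE notes
  map <- if (nrow(dt) == 0L)
    data.table::data.table(kmer = character(0), taxid = integer(0))
  else
    dt[, list(taxid = if (.N == 1L) taxid
              else Reduce(function(a, b) lca(tree, a, b), taxid)),
       by = "kmer"]
  data.table::setkeyv(map, "kmer")
  structure(list(k = k, map = map), class = "kmer_index")
}

#' Look up canonical k-mers in an index
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of canonical k-mers.
#' @return Integer taxids, `NA` where a k-mer is absent from the index.
#' @export
lookup_kmers <- function(index, kmers) {
  if (!length(kmers)) return(integer(0))
  index$map[list(kmer = kmers), ]$taxid
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "|", nrow(x$map), "canonical k-mers |",
      length(unique(x$map$taxid)), "distinct taxids\n")
  invisible(x)
}
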