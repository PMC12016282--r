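# Taxonomy trees in the NCBI nodes.dmp/names.dmp dialect, with the LCA and
# ancestry queries every other module relies on.

# Rank vocabulary, ordered root -> leaf.  "species-group" (e.g. the
# M. tuberculosis complex) sits strictly between genus and species.
# "no-rank" nodes are kept but are pass-through for level queries: the
# level of a read is the rank of its nearest ranked ancestor.
.TAX_RANKS <- c("root", "domain", "kingdom", "phylum", "class", "order",
                "family", "genus", "species-group", "species", "strain")
.RANK_VOCAB <- c(.TAX_RANKS, "no-rank")

.RANK_SYNONYMS <- c("superkingdom"  = "domain",
                    "no rank"       = "no-rank",
                    "norank"        = "no-rank",
                    "species group" = "species-group",
                    "subspecies"    = "strain",
                    "leaf"          = "strain")

.normalize_rank <- function(rank) {
  r <- tolower(trimws(rank))
  hit <- match(r, names(.RANK_SYNONYMS))
  r[!is.na(hit)] <- .RANK_SYNONYMS[hit[!is.na(hit)]]
  bad <- setdiff(unique(r), .RANK_VOCAB)
  if (length(bad))
    stop("unknown rank(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.RANK_VOCAB, collapse = ", "), ")")
  r
}

# Accept either a file path or the lines themselves.
.as_lines <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
}

# Split pipe-delimited dump rows ("1  |  1  |  root  |") into trimmed fields.
.dump_fields <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(lines, "|", fixed = TRUE), trimws)
}

#' Load a taxonomy tree from NCBI-dialect dump files
#'
#' Parses the pipe-delimited `nodes.dmp` dialect (`taxid | parent | rank |`;
#' only the first three columns are consumed) and, optionally, `names.dmp`
#' rows of class "scientific name".  The result is validated: there must be
#' exactly one root (a node that is its own parent), every parent must
#' exist, and every node must be reachable from the root.
#'
#' @param nodes_source path to a nodes file, or a character vector of its
#'   lines.
#' @param names_source optional path/lines of a names file.  Nodes without a
#'   scientific name are named `"taxid:<id>"`.
#' @return A `taxonomy_tree` object.
#' @examples
#' tree <- load_taxonomy(c("1 | 1 | root |",
#'                         "2 | 1 | genus |",
#'                         "3 | 2 | species |"))
#' ancestor_path(tree, 3)
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  fields <- .dump_fields(.as_lines(nodes_source))
  if (!length(fields)) stop("empty nodes source")
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short))
    stop("malformed nodes row ", short[1L], ": fewer than 3 fields")
  taxid  <- as.integer(vapply(fields, `[`, "", 1L))
  parent <- as.integer(vapply(fields, `[`, "", 2L))
  rank   <- .normalize_rank(vapply(fields, `[`, "", 3L))
  if (anyNA(taxid) || anyNA(parent) || any(taxid <= 0L) || any(parent <= 0L))
    stop("taxids and parent taxids must be positive integers")
  if (anyDuplicated(taxid))
    stop("duplicate taxid: ", taxid[duplicated(taxid)][1L])

  name <- paste0("taxid:", taxid)
  if (!is.null(names_source)) {
    nf <- .dump_fields(.as_lines(names_source))
    for (f in nf) {
      if (length(f) >= 4L && !identical(f[4L], "scientific name")) next
      i <- match(as.integer(f[1L]), taxid)
      if (!is.na(i)) name[i] <- f[2L]
    }
  }
  .new_taxonomy(taxid, parent, rank, name)
}

# Validate structure and precompute depths, root-to-node paths and the
# children adjacency (the exact inverse of the parent links).
.new_taxonomy <- function(taxid, parent, rank, name) {
  orphan <- setdiff(parent, taxid)
  if (length(orphan))
    stop("structural error: parent taxid ", orphan[1L],
         " does not exist (orphan link)")
  root <- taxid[parent == taxid]
  if (length(root) != 1L)
    stop("structural error: expected exactly one root, found ",
         length(root),
         if (length(root) == 0L)
           paste0("; cycle involving taxid ", taxid[1L]) else "")

  n <- length(taxid)
  pidx <- match(parent, taxid)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (taxid[i] == root) next
    kids[[pidx[i]]] <- c(kids[[pidx[i]]], taxid[i])
  }

  # breadth-first walk from the root; unreached nodes sit on a cycle
  depth <- rep(NA_integer_, n)
  paths <- vector("list", n)
  order <- integer(n)
  ri <- match(root, taxid)
  depth[ri] <- 0L
  paths[[ri]] <- root
  queue <- ri; qpos <- 1L; filled <- 1L
  order[1L] <- ri
  while (qpos <= length(queue)) {
    i <- queue[qpos]; qpos <- qpos + 1L
    for (ct in kids[[i]]) {
      ci <- match(ct, taxid)
      depth[ci] <- depth[i] + 1L
      paths[[ci]] <- c(paths[[i]], ct)
      filled <- filled + 1L
      order[filled] <- ci
      queue <- c(queue, ci)
    }
  }
  if (anyNA(depth))
    stop("structural error: cycle detected involving taxid ",
         taxid[which(is.na(depth))[1L]])

  structure(list(taxid = taxid, parent = parent, rank = rank, name = name,
                 depth = depth, children = kids, paths = paths,
                 root = root, bfs = order),
            class = "taxonomy_tree")
}

# index of a taxid, with a lookup error for unknown ids
.ti <- function(tree, taxid) {
  i <- match(taxid, tree$taxid)
  if (anyNA(i))
    stop("unknown taxid: ", paste(taxid[is.na(i)], collapse = ", "))
  i
}

#' Root-to-node ancestor path
#'
#' @param tree a `taxonomy_tree`.
#' @param t a taxid present in the tree.
#' @return Integer vector of taxids from the root down to (and including)
#'   `t`; consecutive entries are parent/child.
#' @export
ancestor_path <- function(tree, t) tree$paths[[.ti(tree, t)]]

#' Lowest common ancestor of two taxa
#'
#' The deepest node that is an ancestor-or-self of both arguments, found by
#' intersecting the two root-to-node paths.
#'
#' @inheritParams ancestor_path
#' @param a,b taxids present in the tree.
#' @return A single taxid.
#' @export
lca <- function(tree, a, b) {
  pa <- ancestor_path(tree, a)
  pb <- ancestor_path(tree, b)
  n <- min(length(pa), length(pb))
  same <- pa[seq_len(n)] == pb[seq_len(n)]
  pa[max(which(same))]
}

#' All descendants of a node at a given rank
#'
#' @inheritParams ancestor_path
#' @param rank a rank from the closed vocabulary.
#' @return Integer vector of taxids of the given rank in the subtree rooted
#'   at `t` (including `t` itself if its rank matches); empty when absent.
#' @export
descendants_at_rank <- function(tree, t, rank) {
  rank <- .normalize_rank(rank)
  out <- integer(0)
  stack <- t
  .ti(tree, t)
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    i <- .ti(tree, cur)
    if (tree$rank[i] == rank) out <- c(out, cur)
    stack <- c(stack, tree$children[[i]])
  }
  out
}

#' Serialize a taxonomy tree back to the dump dialect
#'
#' Inverse of [load_taxonomy()]: a tree written and re-loaded is
#' node-for-node identical.
#'
#' @inheritParams ancestor_path
#' @param nodes_path,names_path optional file paths; when omitted the lines
#'   are only returned.
#' @return Invisibly, `list(nodes = <lines>, names = <lines>)`.
#' @export
write_taxonomy <- function(tree, nodes_path = NULL, names_path = NULL) {
  # write ranks in the NCBI spelling so foreign parsers stay happy
  unmap <- c("no-rank" = "no rank", "species-group" = "species group")
  r <- tree$rank
  hit <- match(r, names(unmap))
  r[!is.na(hit)] <- unmap[hit[!is.na(hit)]]
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tree$taxid, tree$parent, r)
  names <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                   tree$taxid, tree$name)
  if (!is.null(nodes_path)) writeLines(nodes, nodes_path)
  if (!is.null(names_path)) writeLines(names, names_path)
  invisible(list(nodes = nodes, names = names))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree: ", length(x$taxid), " nodes, root taxid ", x$root,
      ", max depth ", max(x$depth), "\n", sep = "")
  tab <- table(factor(x$rank, levels = .RANK_VOCAB))
  tab <- tab[tab > 0]
  cat("  ranks: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# For every node, the taxid of its ancestor-or-self whose rank == level
# (NA when the node lies above that level).  Inherited down the BFS order.
.level_ancestors <- function(tree, level) {
  level <- .normalize_rank(level)
  la <- rep(NA_integer_, length(tree$taxid))
  for (i in tree$bfs) {
    if (tree$rank[i] == level) la[i] <- tree$taxid[i]
    else if (tree$taxid[i] != tree$root)
      la[i] <- la[match(tree$parent[i], tree$taxid)]
  }
  la
}

# Kraken-style rank codes: canonical ranks get a letter, intermediate nodes
# (species-group, no-rank, strain) get the nearest lettered ancestor's
# letter plus the number of steps below it (e.g. "G1" for a species group
# directly under its genus).
.RANK_LETTERS <- c(root = "R", domain = "D", kingdom = "K", phylum = "P",
                   class = "C", order = "O", family = "F", genus = "G",
                   species = "S")

.rank_codes <- function(tree) {
  n <- length(tree$taxid)
  codes <- character(n)
  for (i in seq_len(n)) {
    steps <- 0L
    j <- i
    while (!(tree$rank[j] %in% names(.RANK_LETTERS))) {
      if (tree$taxid[j] == tree$root) break
      j <- match(tree$parent[j], tree$taxid)
      steps <- steps + 1L
    }
    letter <- unname(.RANK_LETTERS[tree$rank[j]])
    if (is.na(letter)) letter <- "R"
    codes[i] <- if (steps == 0L) letter else paste0(letter, steps)
  }
  codes
}
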