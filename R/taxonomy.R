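# NCBI-style taxonomy: parent-pointer tree, rank projection, LCA.

#' Construct a taxonomy tree from parallel vectors
#'
#' The root is the (single) node that is its own parent. Every other node
#' must reach the root by parent chasing; orphan parents and cycles are
#' rejected.
#'
#' @param taxid Integer taxon ids (unique).
#' @param parent Integer parent taxon ids.
#' @param rank Character rank labels (e.g. "species", "genus", "family").
#' @param name Scientific names (optional).
#' @return An object of class \code{taxonomy_tree}.
#' @export
taxonomy_tree <- function(taxid, parent, rank, name = as.character(taxid)) {
  taxid <- as.integer(taxid); parent <- as.integer(parent)
  rank <- as.character(rank); name <- as.character(name)
  nn <- length(taxid)
  if (length(parent) != nn || length(rank) != nn || length(name) != nn)
    .dk_stop("dktax_format_error", "taxonomy columns have unequal lengths")
  if (anyDuplicated(taxid))
    .dk_stop("dktax_format_error", "duplicate taxid in taxonomy")
  pidx <- match(parent, taxid)
  if (anyNA(pidx))
    .dk_stop("dktax_format_error",
             sprintf("parent taxid %d not present in taxonomy",
                     parent[which(is.na(pidx))[1]]))
  roots <- which(parent == taxid)
  if (length(roots) != 1L)
    .dk_stop("dktax_format_error", "taxonomy must have exactly one root (parent == self)")
  # depth by parent chasing; a chain longer than the node count is a cycle
  depth <- rep.int(NA_integer_, nn)
  depth[roots] <- 0L
  for (i in seq_len(nn)) {
    if (!is.na(depth[i])) next
    chain <- i; j <- i
    repeat {
      j <- pidx[j]
      if (!is.na(depth[j])) break
      if (length(chain) > nn)
        .dk_stop("dktax_cycle_error", "cycle detected in taxonomy parent chain")
      chain <- c(chain, j)
    }
    depth[chain] <- depth[j] + rev(seq_along(chain))
  }
  structure(list(taxid = taxid, parent = parent, rank = rank, name = name,
                 depth = depth, root = taxid[roots]),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy tree: %d taxa, root %d, ranks: %s\n",
              length(x$taxid), x$root,
              paste(names(sort(-table(x$rank))), collapse = ", ")))
  invisible(x)
}

.tax_index <- function(tree, taxid) {
  i <- match(as.integer(taxid), tree$taxid)
  if (anyNA(i))
    .dk_stop("dktax_unknown_taxid",
             sprintf("unknown taxid: %s",
                     paste(taxid[is.na(i)], collapse = ", ")))
  i
}

.parse_dmp <- function(path) {
  lines <- readLines(path)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load an NCBI-style taxonomy
#'
#' Accepts either the NCBI dump dialect (\code{nodes.dmp} plus
#' \code{names.dmp}, fields separated by \code{"\t|\t"}) or a simplified
#' 4-column TSV (\code{taxid}, \code{parent}, \code{rank}, \code{name},
#' no header) as written by [write_taxonomy()].
#'
#' @param nodes Path to \code{nodes.dmp} or the simplified TSV.
#' @param names Path to \code{names.dmp} (scientific names); ignored for
#'   the TSV dialect.
#' @return A \code{taxonomy_tree}.
#' @export
read_taxonomy <- function(nodes, names = NULL) {
  first <- readLines(nodes, n = 1L)
  if (grepl("\t\\|", first)) {
    rows <- .parse_dmp(nodes)
    if (any(lengths(rows) < 3L))
      .dk_stop("dktax_format_error", "malformed nodes.dmp row")
    taxid <- as.integer(vapply(rows, `[[`, "", 1L))
    parent <- as.integer(vapply(rows, `[[`, "", 2L))
    rank <- vapply(rows, `[[`, "", 3L)
    name <- as.character(taxid)
    if (!is.null(names)) {
      nrows <- .parse_dmp(names)
      sci <- nrows[vapply(nrows, function(r) length(r) >= 4L &&
                            r[[4L]] == "scientific name", logical(1))]
      nm <- setNames(vapply(sci, `[[`, "", 2L),
                     vapply(sci, `[[`, "", 1L))
      hit <- nm[as.character(taxid)]
      name[!is.na(hit)] <- hit[!is.na(hit)]
    }
  } else {
    tab <- read.table(nodes, sep = "\t", header = FALSE,
                      col.names = c("taxid", "parent", "rank", "name"),
                      colClasses = c("integer", "integer", "character",
                                     "character"),
                      quote = "", comment.char = "")
    if (anyNA(tab$taxid) || anyNA(tab$parent))
      .dk_stop("dktax_format_error", "malformed taxonomy TSV row")
    taxid <- tab$taxid; parent <- tab$parent
    rank <- tab$rank; name <- tab$name
  }
  taxonomy_tree(taxid, parent, rank, name)
}

#' Write a taxonomy as simplified TSV
#'
#' @param tree A \code{taxonomy_tree}.
#' @param path Output path.
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  write.table(data.frame(tree$taxid, tree$parent, tree$rank, tree$name),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Lineage of a taxon (self up to the root)
#'
#' @param tree A \code{taxonomy_tree}.
#' @param taxid A taxon id in the tree.
#' @return Integer vector of taxids from \code{taxid} to the root.
#' @export
taxon_lineage <- function(tree, taxid) {
  i <- .tax_index(tree, taxid)
  out <- integer(0)
  repeat {
    out <- c(out, tree$taxid[i])
    ni <- match(tree$parent[i], tree$taxid)
    if (ni == i) break
    i <- ni
  }
  out
}

#' Nearest ancestor (or self) at a given rank
#'
#' @param tree A \code{taxonomy_tree}.
#' @param taxid A taxon id in the tree.
#' @param rank Requested rank label (e.g. "genus").
#' @return The taxid of the nearest ancestor-or-self with that rank, or
#'   \code{NA} if the lineage lacks the rank.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  lin <- taxon_lineage(tree, taxid)
  ranks <- tree$rank[match(lin, tree$taxid)]
  hit <- which(ranks == rank)
  if (length(hit)) lin[hit[1]] else NA_integer_
}

#' Lowest common ancestor of two taxa
#'
#' @param tree A \code{taxonomy_tree}.
#' @param a,b Taxon ids in the tree.
#' @return The taxid of the deepest common ancestor.
#' @export
taxon_lca <- function(tree, a, b) {
  la <- taxon_lineage(tree, a)
  lb <- taxon_lineage(tree, b)
  common <- lb[lb %in% la]
  common[1]
}

#' Depth of a taxon below the root
#'
#' @param tree A \code{taxonomy_tree}.
#' @param taxid Taxon id(s) in the tree.
#' @return Integer depth(s); the root has depth 0.
#' @export
taxon_depth <- function(tree, taxid) {
  tree$depth[.tax_index(tree, taxid)]
}

#' Read a sequence-id to taxid mapping
#'
#' Two-column TSV (\code{seqid}, \code{taxid}), no header. Sequence ids are
#' matched on the first whitespace-delimited token of the FASTA header.
#'
#' @param path Path to the TSV.
#' @param tree Optional \code{taxonomy_tree}; when given, every mapped
#'   taxid must exist in the tree.
#' @return A data.frame with columns \code{seqid} and \code{taxid}.
#' @export
read_seqtax <- function(path, tree = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("seqid", "taxid"),
                    colClasses = c("character", "integer"),
                    quote = "", comment.char = "")
  if (anyNA(tab$taxid))
    .dk_stop("dktax_format_error", "malformed seqid-taxid TSV row")
  if (!is.null(tree)) .tax_index(tree, tab$taxid)
  tab
}
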