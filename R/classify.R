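# Read classification: per-window group probing with approximate k-mer
# matching, max-hit-count assignment with deterministic tie-breaking.

.assign_from_hits <- function(hits, tree, depths, min_hits) {
  if (length(hits$taxid) == 0L || max(hits$count) < min_hits)
    return(list(status = "U", taxid = NA_integer_, max_hits = 0L))
  best <- hits$taxid[hits$count == max(hits$count)]
  if (length(best) > 1L) {
    if (!is.null(tree)) {
      d <- depths[as.character(best)]
      best <- best[d == max(d)]
      if (length(best) > 1L)
        best <- Reduce(function(a, b) taxon_lca(tree, a, b), best)
    } else {
      best <- min(best)
    }
  }
  list(status = "C", taxid = best[1], max_hits = max(hits$count))
}

#' Classify a set of reads against a k-mer database
#'
#' Every valid 32-base window of a read (stride 1; windows containing
#' ambiguous bases are skipped) is looked up in its PREFIX group and
#' probed linearly; the first approximately matching entry (at most one QM
#' substitution plus two DP edits) counts one hit for its taxid. The read
#' is assigned to the taxid with the highest hit count, or left
#' unclassified when the best count is below \code{min_hits}. Ties go to
#' the deepest taxon; residual ties report the LCA of the tied taxa
#' (requires \code{tree}; without one the smallest taxid wins).
#'
#' @param reads Character vector of read sequences (optionally named), a
#'   DNAStringSet, or a FASTA/FASTQ path.
#' @param db A \code{kmer_db}.
#' @param tree Optional \code{taxonomy_tree} used for tie-breaking.
#' @param min_hits Minimum hit count for a positive assignment (default 1).
#' @param details When TRUE, attach the per-read hit-count tables as the
#'   \code{"hits"} attribute.
#' @return data.frame of class \code{read_assignments} with columns
#'   \code{read_id}, \code{status} ("C"/"U"), \code{taxid} (NA when
#'   unclassified), \code{max_hits}, \code{kmers_examined}.
#' @export
classify_reads <- function(reads, db, tree = NULL, min_hits = 1L,
                           details = FALSE) {
  stopifnot(inherits(db, "kmer_db"))
  reads <- .as_seq_vector(reads)
  short <- nchar(reads) < db$params$k
  if (any(short))
    .dk_stop("dktax_short_read",
             sprintf("read(s) shorter than k=%d: %s", db$params$k,
                     paste(names(reads)[short], collapse = ", ")))
  depths <- NULL
  if (!is.null(tree)) {
    taxa <- unique(db$taxid)
    depths <- setNames(taxon_depth(tree, taxa), as.character(taxa))
  }
  hits <- cpp_classify_hits(unname(reads), db$group_size, db$offsets,
                            db$suffix_code, db$taxid,
                            db$params$n, db$params$m)
  rows <- lapply(seq_along(hits), function(i) {
    a <- .assign_from_hits(hits[[i]], tree, depths, min_hits)
    data.frame(read_id = names(reads)[i], status = a$status,
               taxid = a$taxid, max_hits = a$max_hits,
               kmers_examined = hits[[i]]$windows,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(0), status = character(0),
                      taxid = integer(0), max_hits = integer(0),
                      kmers_examined = integer(0))
  class(out) <- c("read_assignments", "data.frame")
  if (details) attr(out, "hits") <- hits
  out
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param read A single read sequence.
#' @return A list: \code{read_id}, \code{status}, \code{taxid},
#'   \code{hit_counts} (named integer vector, taxid -> matched k-mers),
#'   \code{total_kmers_examined}.
#' @export
classify_read <- function(read, db, tree = NULL, min_hits = 1L) {
  res <- classify_reads(setNames(read, "read1"), db, tree = tree,
                        min_hits = min_hits, details = TRUE)
  h <- attr(res, "hits")[[1]]
  list(read_id = res$read_id[1], status = res$status[1],
       taxid = res$taxid[1],
       hit_counts = setNames(h$count, h$taxid),
       total_kmers_examined = h$windows)
}

#' Classify a FASTA/FASTQ file and optionally write a per-read TSV
#'
#' Output columns follow the common per-read report dialect:
#' \code{read_id}, \code{status} (C/U), \code{taxid}, \code{max_hits},
#' \code{kmers_examined}. Gzipped input is handled transparently.
#'
#' @inheritParams classify_reads
#' @param input Path to a FASTA or FASTQ file (optionally gzipped).
#' @param output Optional path for the per-read TSV.
#' @param report Optional path for a short text summary.
#' @return The \code{read_assignments} data.frame, with a
#'   \code{"report"} attribute holding classified/unclassified counts.
#' @export
classify_file <- function(input, db, output = NULL, tree = NULL,
                          min_hits = 1L, report = NULL) {
  seqs <- .as_seq_vector(input)
  res <- if (length(seqs)) classify_reads(seqs, db, tree, min_hits)
         else classify_reads(character(0), db, tree, min_hits)
  rep <- list(n_reads = nrow(res),
              n_classified = sum(res$status == "C"),
              n_unclassified = sum(res$status == "U"))
  attr(res, "report") <- rep
  if (!is.null(output))
    write.table(res, output, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report))
    writeLines(c(sprintf("reads\t%d", rep$n_reads),
                 sprintf("classified\t%d", rep$n_classified),
                 sprintf("unclassified\t%d", rep$n_unclassified)), report)
  res
}

#' @export
print.read_assignments <- function(x, ...) {
  cat(sprintf("read assignments: %d reads, %d classified, %d unclassified\n",
              nrow(x), sum(x$status == "C"), sum(x$status == "U")))
  NextMethod()
}
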