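# Discriminative k-mer database: construction, fine-grained pipeline
# steps, and binary serialization (Size / Suffix / Taxonomy_ID layout).

DB_MAGIC <- "DKTAXDB"
DB_VERSION <- 1L

.stride_for <- function(X) {
  if (!is.numeric(X) || length(X) != 1L || is.na(X) || X <= 0 || X > 100)
    .dk_stop("dktax_value_error", "X must be in (0, 100]")
  max(1L, as.integer(round(100 / X)))
}

#' Collect the deduplicated k-mer set of one species
#'
#' Unions all valid 32-base windows across the strains (and, by default,
#' their reverse complements), keeping each k-mer once together with its
#' window-start positions.
#'
#' @param seqs Sequences of one species: named character vector,
#'   DNAStringSet, or FASTA path.
#' @param params A [codec_params()] object.
#' @param both_strands Also k-merize the reverse complement (default TRUE).
#' @return A list of class \code{species_kmers}: \code{kmers} (data.frame
#'   \code{group_id}, \code{suffix_code}, one row per distinct k-mer) and
#'   \code{occurrences} (data.frame \code{seqid}, \code{strand}, \code{pos},
#'   \code{group_id}, \code{suffix_code}).
#' @export
collect_species_kmers <- function(seqs, params = codec_params(),
                                  both_strands = TRUE) {
  stopifnot(inherits(params, "codec_params"))
  seqs <- .as_seq_vector(seqs)
  occ <- list()
  for (i in seq_along(seqs)) {
    variants <- list(list(strand = "+", s = seqs[[i]]))
    if (both_strands)
      variants <- c(variants, list(list(strand = "-", s = .revcomp(seqs[[i]]))))
    for (v in variants) {
      w <- cpp_encode_windows(v$s, params$n)
      if (length(w$pos))
        occ[[length(occ) + 1L]] <-
          data.frame(seqid = names(seqs)[i], strand = v$strand, pos = w$pos,
                     group_id = w$group_id, suffix_code = w$suffix_code,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(occ))
    .dk_stop("dktax_empty_input", "no valid 32-base window in the input")
  occ <- do.call(rbind, occ)
  key <- paste(occ$group_id, occ$suffix_code)
  kmers <- occ[!duplicated(key), c("group_id", "suffix_code")]
  rownames(kmers) <- NULL
  structure(list(kmers = kmers, occurrences = occ), class = "species_kmers")
}

#' Resolve within-genus k-mer collisions
#'
#' A k-mer present in two or more species of the same genus is assigned to
#' the genus taxid (flagged \code{genus_level}); a k-mer unique to one
#' species keeps the species taxid. K-mers shared across genera emerge with
#' several rows (one per assigned taxid) and are removed later by
#' [remove_cross_taxa()].
#'
#' @param species_sets Named list (names are species taxids) of
#'   \code{species_kmers} objects.
#' @param tree A \code{taxonomy_tree} providing the genus of each species.
#' @return data.frame \code{group_id}, \code{suffix_code}, \code{taxid},
#'   \code{genus_level}.
#' @export
resolve_genus <- function(species_sets, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  sp_tax <- as.integer(names(species_sets))
  genus <- vapply(sp_tax, function(t) {
    g <- ancestor_at_rank(tree, t, "genus")
    if (is.na(g)) 0L else g
  }, integer(1))
  tab <- do.call(rbind, lapply(seq_along(species_sets), function(i) {
    km <- species_sets[[i]]$kmers
    data.frame(group_id = km$group_id, suffix_code = km$suffix_code,
               species = sp_tax[i], genus = genus[i])
  }))
  key <- paste(tab$group_id, tab$suffix_code)
  out <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, ]
    rows <- list()
    for (g in unique(sub$genus)) {
      sp <- unique(sub$species[sub$genus == g])
      if (length(sp) >= 2L && g > 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(group_id = sub$group_id[1], suffix_code = sub$suffix_code[1],
                     taxid = g, genus_level = TRUE)
      } else {
        for (s in sp)
          rows[[length(rows) + 1L]] <-
            data.frame(group_id = sub$group_id[1], suffix_code = sub$suffix_code[1],
                       taxid = s, genus_level = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Uniform positional selection of k-mers
#'
#' Realizes the X% selection as a deterministic stride over window start
#' positions: position \code{p} (1-based) is selected when
#' \code{(p - 1) \%\% round(100 / X) == 0}. A species-unique k-mer survives
#' if any of its source positions is selected; genus-level k-mers are
#' always retained.
#'
#' @param resolved Output of [resolve_genus()].
#' @param occurrences Combined occurrence data.frame (rbind of the
#'   \code{occurrences} of every \code{species_kmers} object).
#' @param X Selection proportion in percent, \code{0 < X <= 100}
#'   (default 15).
#' @return \code{resolved} restricted to the surviving k-mers.
#' @export
select_kmers <- function(resolved, occurrences, X = 15) {
  stride <- .stride_for(X)
  sel_occ <- occurrences[((occurrences$pos - 1L) %% stride) == 0L, ]
  sel_key <- unique(paste(sel_occ$group_id, sel_occ$suffix_code))
  key <- paste(resolved$group_id, resolved$suffix_code)
  keep <- resolved$genus_level | (key %in% sel_key)
  out <- resolved[keep, ]
  rownames(out) <- NULL
  out
}

#' Remove k-mers shared across taxa
#'
#' After genus resolution, any k-mer still mapped to more than one distinct
#' taxid (shared across genera) is deleted; survivors map to exactly one
#' taxid.
#'
#' @param resolved data.frame as produced by [resolve_genus()] (optionally
#'   after [select_kmers()]).
#' @return The discriminative subset, one row per k-mer.
#' @export
remove_cross_taxa <- function(resolved) {
  key <- paste(resolved$group_id, resolved$suffix_code)
  ntax <- tapply(resolved$taxid, key, function(t) length(unique(t)))
  keep <- key %in% names(ntax)[ntax == 1L]
  out <- resolved[keep & !duplicated(key), ]
  rownames(out) <- NULL
  out
}

#' Build a discriminative k-mer database
#'
#' Runs the full construction pipeline: species-level deduplication,
#' genus-level collision assignment, X% uniform positional selection of
#' species-unique k-mers (genus-level k-mers are always retained),
#' cross-taxon removal, and grouping of the survivors into the 4^n PREFIX
#' groups. Deterministic given inputs and parameters: species are
#' processed in ascending taxid order and sequences in name order.
#'
#' @param genomes Sequences: named character vector, DNAStringSet, or
#'   FASTA path(s) (gzip transparently supported).
#' @param seqtax Sequence-id to taxid mapping: data.frame
#'   (\code{seqid}, \code{taxid}), named vector, or TSV path.
#' @param tree A \code{taxonomy_tree}.
#' @param params A [codec_params()] object. Group-table memory is
#'   \code{4 * 4^n} bytes, so small fixtures should use a small \code{n}.
#' @param X Selection proportion in percent (default 15).
#' @param both_strands K-merize the reverse complement too (default TRUE).
#' @return An object of class \code{kmer_db}.
#' @export
build_kmer_db <- function(genomes, seqtax, tree, params = codec_params(),
                          X = 15, both_strands = TRUE) {
  stopifnot(inherits(params, "codec_params"), inherits(tree, "taxonomy_tree"))
  stride <- .stride_for(X)
  seqs <- .as_seq_vector(genomes)
  if (is.character(seqtax) && length(seqtax) == 1L && file.exists(seqtax))
    seqtax <- read_seqtax(seqtax, tree)
  if (is.data.frame(seqtax))
    seqtax <- setNames(as.integer(seqtax$taxid), seqtax$seqid)
  tax <- as.integer(seqtax[names(seqs)])
  if (anyNA(tax))
    .dk_stop("dktax_format_error",
             sprintf("sequence(s) without a taxid mapping: %s",
                     paste(names(seqs)[is.na(tax)], collapse = ", ")))
  .tax_index(tree, unique(tax))
  if (is.null(names(seqs))) names(seqs) <- character(0)
  ord <- order(tax, names(seqs))
  seqs <- seqs[ord]; tax <- tax[ord]
  if (both_strands) {
    n0 <- length(seqs)
    idx <- rep(seq_len(n0), each = 2L)
    rc <- .revcomp(seqs)
    seqs <- as.vector(rbind(seqs, rc))
    tax <- tax[idx]
  }
  genus <- vapply(tax, function(t) {
    g <- ancestor_at_rank(tree, t, "genus")
    if (is.na(g)) 0L else g
  }, integer(1))
  raw <- cpp_build_db(unname(seqs), tax, genus, params$n, stride)
  new_kmer_db(params, X, stride, both_strands, raw$group_size,
              raw$suffix_code, raw$taxid)
}

#' Assemble a database from an explicit k-mer table
#'
#' Groups an already-resolved discriminative k-mer table (e.g. the output
#' of the [collect_species_kmers()] / [resolve_genus()] / [select_kmers()]
#' / [remove_cross_taxa()] pipeline) into the 4^n-group layout.
#'
#' @param kmers data.frame with \code{group_id}, \code{suffix_code},
#'   \code{taxid}; at most one taxid per k-mer.
#' @param params A [codec_params()] object.
#' @param X Selection proportion recorded in the header (default 100).
#' @param both_strands Strand flag recorded in the header.
#' @return A \code{kmer_db}.
#' @export
kmer_db_from_table <- function(kmers, params = codec_params(), X = 100,
                               both_strands = TRUE) {
  stopifnot(inherits(params, "codec_params"))
  key <- paste(kmers$group_id, kmers$suffix_code)
  if (anyDuplicated(key))
    .dk_stop("dktax_value_error", "duplicate (group, suffix) pair in k-mer table")
  ord <- order(kmers$group_id)
  kmers <- kmers[ord, ]
  ngroups <- 4^params$n
  group_size <- integer(ngroups)
  tab <- table(kmers$group_id)
  group_size[as.numeric(names(tab)) + 1] <- as.integer(tab)
  new_kmer_db(params, X, .stride_for(X), both_strands, group_size,
              kmers$suffix_code, as.integer(kmers$taxid))
}

new_kmer_db <- function(params, X, stride, both_strands, group_size,
                        suffix_code, taxid) {
  offsets <- c(0, cumsum(as.numeric(group_size)))[seq_along(group_size)]
  structure(list(params = params, X = as.numeric(X), stride = as.integer(stride),
                 both_strands = both_strands,
                 group_size = group_size, offsets = offsets,
                 suffix_code = suffix_code, taxid = taxid),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("discriminative k-mer database: %d k-mers in %.0f groups (n=%d, m=%d, X=%g%%)\n",
              length(x$suffix_code), length(x$group_size),
              x$params$n, x$params$m, x$X))
  cat(sprintf("  taxa: %d; strands at build: %s\n",
              length(unique(x$taxid)),
              if (x$both_strands) "forward + reverse complement" else "forward"))
  invisible(x)
}

#' Entries of one PREFIX group
#'
#' Group offsets are prefix sums of the group sizes; lookup returns the
#' group's entries in stored order (classification probes them linearly).
#'
#' @param db A \code{kmer_db}.
#' @param group_id Group id in \code{[0, 4^n)}.
#' @return data.frame \code{suffix_code}, \code{taxid} (possibly empty).
#' @export
lookup_group <- function(db, group_id) {
  stopifnot(inherits(db, "kmer_db"))
  if (group_id < 0 || group_id >= length(db$group_size))
    .dk_stop("dktax_value_error", "group_id out of range")
  sz <- db$group_size[group_id + 1]
  off <- db$offsets[group_id + 1]
  idx <- if (sz > 0) off + seq_len(sz) else integer(0)
  data.frame(suffix_code = db$suffix_code[idx], taxid = db$taxid[idx])
}

#' Write a k-mer database to disk
#'
#' The on-disk layout is a directory with a JSON text header and three
#' little-endian binary files: \code{size.bin} (4 bytes per group, 4*4^n
#' total), \code{suffix.bin} and \code{taxid.bin} (4 bytes per stored
#' k-mer). Writing is bit-exact and reproducible.
#'
#' @param db A \code{kmer_db}.
#' @param path Output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_kmer_db <- function(db, path) {
  stopifnot(inherits(db, "kmer_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(magic = DB_MAGIC, version = DB_VERSION,
                 k = db$params$k, n = db$params$n, m = db$params$m,
                 X = db$X, stride = db$stride,
                 both_strands = db$both_strands,
                 base_order = db$params$base_order,
                 n_kmers = length(db$suffix_code), endian = "little")
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (spec in list(c("size.bin", "group_size"),
                    c("suffix.bin", "suffix_code"),
                    c("taxid.bin", "taxid"))) {
    con <- file(file.path(path, spec[1]), "wb")
    .write_u32(db[[spec[2]]], con)
    close(con)
  }
  invisible(path)
}

#' Read a k-mer database from disk
#'
#' @param path Directory written by [write_kmer_db()].
#' @return A \code{kmer_db}. Magic/version mismatches and size
#'   inconsistencies between the header and the binary files raise a
#'   format error.
#' @export
read_kmer_db <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath))
    .dk_stop("dktax_format_error", "not a k-mer database directory (no header.json)")
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$magic, DB_MAGIC))
    .dk_stop("dktax_format_error", "bad magic string in database header")
  if (!identical(as.integer(h$version), DB_VERSION))
    .dk_stop("dktax_format_error", "unsupported database version")
  params <- codec_params(n = h$n, m = h$m)
  ngroups <- 4^params$n
  fs <- function(f) file.path(path, f)
  if (file.info(fs("size.bin"))$size != 4 * ngroups)
    .dk_stop("dktax_format_error",
             "size.bin length inconsistent with header n")
  con <- file(fs("size.bin"), "rb")
  group_size <- as.integer(.read_u32(con, ngroups))
  close(con)
  total <- sum(as.numeric(group_size))
  if (!identical(as.numeric(h$n_kmers), total) ||
      file.info(fs("suffix.bin"))$size != 4 * total ||
      file.info(fs("taxid.bin"))$size != 4 * total)
    .dk_stop("dktax_format_error",
             "suffix/taxid file sizes inconsistent with group sizes")
  con <- file(fs("suffix.bin"), "rb")
  suffix_code <- .read_u32(con, total)
  close(con)
  con <- file(fs("taxid.bin"), "rb")
  taxid <- as.integer(.read_u32(con, total))
  close(con)
  new_kmer_db(params, h$X, h$stride, isTRUE(h$both_strands),
              group_size, suffix_code, taxid)
}
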