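# Independent reference implementations used as test oracles. These work
# on decoded strings and base-R primitives only, never through the
# package's encoded/compiled path.

BASES <- c("A", "C", "G", "T")

# per-base 2-bit packing, written independently of the package codec
oracle_encode <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], BASES) - 1
  stopifnot(!anyNA(codes))
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# min over prefixes of q of the (unbanded) edit distance to all of r;
# utils::adist is the independent C implementation of Levenshtein
oracle_prefix_dist <- function(q, r) {
  min(utils::adist(substring(q, 1, 0:nchar(q)), r))
}

# decision oracle for approximate k-mer matching: exact PREFIX, <=1
# substitution in QM, <=2 edits from the best query-prefix alignment of
# the DP fields (query side runs to at most 2 bases past the window)
oracle_match <- function(query, ref, n, m) {
  if (nchar(query) < 16 + m) return(FALSE)
  if (substr(query, 1, n) != substr(ref, 1, n)) return(FALSE)
  if (oracle_hamming(substr(query, 17, 16 + m), substr(ref, 17, 16 + m)) > 1)
    return(FALSE)
  qdp <- substr(query, 17 + m, min(nchar(query), 34))
  rdp <- substr(ref, 17 + m, 32)
  oracle_prefix_dist(qdp, rdp) <= 2
}

# windows of a sequence as strings; k-mer identity is (first n, last 16)
# bases since the middle is neither stored nor compared
oracle_windows <- function(s, n) {
  L <- nchar(s)
  if (L < 32) return(data.frame(pos = integer(0), key = character(0)))
  pos <- seq_len(L - 31)
  w <- substring(s, pos, pos + 31)
  ok <- !grepl("[^ACGT]", w)
  data.frame(pos = pos[ok],
             key = paste0(substr(w[ok], 1, n), substr(w[ok], 17, 32)),
             stringsAsFactors = FALSE)
}

# full naive database construction on decoded strings: species dedup,
# genus-level assignment of k-mers shared by >=2 species of a genus,
# stride selection of species-unique k-mers, cross-taxon removal
oracle_build <- function(genomes, seqtax, tree, n, X, both_strands = TRUE) {
  stride <- max(1, round(100 / X))
  taxmap <- setNames(as.integer(seqtax$taxid), seqtax$seqid)
  rows <- list()
  for (sp in sort(unique(taxmap[names(genomes)]))) {
    seqs <- genomes[names(genomes) %in% names(taxmap)[taxmap == sp]]
    seqs <- seqs[order(names(seqs))]
    if (both_strands)
      seqs <- as.vector(rbind(seqs, vapply(seqs, oracle_revcomp, "")))
    occ <- do.call(rbind, lapply(seqs, oracle_windows, n = n))
    if (is.null(occ) || nrow(occ) == 0) next
    sel <- tapply(((occ$pos - 1) %% stride) == 0, occ$key, any)
    g <- ancestor_at_rank(tree, sp, "genus")
    rows[[length(rows) + 1]] <-
      data.frame(key = names(sel), species = sp,
                 genus = if (is.na(g)) 0L else g,
                 selected = as.vector(sel), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  out <- lapply(split(tab, tab$key), function(sub) {
    assigned <- integer(0); genus_level <- logical(0); selected <- logical(0)
    for (g in unique(sub$genus)) {
      s <- sub[sub$genus == g, ]
      if (nrow(s) >= 2 && g > 0) {
        assigned <- c(assigned, g)
        genus_level <- c(genus_level, TRUE); selected <- c(selected, TRUE)
      } else {
        assigned <- c(assigned, s$species)
        genus_level <- c(genus_level, rep(FALSE, nrow(s)))
        selected <- c(selected, s$selected)
      }
    }
    if (length(unique(assigned)) > 1) return(NULL)  # cross-taxon: removed
    if (!any(selected)) return(NULL)                # not sampled
    data.frame(key = sub$key[1], taxid = assigned[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# decode a database into the oracle's string-keyed representation
db_as_keys <- function(db) {
  n <- db$params$n
  gid <- rep(seq_along(db$group_size) - 1, db$group_size)
  data.frame(
    key = paste0(vapply(gid, function(g) decode_bases(g, n), ""),
                 vapply(db$suffix_code, function(s) decode_bases(s, 16), "")),
    taxid = db$taxid, stringsAsFactors = FALSE)
}

# apply a controlled corruption to a 32-base k-mer: substitutions at given
# (1-based) positions, plus edits in the DP field; returns the read-like
# fragment (with continuation bases appended) that a window would present
corrupt_kmer <- function(ref, sub_pos = integer(0), dp_ops = character(0),
                         dp_sub_pos = integer(0), m = 6,
                         continuation = "ACGTAC") {
  ch <- strsplit(ref, "")[[1]]
  for (p in sub_pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  dp_start <- 17 + m
  dp <- ch[dp_start:32]
  # dp_sub_pos: distinct DP-field positions, each substituted exactly once,
  # guaranteeing that many real substitutions in the DP field
  for (p in dp_sub_pos) dp[p] <- sample(setdiff(BASES, dp[p]), 1)
  for (op in dp_ops) {
    p <- sample(length(dp), 1)
    if (op == "sub") dp[p] <- sample(setdiff(BASES, dp[p]), 1)
    else if (op == "ins") dp <- append(dp, sample(BASES, 1), after = p)
    else dp <- dp[-p]
  }
  frag <- paste0(paste(ch[1:(dp_start - 1)], collapse = ""),
                 paste(dp, collapse = ""), continuation)
  substr(frag, 1, 34)
}

random_dna <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# shared small community fixture (deterministic)
fixture_community <- function(seed = 11, ...) {
  defaults <- list(n_genera = 3, species_per_genus = 3, genome_length = 2000,
                   shared_fraction = 0.25, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulate_community, args)
}

fixture_params <- function() codec_params(n = 8, m = 6)

# run the exported fine-grained pipeline to a discriminative k-mer table
db_table_from <- function(com, p, X) {
  taxmap <- setNames(com$seqtax$taxid, com$seqtax$seqid)
  sets <- lapply(split(names(com$genomes), taxmap[names(com$genomes)]),
                 function(ids) collect_species_kmers(com$genomes[ids], p))
  res <- resolve_genus(sets, com$tree)
  occ <- do.call(rbind, lapply(sets, `[[`, "occurrences"))
  out <- remove_cross_taxa(select_kmers(res, occ, X))
  out[c("group_id", "suffix_code", "taxid")]
}
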