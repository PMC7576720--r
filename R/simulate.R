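# Synthetic genomes, taxonomies and error-injected long reads.

#' Per-base sequencing error model
#'
#' @param rate Total per-base error probability in [0, 1).
#' @param mix Proportions of (substitution, insertion, deletion) errors,
#'   summing to 1. Default c(0.5, 0.25, 0.25), loosely nanopore-like.
#' @return An object of class \code{error_model}.
#' @export
error_model <- function(rate = 0.1, mix = c(sub = 0.5, ins = 0.25, del = 0.25)) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate >= 1)
    .dk_stop("dktax_value_error", "error rate must be in [0, 1)")
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    .dk_stop("dktax_value_error", "mix must be 3 non-negative proportions summing to 1")
  structure(list(rate = rate, mix = unname(mix)), class = "error_model")
}

#' Generate a synthetic taxonomy with genomes and a sequence-taxid map
#'
#' Builds a four-level taxonomy (root, one family, \code{n_genera} genera,
#' \code{species_per_genus} species each) with i.i.d.-uniform random
#' genomes. Within each genus the species share a planted sequence block of
#' \code{shared_fraction * genome_length} bases (placed at a random offset
#' per species) so that genus-level k-mer collisions occur. Additional
#' strains of a species are copies of the first strain with sparse random
#' substitutions. Deterministic per seed.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param genome_length Genome length in bases.
#' @param shared_fraction Fraction of each genome shared within a genus,
#'   in [0, 1).
#' @param strains_per_species Strains (FASTA records) per species.
#' @param strain_divergence Per-base substitution rate between strains.
#' @param seed Optional RNG seed.
#' @return A list of class \code{sim_community}: \code{tree}
#'   (\code{taxonomy_tree}), \code{genomes} (named character vector),
#'   \code{seqtax} (data.frame \code{seqid}, \code{taxid}).
#' @export
simulate_community <- function(n_genera = 4, species_per_genus = 5,
                               genome_length = 10000, shared_fraction = 0.3,
                               strains_per_species = 1,
                               strain_divergence = 0.005, seed = NULL) {
  if (!.is_count(n_genera) || n_genera < 1 ||
      !.is_count(species_per_genus) || species_per_genus < 1 ||
      !.is_count(genome_length) || genome_length < 32)
    .dk_stop("dktax_value_error", "community sizes must be positive (genomes >= 32 bases)")
  if (!is.numeric(shared_fraction) || shared_fraction < 0 || shared_fraction >= 1)
    .dk_stop("dktax_value_error", "shared_fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  genus_ids <- 10L + seq_len(n_genera)
  sp_ids <- outer(seq_len(species_per_genus),
                  (seq_len(n_genera) - 1L) * as.integer(species_per_genus),
                  `+`) + 100L
  taxid <- c(1L, 2L, genus_ids, as.vector(sp_ids))
  parent <- c(1L, 1L, rep(2L, n_genera),
              rep(genus_ids, each = species_per_genus))
  rank <- c("no rank", "family", rep("genus", n_genera),
            rep("species", n_genera * species_per_genus))
  name <- c("root", "family_1", paste0("genus_", seq_len(n_genera)),
            paste0("species_", rep(seq_len(n_genera), each = species_per_genus),
                   "_", rep(seq_len(species_per_genus), n_genera)))
  tree <- taxonomy_tree(taxid, parent, rank, name)
  shared_len <- as.integer(round(shared_fraction * genome_length))
  genomes <- character(0)
  seqid <- character(0); seqtaxid <- integer(0)
  for (g in seq_len(n_genera)) {
    block <- if (shared_len > 0) cpp_random_genome(shared_len) else ""
    for (s in seq_len(species_per_genus)) {
      sp <- sp_ids[s, g]
      free <- genome_length - shared_len
      offset <- if (free > 0) sample.int(free + 1L, 1L) - 1L else 0L
      left <- if (offset > 0) cpp_random_genome(offset) else ""
      right <- if (free - offset > 0) cpp_random_genome(free - offset) else ""
      base_genome <- paste0(left, block, right)
      for (st in seq_len(strains_per_species)) {
        gnm <- base_genome
        if (st > 1L && strain_divergence > 0) {
          chars <- strsplit(gnm, "")[[1]]
          mut <- which(runif(length(chars)) < strain_divergence)
          if (length(mut)) {
            for (p in mut) {
              alt <- setdiff(c("A", "C", "G", "T"), chars[p])
              chars[p] <- alt[sample.int(3L, 1L)]
            }
            gnm <- paste(chars, collapse = "")
          }
        }
        id <- sprintf("seq%d.%d", sp, st)
        genomes[id] <- gnm
        seqid <- c(seqid, id); seqtaxid <- c(seqtaxid, sp)
      }
    }
  }
  structure(list(tree = tree, genomes = genomes,
                 seqtax = data.frame(seqid = seqid, taxid = seqtaxid,
                                     stringsAsFactors = FALSE)),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat(sprintf("synthetic community: %d genomes (%d taxa), genome length ~%d\n",
              length(x$genomes), length(unique(x$seqtax$taxid)),
              as.integer(mean(nchar(x$genomes)))))
  invisible(x)
}

#' Simulate error-injected reads from one genome
#'
#' Read start positions are uniform on the forward strand; each source base
#' independently receives an error with probability \code{model$rate}
#' (type drawn from \code{model$mix}: a substitution replaces the base
#' with one of the other three, an insertion adds a uniform random base
#' after it, a deletion skips it). The nominal read length refers to the
#' drawn source span; the emitted length drifts by the net indel count.
#' Truth coordinates are 1-based, inclusive, forward-strand.
#'
#' @param genome A single genome sequence (length >= \code{read_length}).
#' @param n_reads Number of reads.
#' @param read_length Source span length in bases.
#' @param model An [error_model()].
#' @param seed Optional RNG seed.
#' @param prefix Read-id prefix.
#' @param sample_strands When TRUE, each read is reverse-complemented with
#'   probability 1/2 (truth coordinates stay forward-strand).
#' @return data.frame \code{read_id}, \code{seq}, \code{start}, \code{end},
#'   \code{strand}, \code{n_sub}, \code{n_ins}, \code{n_del}.
#' @export
simulate_reads <- function(genome, n_reads, read_length,
                           model = error_model(), seed = NULL,
                           prefix = "read", sample_strands = FALSE) {
  stopifnot(inherits(model, "error_model"))
  if (!.is_count(n_reads) || n_reads < 0 || !.is_count(read_length) ||
      read_length < 1)
    .dk_stop("dktax_value_error", "n_reads and read_length must be positive integers")
  if (nchar(genome) < read_length)
    .dk_stop("dktax_value_error", "genome shorter than read_length")
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_simulate_reads(toupper(genome), as.integer(n_reads),
                            as.integer(read_length), model$rate,
                            model$mix[1], model$mix[2], model$mix[3])
  seq <- as.character(raw$seq)
  strand <- rep("+", n_reads)
  if (sample_strands && n_reads > 0) {
    flip <- runif(n_reads) < 0.5
    if (any(flip)) {
      seq[flip] <- .revcomp(seq[flip])
      strand[flip] <- "-"
    }
  }
  data.frame(read_id = sprintf("%s_%d", prefix, seq_len(n_reads)),
             seq = seq, start = raw$start,
             end = raw$start + read_length - 1L, strand = strand,
             n_sub = raw$n_sub, n_ins = raw$n_ins, n_del = raw$n_del,
             stringsAsFactors = FALSE)
}

#' Simulate a read set over a whole community
#'
#' Draws the same number of reads from every genome and attaches the truth
#' taxid and source genome id.
#'
#' @param community A \code{sim_community}, or a named character vector of
#'   genomes combined with \code{seqtax}.
#' @param reads_per_genome Reads drawn from each genome.
#' @param read_length Source span length.
#' @param model An [error_model()].
#' @param seed Optional RNG seed.
#' @param seqtax Required when \code{community} is a plain genome vector.
#' @inheritParams simulate_reads
#' @return data.frame as from [simulate_reads()] plus \code{taxid} and
#'   \code{genome_id}.
#' @export
simulate_metagenome <- function(community, reads_per_genome, read_length,
                                model = error_model(), seed = NULL,
                                seqtax = NULL, sample_strands = FALSE) {
  if (inherits(community, "sim_community")) {
    genomes <- community$genomes
    seqtax <- community$seqtax
  } else {
    genomes <- .as_seq_vector(community)
    if (is.null(seqtax))
      .dk_stop("dktax_value_error", "seqtax required for a plain genome vector")
  }
  taxmap <- setNames(as.integer(seqtax$taxid), seqtax$seqid)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(genomes), function(i) {
    id <- names(genomes)[i]
    r <- simulate_reads(genomes[[i]], reads_per_genome, read_length,
                        model = model, prefix = id,
                        sample_strands = sample_strands)
    r$taxid <- taxmap[[id]]
    r$genome_id <- id
    r
  })
  do.call(rbind, out)
}

#' Expected number of error-free k-mers in a read
#'
#' Under a simple binomial model with independent per-base errors at rate
#' \code{e}, a k-mer survives error-free with probability (1 - e)^k, so a
#' read of length L carries round((L - k + 1) * (1 - e)^k) exact k-mers in
#' expectation. At L = 1000, k = 16, e = 0.15 this is 73 -- the motivation
#' for approximate rather than exact k-mer matching on long noisy reads.
#'
#' @param read_length Read length L (>= k).
#' @param k K-mer length.
#' @param error_rate Per-base error rate in [0, 1).
#' @return Integer expectation, rounded to the nearest integer.
#' @examples
#' expected_exact_kmer_matches(1000, 16, 0.15)  # 73
#' @export
expected_exact_kmer_matches <- function(read_length, k, error_rate) {
  if (!.is_count(read_length) || !.is_count(k) || k < 1 || read_length < k)
    .dk_stop("dktax_value_error", "need integer read_length >= k >= 1")
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      is.na(error_rate) || error_rate < 0 || error_rate >= 1)
    .dk_stop("dktax_value_error", "error_rate must be in [0, 1)")
  round((read_length - k + 1) * (1 - error_rate)^k)
}

#' Count exact k-mer matches between a read and its source span
#'
#' Positional comparison (suitable for substitution-only error models):
#' position i matches when the k bases starting at i are identical in both
#' strings.
#'
#' @param read,source Equal-frame sequences.
#' @param k K-mer length.
#' @return Number of matching positions.
#' @export
count_exact_kmer_matches <- function(read, source, k) {
  cpp_count_exact_matches(toupper(read), toupper(source), as.integer(k))
}

#' Write simulated reads as FASTA or FASTQ with a truth TSV
#'
#' @param reads data.frame from [simulate_reads()] or
#'   [simulate_metagenome()].
#' @param path Output reads path (format from extension: .fq/.fastq is
#'   FASTQ with dummy qualities, otherwise FASTA).
#' @param truth Optional path for the truth TSV (read_id, taxid,
#'   genome_id, start, end, n_sub, n_ins, n_del).
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(reads, path, truth = NULL) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  if (!is.null(truth)) {
    cols <- intersect(c("read_id", "taxid", "genome_id", "start", "end",
                        "n_sub", "n_ins", "n_del"), colnames(reads))
    write.table(reads[, cols], truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
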