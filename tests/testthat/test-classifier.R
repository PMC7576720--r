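# Approximate matching and read classification.

test_that("match_kmer agrees with the brute-force string oracle on random pairs", {
  p <- codec_params(n = 14, m = 6)
  set.seed(55)
  n_pairs <- 4000
  mismatch <- 0L
  for (i in seq_len(n_pairs)) {
    ref <- random_dna(32)
    kind <- sample(3, 1)
    query <- if (kind == 1) {
      random_dna(sample(30:34, 1))                     # unrelated
    } else if (kind == 2) {
      corrupt_kmer(ref, sub_pos = sample(15:22, sample(0:2, 1)),
                   dp_ops = sample(c("sub", "ins", "del"), sample(0:3, 1),
                                   replace = TRUE),
                   continuation = random_dna(6))       # in-budget-ish
    } else {
      corrupt_kmer(ref, sub_pos = sample(32, sample(0:4, 1)),
                   dp_ops = sample(c("sub", "ins", "del"), sample(0:4, 1),
                                   replace = TRUE),
                   continuation = random_dna(6))       # heavier damage
    }
    got <- match_kmer(query, ref, p)$matched
    want <- oracle_match(query, ref, p$n, p$m)
    if (got != want) mismatch <- mismatch + 1L
  }
  expect_identical(mismatch, 0L)
})

test_that("match_kmer decision equals the oracle exhaustively for tiny QM fields", {
  # m = 2 keeps the space small; enumerate all QM corruptions and a grid of
  # DP edit placements for a fixed reference k-mer
  p <- codec_params(n = 14, m = 2)
  set.seed(77)
  ref <- random_dna(32)
  qm_pos <- 17:18
  for (a in BASES) for (b in BASES) {
    q <- ref
    substr(q, 17, 17) <- a
    substr(q, 18, 18) <- b
    for (ops in list(character(0), "sub", "del", "ins", c("sub", "sub"),
                     c("ins", "del"), c("sub", "sub", "sub"),
                     c("del", "del"), c("ins", "ins"))) {
      frag <- corrupt_kmer(q, dp_ops = ops, m = p$m,
                           continuation = random_dna(6))
      expect_identical(match_kmer(frag, ref, p)$matched,
                       oracle_match(frag, ref, p$n, p$m))
    }
  }
})

test_that("the error budget is sound: <=1 QM sub plus <=2 DP edits always match", {
  p <- codec_params(n = 14, m = 6)
  set.seed(66)
  for (i in 1:300) {
    ref <- random_dna(32)
    n_qm <- sample(0:1, 1)
    sub_pos <- if (n_qm) sample(17:22, 1) else integer(0)
    ops <- sample(c("sub", "ins", "del"), sample(0:2, 1), replace = TRUE)
    frag <- corrupt_kmer(ref, sub_pos = sub_pos, dp_ops = ops,
                         continuation = random_dna(6))
    expect_true(match_kmer(frag, ref, p)$matched)
    res <- match_kmer(frag, ref, p)
    expect_lte(res$edit_cost, 3)
    expect_lte(res$qm_subs, 1)
    expect_lte(res$dp_cost, 2)
  }
})

test_that("two QM substitutions or any PREFIX damage are rejected", {
  p <- codec_params(n = 14, m = 6)
  set.seed(88)
  for (i in 1:200) {
    ref <- random_dna(32)
    # two distinct QM positions forced to different bases
    frag <- corrupt_kmer(ref, sub_pos = sample(17:22, 2),
                         continuation = random_dna(6))
    expect_false(match_kmer(frag, ref, p)$matched)
    # a PREFIX substitution changes the group: no match
    frag2 <- corrupt_kmer(ref, sub_pos = sample(1:14, 1),
                          continuation = random_dna(6))
    expect_false(match_kmer(frag2, ref, p)$matched)
  }
  # beyond-budget DP damage agrees with the oracle (usually rejected);
  # three substitutions at distinct DP positions guarantee Hamming 3
  rejected <- 0L
  for (i in 1:200) {
    ref <- random_dna(32)
    frag <- corrupt_kmer(ref, dp_sub_pos = sample(10, 3),
                         continuation = random_dna(6))
    got <- match_kmer(frag, ref, p)$matched
    expect_identical(got, oracle_match(frag, ref, p$n, p$m))
    if (!got) rejected <- rejected + 1L
  }
  expect_gt(rejected, 150)
})

test_that("middle bases are not compared: free tolerance between PREFIX and SUFFIX", {
  p <- codec_params(n = 14, m = 6)
  set.seed(99)
  ref <- random_dna(32)
  q <- ref
  substr(q, 15, 16) <- setdiff(c("AA", "CC", "GG", "TT"),
                               substr(ref, 15, 16))[1]
  expect_true(match_kmer(q, ref, p)$matched)
  expect_identical(match_kmer(q, ref, p)$edit_cost, 0L)
})

test_that("group lookup offsets are prefix sums and slices tile the arrays", {
  com <- fixture_community(genome_length = 1000)
  p <- fixture_params()
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 30)
  expect_identical(db$offsets,
                   c(0, cumsum(as.numeric(db$group_size)))[seq_along(db$group_size)])
  expect_identical(nrow(lookup_group(db, which(db$group_size == 0)[1] - 1)), 0L)
  nonempty <- which(db$group_size > 0) - 1
  pieces <- lapply(nonempty, function(g) lookup_group(db, g))
  cat_suffix <- unlist(lapply(pieces, `[[`, "suffix_code"))
  expect_identical(cat_suffix, db$suffix_code)
  expect_error(lookup_group(db, 4^p$n), class = "dktax_value_error")
})

test_that("reads from database genomes classify to their species; noise stays unclassified", {
  # shared_fraction = 0: every k-mer is species-unique, so error-free reads
  # must land exactly on their source species (with sharing, reads drawn
  # mostly from a genus-shared block legitimately classify to the genus)
  com <- fixture_community(n_genera = 2, species_per_genus = 3,
                           genome_length = 3000, shared_fraction = 0,
                           seed = 4)
  p <- fixture_params()
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 100)

  # error-free reads: exact windows everywhere
  reads <- simulate_metagenome(com, reads_per_genome = 3, read_length = 500,
                               model = error_model(0), seed = 10)
  res <- classify_reads(setNames(reads$seq, reads$read_id), db, com$tree)
  expect_true(all(res$status == "C"))
  expect_identical(res$taxid, reads$taxid)
  expect_true(all(res$kmers_examined == 500 - 32 + 1))

  # unrelated random reads: no hits
  set.seed(12)
  junk <- vapply(1:5, function(i) random_dna(300), "")
  resj <- classify_reads(junk, db, com$tree)
  expect_true(all(resj$status == "U"))
  expect_true(all(is.na(resj$taxid)))

  expect_error(classify_reads("ACGT", db), class = "dktax_short_read")
})

test_that("single-read interface exposes hit counts consistent with the batch call", {
  com <- fixture_community(genome_length = 1500, seed = 5)
  p <- fixture_params()
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 50)
  reads <- simulate_metagenome(com, reads_per_genome = 1, read_length = 400,
                               model = error_model(0.1), seed = 20)
  one <- classify_read(reads$seq[1], db, com$tree)
  batch <- classify_reads(setNames(reads$seq, reads$read_id), db, com$tree)
  expect_identical(one$taxid, batch$taxid[1])
  expect_identical(one$total_kmers_examined, batch$kmers_examined[1])
  expect_identical(sum(one$hit_counts == max(one$hit_counts)) >= 1, TRUE)
  expect_identical(unname(max(one$hit_counts)), batch$max_hits[1])
})

test_that("adding k-mers of the true taxon never unclassifies a read", {
  com <- fixture_community(n_genera = 2, species_per_genus = 2,
                           genome_length = 2500, shared_fraction = 0, seed = 6)
  p <- fixture_params()
  taxA <- com$seqtax$taxid[1]
  base_tab <- db_table_from(com, p, X = 10)
  more_tab <- db_table_from(com, p, X = 30)
  extraA <- more_tab[more_tab$taxid == taxA &
                       !(paste(more_tab$group_id, more_tab$suffix_code) %in%
                           paste(base_tab$group_id, base_tab$suffix_code)), ]
  expect_gt(nrow(extraA), 0)
  db1 <- kmer_db_from_table(base_tab, p)
  db2 <- kmer_db_from_table(rbind(base_tab, extraA), p)
  reads <- simulate_reads(com$genomes[[1]], 10, 600, error_model(0.1), seed = 30)
  r1 <- classify_reads(setNames(reads$seq, reads$read_id), db1, com$tree)
  r2 <- classify_reads(setNames(reads$seq, reads$read_id), db2, com$tree)
  was_ok <- r1$status == "C" & r1$taxid == taxA
  expect_true(all(r2$status[was_ok] == "C"))
  expect_true(all(r2$max_hits[was_ok] >= r1$max_hits[was_ok]))
})

test_that("file classification matches per-read calls and is format-independent", {
  com <- fixture_community(genome_length = 1500, seed = 8)
  p <- fixture_params()
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 30)
  reads <- simulate_metagenome(com, reads_per_genome = 2, read_length = 400,
                               model = error_model(0.08), seed = 40)
  fa <- tempfile(fileext = ".fasta"); fq <- tempfile(fileext = ".fq")
  write_reads(reads, fa)
  write_reads(reads, fq)
  ra <- classify_file(fa, db, tree = com$tree)
  rq <- classify_file(fq, db, tree = com$tree)
  expect_identical(as.data.frame(ra), as.data.frame(rq))
  direct <- classify_reads(setNames(reads$seq, reads$read_id), db, com$tree)
  expect_identical(ra$taxid, direct$taxid)
  rep <- attr(ra, "report")
  expect_identical(rep$n_reads, nrow(reads))
  expect_identical(rep$n_classified + rep$n_unclassified, rep$n_reads)

  # empty input
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  r0 <- classify_file(empty, db, tree = com$tree)
  expect_identical(nrow(r0), 0L)
  expect_identical(attr(r0, "report")$n_reads, 0L)
})
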