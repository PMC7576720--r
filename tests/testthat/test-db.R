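# Database construction pipeline and serialization.

test_that("species k-mer collection deduplicates and skips bad windows", {
  p <- fixture_params()
  set.seed(7)
  g <- random_dna(300)
  one <- collect_species_kmers(c(s1 = g), p)
  two <- collect_species_kmers(c(s1 = g, s2 = g), p)  # identical strains
  expect_identical(one$kmers, two$kmers)

  # a 35-base sequence yields at most 4 windows (here exactly 4, one strand)
  w <- collect_species_kmers(c(s = random_dna(35)), p, both_strands = FALSE)
  expect_lte(nrow(w$kmers), 4)
  expect_identical(nrow(w$occurrences), 4L)

  # ambiguous windows are skipped, not failed
  s <- random_dna(100)
  substr(s, 50, 50) <- "N"
  w <- collect_species_kmers(c(s = s), p, both_strands = FALSE)
  expect_false(any(w$occurrences$pos %in% 19:50))
  expect_error(collect_species_kmers(c(s = strrep("N", 40)), p),
               class = "dktax_empty_input")

  # duplicated segment: set size equals the naive string-set oracle
  set.seed(8)
  seg <- random_dna(120)
  gen <- paste0(random_dna(200), seg, random_dna(150), seg, random_dna(100))
  got <- collect_species_kmers(c(s = gen), p, both_strands = FALSE)
  want <- unique(oracle_windows(gen, p$n)$key)
  expect_identical(nrow(got$kmers), length(want))
})

test_that("within-genus sharing is promoted to the genus taxid", {
  com <- fixture_community(shared_fraction = 0.4)
  p <- fixture_params()
  taxmap <- setNames(com$seqtax$taxid, com$seqtax$seqid)
  sets <- lapply(split(names(com$genomes), taxmap[names(com$genomes)]),
                 function(ids) collect_species_kmers(com$genomes[ids], p))
  res <- resolve_genus(sets, com$tree)

  # brute-force multiplicity oracle over decoded strings
  long <- do.call(rbind, lapply(names(sets), function(sp) {
    data.frame(key = paste(sets[[sp]]$kmers$group_id,
                           sets[[sp]]$kmers$suffix_code),
               species = as.integer(sp))
  }))
  genus_of <- function(sp) ancestor_at_rank(com$tree, sp, "genus")
  want <- lapply(split(long$species, long$key), function(sp) {
    g <- vapply(sp, genus_of, 0L)
    out <- integer(0)
    for (gg in unique(g))
      out <- c(out, if (sum(g == gg) >= 2) gg else sp[g == gg])
    sort(out)
  })
  key <- paste(res$group_id, res$suffix_code)
  got <- lapply(split(res$taxid, key), sort)
  expect_identical(got[order(names(got))], want[order(names(want))])

  genus_ids <- com$tree$taxid[com$tree$rank == "genus"]
  expect_gt(sum(res$taxid %in% genus_ids), 0)   # sharing produced genus k-mers
  expect_true(all(res$genus_level == (res$taxid %in% genus_ids)))
})

test_that("positional selection keeps ~X% of windows and all genus k-mers", {
  p <- fixture_params()
  com <- fixture_community(shared_fraction = 0.4)
  taxmap <- setNames(com$seqtax$taxid, com$seqtax$seqid)
  sets <- lapply(split(names(com$genomes), taxmap[names(com$genomes)]),
                 function(ids) collect_species_kmers(com$genomes[ids], p))
  res <- resolve_genus(sets, com$tree)
  occ <- do.call(rbind, lapply(sets, `[[`, "occurrences"))

  expect_identical(select_kmers(res, occ, X = 100), res)  # identity at 100%

  sel <- select_kmers(res, occ, X = 15)
  expect_true(all(res[res$genus_level, "suffix_code"] %in%
                    sel$suffix_code[sel$genus_level]))  # genus always kept
  for (X in c(5, 15, 50)) {
    s <- select_kmers(res, occ, X)
    expect_lt(nrow(s), nrow(res) + 1)
  }

  # stride arithmetic: a 10,000-position range keeps within 1 of 1/stride
  stride <- round(100 / 15)
  pos <- 1:10000
  kept <- sum(((pos - 1) %% stride) == 0)
  expect_lte(abs(kept - 10000 / stride), 1)
})

test_that("cross-taxon k-mers are removed, within-genus kept", {
  res <- data.frame(group_id = c(1, 1, 2, 3), suffix_code = c(9, 9, 5, 7),
                    taxid = c(101L, 201L, 11L, 102L),
                    genus_level = c(FALSE, FALSE, TRUE, FALSE))
  out <- remove_cross_taxa(res)
  expect_identical(out$suffix_code, c(5, 7))   # shared-across-genera dropped
  expect_identical(out$taxid, c(11L, 102L))    # genus-assigned single kept
})

test_that("full build equals the naive string-based reference on a small fixture", {
  com <- fixture_community(genome_length = 1500, shared_fraction = 0.3)
  p <- fixture_params()
  for (X in c(100, 15)) {
    db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = X)
    got <- db_as_keys(db)
    want <- oracle_build(com$genomes, com$seqtax, com$tree, p$n, X)
    expect_identical(nrow(got), nrow(want))
    expect_identical(sort(paste(got$key, got$taxid)),
                     sort(paste(want$key, want$taxid)))
  }
})

test_that("fine-grained pipeline composition reproduces the fused build", {
  com <- fixture_community(genome_length = 1200)
  p <- fixture_params()
  taxmap <- setNames(com$seqtax$taxid, com$seqtax$seqid)
  sets <- lapply(split(names(com$genomes), taxmap[names(com$genomes)]),
                 function(ids) collect_species_kmers(com$genomes[ids], p))
  res <- resolve_genus(sets, com$tree)
  occ <- do.call(rbind, lapply(sets, `[[`, "occurrences"))
  tabl <- remove_cross_taxa(select_kmers(res, occ, X = 15))
  db2 <- kmer_db_from_table(tabl[c("group_id", "suffix_code", "taxid")],
                            p, X = 15)
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 15)
  expect_identical(db2$group_size, db$group_size)
  expect_identical(sort(paste(db2$suffix_code, db2$taxid)),
                   sort(paste(db$suffix_code, db$taxid)))
})

test_that("database invariants: conservation, discriminativeness, determinism, monotonicity", {
  com <- fixture_community(genome_length = 1500, shared_fraction = 0.3)
  p <- fixture_params()
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 20)

  # conservation
  expect_identical(sum(as.numeric(db$group_size)), as.numeric(length(db$suffix_code)))
  expect_identical(length(db$suffix_code), length(db$taxid))
  # no duplicate (group, suffix), hence no k-mer with two taxids
  gid <- rep(seq_along(db$group_size) - 1, db$group_size)
  expect_false(anyDuplicated(paste(gid, db$suffix_code)) > 0)

  # byte determinism of a rebuild
  db2 <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 20)
  expect_identical(db2, db)

  # nested strides: k-mer set at X=10 is a subset of the set at X=20
  d10 <- db_as_keys(build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 10))
  d20 <- db_as_keys(db)
  expect_true(all(d10$key %in% d20$key))

  # empty genome set
  empty <- build_kmer_db(character(0),
                         data.frame(seqid = character(0), taxid = integer(0)),
                         com$tree, p)
  expect_identical(sum(empty$group_size), 0L)
})

test_that("binary serialization round-trips byte-exactly and rejects corruption", {
  com <- fixture_community(genome_length = 800)
  p <- fixture_params()
  db <- build_kmer_db(com$genomes, com$seqtax, com$tree, p, X = 15)
  d1 <- tempfile(); d2 <- tempfile()
  write_kmer_db(db, d1)
  back <- read_kmer_db(d1)
  expect_identical(back$group_size, db$group_size)
  expect_identical(back$suffix_code, db$suffix_code)
  expect_identical(back$taxid, db$taxid)
  expect_identical(back$X, db$X)
  write_kmer_db(back, d2)
  for (f in c("header.json", "size.bin", "suffix.bin", "taxid.bin"))
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))

  # truncated suffix file: size mismatch vs the Size file
  trunc <- readBin(file.path(d1, "suffix.bin"), "raw",
                   file.size(file.path(d1, "suffix.bin")) - 4)
  writeBin(trunc, file.path(d1, "suffix.bin"))
  expect_error(read_kmer_db(d1), class = "dktax_format_error")

  # header n inconsistent with the Size file content
  h <- jsonlite::read_json(file.path(d2, "header.json"), simplifyVector = TRUE)
  h$n <- h$n + 1
  jsonlite::write_json(h, file.path(d2, "header.json"), auto_unbox = TRUE)
  expect_error(read_kmer_db(d2), class = "dktax_format_error")

  # bad magic
  d3 <- tempfile()
  write_kmer_db(db, d3)
  h <- jsonlite::read_json(file.path(d3, "header.json"), simplifyVector = TRUE)
  h$magic <- "NOTADB"
  jsonlite::write_json(h, file.path(d3, "header.json"), auto_unbox = TRUE)
  expect_error(read_kmer_db(d3), class = "dktax_format_error")
})
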