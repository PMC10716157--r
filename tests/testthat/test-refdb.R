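prim <- primer_pair("ACGTACGTACGTACGTACGT", "TTGGCCAATTGGCCAATTGG",
                    max_mismatches = 0L)
rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
set.seed(42)
ins <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

test_that("in-silico PCR recovers primer-flanked inserts on both strands", {
  x <- ins(460)
  genome <- paste0(ins(100), prim$forward, x, rc(prim$reverse), ins(100))
  expect_identical(extract_amplicon(genome, prim), x)
  expect_identical(extract_amplicon(rc(genome), prim), x)
  expect_identical(extract_amplicon(ins(800), prim), character(0))
  expect_error(extract_amplicon("ACGT-12", prim), "IUPAC")
})

test_that("k disjoint cassettes yield exactly k amplicons", {
  xs <- replicate(3, ins(420))
  genome <- paste0(ins(50),
                   paste0(prim$forward, xs, rc(prim$reverse), collapse = ins(80)),
                   ins(50))
  got <- extract_amplicon(genome, prim)
  expect_length(got, 3L)
  expect_setequal(got, xs)
})

test_that("length window and mismatch tolerance are honoured", {
  short <- ins(100)
  genome <- paste0(prim$forward, short, rc(prim$reverse))
  expect_length(extract_amplicon(genome, prim), 0L)
  x <- ins(460)
  mut <- prim$forward
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  genome2 <- paste0(mut, x, rc(prim$reverse))
  expect_length(extract_amplicon(genome2, prim), 0L)  # max_mismatches = 0
  prim1 <- primer_pair(prim$forward, prim$reverse, max_mismatches = 1L)
  expect_identical(extract_amplicon(genome2, prim1), x)
})

test_that("IUPAC degeneracy in primers counts as a match", {
  p <- primer_pair("ACGTRYACGTACGTACGTAC", "TTGGCCAATTGGCCAATTGG", 0L)
  x <- ins(400)
  genome <- paste0("ACGTACACGTACGTACGTAC", x, rc(p$reverse))
  expect_identical(extract_amplicon(genome, p), x)
})

test_that("dedupe collapses exact duplicates, keeps first, is idempotent", {
  rec <- data.frame(id = c("r1", "r2", "r3"),
                    sequence = c("AAAA", "AAAA", "CCCC"),
                    taxonomy = "g__Bifidobacterium", source_genome = "g",
                    is_outgroup = FALSE, stringsAsFactors = FALSE)
  db <- dedupe(rec)
  expect_identical(db$records$id, c("r1", "r3"))
  expect_identical(unname(db$dedup_map[c("r1", "r2", "r3")]),
                   c("r1", "r1", "r3"))
  db2 <- dedupe(db$records)
  expect_identical(db2$records, db$records)
  # distinct-string counting on a random fixture
  seqs <- sample(c("AA", "CC", "GG"), 10, replace = TRUE)
  rec10 <- data.frame(id = paste0("x", 1:10), sequence = seqs,
                      taxonomy = "g__Bifidobacterium", source_genome = "g",
                      is_outgroup = FALSE, stringsAsFactors = FALSE)
  expect_identical(nrow(dedupe(rec10)$records), length(unique(seqs)))
})

test_that("pairwise identity matches column counting", {
  rec <- data.frame(id = c("a", "b"), sequence = c("AAAA", "AAAT"),
                    taxonomy = "g__Bifidobacterium", source_genome = "g",
                    is_outgroup = FALSE, stringsAsFactors = FALSE)
  qc <- identity_summary(dedupe(rec))
  expect_equal(qc$identities$identity, 0.75)
  rec$sequence <- c("AAAA", "AAAA")
  expect_error(identity_summary(dedupe(rec)), "2 records")  # collapses to 1
})

test_that("a mutated sequence family clusters near its expected identity", {
  set.seed(7)
  root <- ins(300)
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  rec <- data.frame(id = paste0("v", 1:10),
                    sequence = replicate(10, mutate(root, 0.10)),
                    taxonomy = "g__Bifidobacterium;s__Bifidobacterium x",
                    source_genome = "g", is_outgroup = FALSE,
                    stringsAsFactors = FALSE)
  qc <- identity_summary(dedupe(rec))
  # two sequences each 10% mutated from the root: expected identity
  # ~ 0.9^2 + 0.1^2/3 = 0.813
  expect_equal(mean(qc$identities$identity), 0.813, tolerance = 0.03)
})

test_that("refdb build + write + read round-trips records exactly", {
  rs <- simulate_refset(n_species = 3, n_variants_per_species = 2, seed = 11)
  db <- build_refdb(rs$genomes, rs$taxonomy)
  expect_identical(nrow(db$records), 7L)  # 3 x 2 + outgroup
  expect_identical(sum(db$records$is_outgroup), 1L)
  dir <- withr::local_tempdir()
  write_refdb(db, dir)
  back <- read_refdb(dir)
  expect_identical(back$records$id, db$records$id)
  expect_identical(back$records$sequence, db$records$sequence)
  expect_identical(back$records$taxonomy, db$records$taxonomy)
  expect_identical(back$records$is_outgroup, db$records$is_outgroup)
  expect_identical(back$dedup_map, db$dedup_map)
})

test_that("zero mutation collapses variants per species after dedup", {
  rs <- simulate_refset(n_species = 4, n_variants_per_species = 3,
                        mutation_rate = 0, n_outgroup = 0, seed = 5)
  db <- build_refdb(rs$genomes, rs$taxonomy)
  expect_identical(nrow(db$records), 4L)
  expect_identical(length(db$dedup_map), 12L)
})
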