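test_that("enumeration covers the space exactly once in lexicographic order", {
  # P = 1 and P = 2 checked against brute-force construction
  expect_length(enumerate_space(region_p1), 20)
  sp2 <- enumerate_space(region_p2)
  brute <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  expect_identical(sp2, brute)
  expect_identical(sp2[1], paste0(AA_ALPHABET[1], AA_ALPHABET[1]))

  sp3 <- enumerate_space(region_B)
  expect_length(sp3, 20^3)
  expect_identical(anyDuplicated(sp3), 0L)
  expect_identical(sum(sp3 == "LQE"), 1L)
  # lexicographic: position-major, alphabet order
  expect_true(all(sp3 == sort(sp3)))
})

test_that("invalid regions are rejected", {
  expect_error(region_spec("Z", integer(0), character(0)), "empty region")
  expect_error(region_spec("Z", c(5, 3), "AC"), "strictly increasing")
  expect_error(region_spec("Z", c(3, 7), "AB"), "alphabet")
  expect_error(region_spec("Z", c(3, 7), "A"), "one letter per position")
})

test_that("random libraries are distinct, reproducible, and WT-free by default", {
  lib <- random_library(region_B, 48, seed = 11)
  expect_identical(nrow(lib), 48L)
  expect_identical(anyDuplicated(lib$identities), 0L)
  expect_false("LQE" %in% lib$identities)
  expect_identical(lib, random_library(region_B, 48, seed = 11))

  one <- random_library(region_B, 1, seed = 5)
  expect_identical(one, random_library(region_B, 1, seed = 5))

  expect_error(random_library(region_p1, 20, seed = 1), "infeasible")
  expect_error(random_library(region_B, 8001, seed = 1), "infeasible")
})

test_that("a full-space request terminates and recovers the enumeration", {
  lib <- random_library(region_B, 8000, seed = 3, exclude_wt = FALSE)
  expect_setequal(lib$identities, enumerate_space(region_B))
})

test_that("each position is drawn uniformly from the alphabet", {
  # 10,000 single-variant draws on a one-position region: every letter's
  # frequency within 5 binomial SDs of 1/20
  letters_drawn <- vapply(seq_len(10000), function(s) {
    random_library(region_p1, 1, seed = s, exclude_wt = FALSE)$identities
  }, character(1))
  counts <- table(factor(letters_drawn, levels = AA_ALPHABET))
  p <- 1 / 20
  bound <- 5 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) < bound))
})

test_that("coverage reports count per-position amino acids and flag gaps", {
  full <- coverage_report(enumerate_space(region_p2), region_p2)
  expect_true(all(full$counts == 20))
  expect_identical(nrow(full$uncovered), 0L)
  expect_equal(unname(rowSums(full$counts)),
               rep(400, 2))  # per-position totals equal library size

  single <- coverage_report("HLF", region_A)
  expect_identical(sum(single$counts > 0), 3L)
  expect_identical(sum(single$counts), 3L)

  # library missing W at the first position flags exactly that pair
  lib <- random_library(region_A, 48, seed = 2)
  ids <- lib$identities
  substr(ids[startsWith(ids, "W")], 1, 1) <- "A"
  rep_ <- coverage_report(ids, region_A)
  expect_true(any(rep_$uncovered$position == 167 &
                    rep_$uncovered$amino_acid == "W"))
  expect_error(coverage_report(character(0), region_A), "empty library")
})

test_that("one-hot encoding has the stated layout and is invertible", {
  X <- encode_one_hot("HLF", region_A)
  expect_identical(dim(X), c(1L, 60L))
  expect_identical(sum(X), 3L)
  # exactly one bit per 20-wide block
  blocks <- split(X[1, ], rep(1:3, each = 20))
  expect_true(all(vapply(blocks, sum, numeric(1)) == 1))

  # a single substitution flips exactly two bits
  d <- encode_one_hot("HLF", region_A) != encode_one_hot("QLF", region_A)
  expect_identical(sum(d), 2L)

  # round-trip over a 100-variant sample
  lib <- random_library(region_A, 100, seed = 9)
  expect_identical(decode_one_hot(encode_one_hot(lib, region_A), region_A),
                   lib$identities)

  expect_error(encode_one_hot("BLF", region_A), "outside the alphabet")
  bad <- encode_one_hot("HLF", region_A)
  bad[1, 1:2] <- 1L
  expect_error(decode_one_hot(bad, region_A), "one-hot")
})

test_that("variant tables round-trip through delimited text", {
  lib <- random_library(region_B, 10, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_variant_table(lib, f)
  back <- read_variant_table(f)
  expect_identical(back$identities, lib$identities)
  expect_identical(back$variant_id, lib$variant_id)
})

test_that("FASTA export applies substitutions to a scaffold", {
  skip_if_not_installed("Biostrings")
  # synthetic 230-residue scaffold carrying the region-B wild type letters
  set.seed(42)
  chars <- sample(AA_ALPHABET, 230, replace = TRUE)
  chars[c(217, 218, 219)] <- c("L", "Q", "E")
  scaffold <- paste(chars, collapse = "")
  vars <- new_variants(region_B, c("LQE", "AAA"))
  f <- withr::local_tempfile(fileext = ".fasta")
  export_fasta(vars, region_B, scaffold, f)
  seqs <- Biostrings::readAAStringSet(f)
  expect_identical(names(seqs), vars$variant_id)
  expect_identical(as.character(seqs[[1]]), scaffold)
  expect_identical(substr(as.character(seqs[[2]]), 217, 219), "AAA")

  expect_error(export_fasta(vars, region_B, paste(rev(chars), collapse = ""),
                            f), "wild-type letters")
})
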