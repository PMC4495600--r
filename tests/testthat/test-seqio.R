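test_that("read_fasta parses, uppercases and strips stop characters", {
  p <- write_temp_fasta(c(">P1", "MKAE"))
  rec <- read_fasta(p)
  expect_equal(rec$id, "P1")
  expect_equal(rec$sequence, "MKAE")

  p <- write_temp_fasta(c(">A desc here", "MKAE", "LLKE", ">B", "mkw*"))
  rec <- read_fasta(p)
  expect_equal(rec$id, c("A", "B"))
  expect_equal(rec$sequence, c("MKAELLKE", "MKW"))

  bad <- write_temp_fasta(c("MKAE", ">P1"))
  expect_error(read_fasta(bad), "line 1")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("fasta round trip preserves records", {
  rec <- protein_records(c("X1", "X2"),
                         c(random_sequence(50, 1), random_sequence(30, 2)))
  p <- tempfile(fileext = ".fasta")
  write_fasta(rec, p)
  expect_equal(read_fasta(p), rec)
})

test_that("parse_variant_token handles three-letter, mixed and bad tokens", {
  expect_equal(parse_variant_token("Lys386Asn"),
               list(wt_aa = "K", position = 386L, mut_aa = "N"))
  expect_equal(parse_variant_token("Gln1792Lys"),
               list(wt_aa = "Q", position = 1792L, mut_aa = "K"))
  expect_equal(parse_variant_token("Lys477T"),
               list(wt_aa = "K", position = 477L, mut_aa = "T"))
  expect_equal(parse_variant_token("K386N")$wt_aa, "K")
  expect_equal(parse_variant_token("Leu240 Lys")$mut_aa, "K")
  expect_error(parse_variant_token("Xyz10Ala"), "Xyz10Ala")
  expect_error(parse_variant_token("12345"), "cannot parse")
})

test_that("apply_variant substitutes exactly one residue", {
  rec <- list(id = "P", sequence = "MKAE")
  out <- apply_variant(rec, list(position = 2, wt_aa = "K", mut_aa = "R"))
  expect_equal(out$sequence, "MRAE")
  out <- apply_variant(rec, list(position = 4, wt_aa = "E", mut_aa = "D"))
  expect_equal(out$sequence, "MKAD")
  expect_error(apply_variant(rec, list(position = 2, wt_aa = "A",
                                       mut_aa = "R")),
               "expected A, observed K")
})

test_that("apply_variant: Hamming distance 1 and involution (100 random cases)", {
  set.seed(7)
  for (i in 1:100) {
    s <- random_sequence(sample(20:80, 1))
    pos <- sample(nchar(s), 1)
    wt <- substr(s, pos, pos)
    mut <- sample(setdiff(AA_ALPHABET, wt), 1)
    rec <- list(id = "P", sequence = s)
    out <- apply_variant(rec, list(position = pos, wt_aa = wt, mut_aa = mut))
    d <- sum(strsplit(s, "")[[1]] != strsplit(out$sequence, "")[[1]])
    expect_identical(d, 1L)
    back <- apply_variant(out, list(position = pos, wt_aa = mut, mut_aa = wt))
    expect_identical(back$sequence, s)
  }
})

test_that("extract_fragment pads with X and matches a slice oracle", {
  # published example: K386 of a 393-residue protein, window runs off the end
  s <- paste0(paste(rep("A", 375), collapse = ""), "STSRHKKLMFKTEGPDSD")
  expect_equal(nchar(s), 393)
  expect_equal(extract_fragment(s, 386), "STSRHKKLMFKTEGPDSDXXX")

  expect_equal(extract_fragment("KAAAAAAAAAAAAA", 1),
               paste0(strrep("X", 10), "K", "AAAAAAAAAA"))
  expect_error(extract_fragment("MKAE", 9), "out of range")

  # brute-force oracle on interior and boundary positions
  set.seed(11)
  for (i in 1:50) {
    s <- random_sequence(sample(25:60, 1))
    pos <- sample(nchar(s), 1)
    chars <- c(rep("X", 10), strsplit(s, "")[[1]], rep("X", 10))
    oracle <- paste(chars[pos:(pos + 20)], collapse = "")
    expect_identical(extract_fragment(s, pos), oracle)
  }
})

test_that("build_dataset labels annotated lysines and the rest as negatives", {
  rec <- protein_records(c("A", "B"), c("MKAKE", "KKKK"))
  sites <- data.frame(protein_id = "A", position = 2, evidence = "annotated")
  ds <- build_dataset(rec, sites)
  expect_equal(nrow(ds), 2)                 # only protein A contributes
  expect_equal(ds$label[ds$center_pos == 2], "positive")
  expect_equal(ds$label[ds$center_pos == 4], "negative")
  expect_true(all(nchar(ds$residues) == 21))
  expect_true(all(substr(ds$residues, 11, 11) == "K"))

  # annotated non-lysine position is skipped with a warning
  sites2 <- data.frame(protein_id = "A", position = c(2, 3),
                       evidence = "annotated")
  expect_warning(ds2 <- build_dataset(rec, sites2), "non-lysine")
  expect_equal(sum(ds2$label == "positive"), 1)
})

test_that("build_dataset bookkeeping matches the generator truth", {
  prot <- small_proteome(seed = 5)
  ds <- build_dataset(prot$records, prot$sites)
  expect_equal(sum(ds$label == "positive"), nrow(prot$truth))
  # positives + negatives = all distinct lysines of site-annotated proteins
  n_lys <- sum(vapply(prot$records$sequence[prot$records$id %in%
                                              prot$sites$protein_id],
                      function(s) sum(strsplit(s, "")[[1]] == "K"), 0L))
  expect_equal(nrow(ds), n_lys)
  expect_false(any(duplicated(paste(ds$protein_id, ds$center_pos))))
})

test_that("reduce_redundancy equals the quadratic greedy oracle", {
  expect_equal(reduce_redundancy(c("AAAA", "AAAA"), 0.3), "AAAA")
  frags <- random_fragments(50, seed = 3)
  expect_equal(reduce_redundancy(frags, 1.0), frags)

  # oracle: plain double loop over retained set
  greedy_oracle <- function(seqs, cutoff) {
    kept <- character(0)
    for (s in seqs) {
      a <- strsplit(s, "")[[1]]
      dup <- FALSE
      for (t in kept) {
        b <- strsplit(t, "")[[1]]
        if (sum(a == b & a != "X") / length(a) > cutoff) { dup <- TRUE; break }
      }
      if (!dup) kept <- c(kept, s)
    }
    kept
  }
  # correlated fragments so the cutoff actually bites
  set.seed(9)
  base <- random_fragments(20, seed = 9)
  pool <- unlist(lapply(base, function(b) {
    vapply(1:10, function(i) {
      ch <- strsplit(b, "")[[1]]
      idx <- sample(21, sample(0:15, 1))
      ch[idx] <- sample(AA_ALPHABET, length(idx), replace = TRUE)
      paste(ch, collapse = "")
    }, "")
  }))
  expect_equal(reduce_redundancy(pool, 0.3), greedy_oracle(pool, 0.3))

  # 'X' never matches: identical all-X fragments are all retained
  expect_equal(length(reduce_redundancy(rep(strrep("X", 21), 3), 0.3)), 3)
})
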