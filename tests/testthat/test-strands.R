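test_that("reverse complement follows base-pairing rules and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("GGGT"), "ACCC")
  expect_error(reverse_complement("ACGU"), "alphabet")
  set.seed(11)
  for (i in 1:100) {
    s <- random_dna(sample(1:40, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("strand sets enforce alphabet, unique names and a single beacon", {
  expect_error(
    strand_set("MB", "ACGTN", "beacon"),
    "alphabet"
  )
  expect_error(
    strand_set(c("A", "A"), c("ACGT", "ACGT"), c("beacon", "input")),
    "unique"
  )
  expect_error(
    strand_set(c("A", "B"), c("ACGT", "ACGT"), c("input", "input")),
    "beacon"
  )
  expect_error(
    strand_set(c("A", "B"), c("ACGT", "ACGT"), c("beacon", "beacon")),
    "beacon"
  )
  s <- strand_set(c("MB", "IN"), c("ACGTT", "AACGT"), c("beacon", "input"))
  expect_s3_class(s, "strand_set")
  expect_error(subset_strands(s, "nope"), "not in set")
  expect_identical(subset_strands(s, character(0))$name, "MB")
})

test_that("guanine tract detection finds maximal disjoint all-G runs", {
  tr <- find_g_tracts("TGGGTGGGTGGG")
  expect_identical(nrow(tr), 3L)
  tr1 <- find_g_tracts("GGGT")
  expect_identical(nrow(tr1), 1L)
  expect_identical(tr1$start, 1L)
  expect_identical(tr1$end, 3L)
  expect_identical(nrow(find_g_tracts("ACAC")), 0L)
  # property: disjoint, ordered, all G, non-extendable
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(sample(5:60, 1), alphabet = c("A", "G", "G", "T"))
    tr <- find_g_tracts(s)
    if (nrow(tr) == 0) next
    expect_true(all(diff(tr$start) > 0))
    if (nrow(tr) > 1) expect_true(all(tr$start[-1] > tr$end[-nrow(tr)] + 1))
    for (r in seq_len(nrow(tr))) {
      run <- substr(s, tr$start[r], tr$end[r])
      expect_true(grepl("^G+$", run))
      expect_true(tr$end[r] - tr$start[r] + 1 >= 3)
      if (tr$start[r] > 1) {
        expect_false(substr(s, tr$start[r] - 1, tr$start[r] - 1) == "G")
      }
      if (tr$end[r] < nchar(s)) {
        expect_false(substr(s, tr$end[r] + 1, tr$end[r] + 1) == "G")
      }
    }
  }
})

test_that("duplex window enumeration matches exhaustive offset enumeration", {
  a <- "ACGTACGTAC"
  b <- reverse_complement(a)
  w <- duplex_windows(a, b, min_len = 10, max_mismatches = 0)
  expect_identical(nrow(w), 1L)
  expect_identical(w$length, 10L)
  expect_identical(w$mismatches, 0L)
  # one internal substitution still yields the full window at 1 mismatch
  b_mut <- paste0(substr(b, 1, 4), "A", substr(b, 6, 10))
  if (substr(b, 5, 5) == "A") b_mut <- paste0(substr(b, 1, 4), "C", substr(b, 6, 10))
  w1 <- duplex_windows(a, b_mut, min_len = 10, max_mismatches = 1)
  expect_identical(nrow(w1), 1L)
  expect_identical(w1$mismatches, 1L)
  # oracle equivalence on random 15-mers
  set.seed(21)
  for (i in 1:20) {
    a <- random_dna(15)
    b <- if (i %% 2 == 0) random_dna(15) else mutate_base(reverse_complement(a), sample(15, 1))
    for (mm in 0:2) {
      got <- sort_windows(duplex_windows(a, b, min_len = 5, max_mismatches = mm))
      want <- sort_windows(brute_windows(a, b, min_len = 5, max_mm = mm))
      expect_equal(got, want)
    }
  }
})

test_that("duplex windows are symmetric under swapping the two strands", {
  set.seed(33)
  for (i in 1:10) {
    a <- random_dna(14)
    b <- mutate_base(reverse_complement(a), sample(14, 1))
    ab <- sort_windows(duplex_windows(a, b, min_len = 5, max_mismatches = 2))
    ba <- duplex_windows(b, a, min_len = 5, max_mismatches = 2)
    # mirror: swap a/b coordinates
    mirrored <- sort_windows(data.frame(
      a_start = ba$b_start, a_end = ba$b_end,
      b_start = ba$a_start, b_end = ba$a_end,
      length = ba$length, mismatches = ba$mismatches
    ))
    expect_equal(ab, mirrored)
  }
})

test_that("FASTA round trip is lossless and carries roles", {
  des <- cached_design("half_adder")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_strand_fasta(des$strands, path)
  back <- read_strand_fasta(path)
  expect_equal(as.data.frame(back), as.data.frame(des$strands))
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_strand_fasta(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(read_strand_fasta(tempfile()), "")
})
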