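test_that("candidate enumeration covers all pairs plus the beacon hairpin", {
  des <- cached_design("half_adder")
  cand <- enumerate_candidates(des$strands, tp)
  expect_identical(sum(cand$type == "duplex"), 3L)
  expect_identical(sum(cand$type == "hairpin"), 1L)
  expect_identical(cand$strand_a[cand$type == "hairpin"], "MB")
  # candidates match direct best_duplex calls
  seqs <- setNames(des$strands$sequence, des$strands$name)
  for (r in which(cand$type == "duplex")) {
    bd <- best_duplex(seqs[[cand$strand_a[r]]], seqs[[cand$strand_b[r]]], tp)
    expect_equal(cand$dG[r], bd$dG)
  }
  # single-strand beacon set: hairpin candidate only
  mb_only <- subset_strands(des$strands, character(0))
  cand1 <- enumerate_candidates(mb_only, tp)
  expect_identical(cand1$type, "hairpin")
})

test_that("designed half-adder subsets resolve to the intended species", {
  des <- cached_design("half_adder")
  s <- des$strands
  # one input opens the beacon
  st1 <- resolve_state(subset_strands(s, "HA-IN 1"), tp)
  expect_identical(nrow(st1$duplexes), 1L)
  expect_true(st1$beacon_open)
  expect_identical(st1$g4_count, 0L)
  # both inputs: input-input duplex takes priority, beacon closes,
  # split G-quadruplex forms
  st2 <- resolve_state(s, tp)
  expect_identical(nrow(st2$duplexes), 1L)
  expect_setequal(
    c(st2$duplexes$strand_a, st2$duplexes$strand_b),
    c("HA-IN 1", "HA-IN 2")
  )
  expect_false(st2$beacon_open)
  expect_false(is.null(st2$hairpin))
  expect_identical(st2$g4_count, 1L)
})

test_that("full-adder triple input leaves input 1 free to open the beacon", {
  des <- cached_design("full_adder")
  st <- resolve_state(des$strands, tp)
  expect_identical(nrow(st$duplexes), 2L)
  pairs <- paste(
    pmin(st$duplexes$strand_a, st$duplexes$strand_b),
    pmax(st$duplexes$strand_a, st$duplexes$strand_b)
  )
  expect_setequal(pairs, c("FA-IN 2 FA-IN 3", "FA-IN 1 MB"))
  expect_true(st$beacon_open)
  expect_identical(st$g4_count, 1L)
})

test_that("degenerate sets resolve cleanly", {
  empty <- strand_set(character(), character(), character())
  st <- resolve_state(empty, tp)
  expect_identical(st$total_dG, 0)
  expect_identical(st$g4_count, 0L)
  lone <- strand_set("IN", "ACGTACGTAA", "input", require_beacon = FALSE)
  st1 <- brute_force_state(lone, tp)
  expect_identical(st1$free, "IN")
  expect_identical(st1$total_dG, 0)
  too_big <- strand_set(
    sprintf("S%d", 1:8), replicate(8, random_dna(10)), rep("input", 8),
    require_beacon = FALSE
  )
  expect_error(brute_force_state(too_big, tp), "7 strands")
})

test_that("resolved states conserve strands and match the exhaustive optimum", {
  set.seed(101)
  sc <- search_config(min_len = 6, max_mismatches = 2)
  for (i in 1:50) {
    strands <- random_strand_set(sample(2:6, 1), with_beacon = i %% 2 == 0)
    res <- resolve_state(strands, tp, sc)
    # strand conservation
    in_dup <- c(res$duplexes$strand_a, res$duplexes$strand_b)
    hair <- if (!is.null(res$hairpin)) res$beacon else character(0)
    expect_setequal(c(in_dup, hair, res$free), strands$name)
    expect_identical(anyDuplicated(in_dup), 0L)
    # total energy is the sum over complexes
    hp_dg <- if (!is.null(res$hairpin)) res$hairpin$dG else 0
    expect_equal(res$total_dG, sum(res$duplexes$dG) + hp_dg)
    # exhaustive oracle equivalence
    bf <- brute_force_state(strands, tp, sc)
    expect_same_state(res, bf)
  }
})

test_that("split and intramolecular G-quadruplex rules count as designed", {
  # half-adder style: overhangs GGGT + TGGGTGGGTGGG at one junction -> 1
  blk <- "ATACTACTACTATACCAT"
  in1 <- paste0("GGGT", blk)
  in2 <- paste0(reverse_complement(blk), "TGGGTGGGTGGG")
  s <- strand_set(c("I1", "I2"), c(in1, in2), c("input", "input"),
    require_beacon = FALSE
  )
  st <- resolve_state(s, tp)
  expect_identical(st$g4_count, 1L)
  expect_identical(st$g4_detail$kind, "junction")
  # tracts covered by a fully complementary partner are silenced
  cover <- strand_set(
    c("I2", "AC"),
    c(in2, reverse_complement(in2)),
    c("input", "input"),
    require_beacon = FALSE
  )
  st0 <- resolve_state(cover, tp)
  expect_identical(st0$g4_count, 0L)
  # a free strand with four proximal tracts folds intramolecularly
  lone <- strand_set("G4", "AAGGGTGGGTGGGTGGGAA", "input", require_beacon = FALSE)
  st2 <- resolve_state(lone, tp)
  expect_identical(st2$g4_count, 1L)
  expect_identical(st2$g4_detail$kind, "intramolecular")
  # four tracts spread beyond the span limit do not fold
  spread <- strand_set(
    "far",
    paste0("GGGT", strrep("A", 12), "GGGT", strrep("A", 12), "GGGTAGGG"),
    "input",
    require_beacon = FALSE
  )
  expect_identical(resolve_state(spread, tp)$g4_count, 0L)
})

test_that("full-subtractor pair row assembles two G-quadruplexes, one per junction", {
  des <- cached_design("full_subtractor")
  st <- resolve_state(
    subset_strands(des$strands, c("FS-IN 2", "FS-IN 3")), tp
  )
  expect_identical(st$g4_count, 2L)
  expect_identical(sum(st$g4_detail$kind == "junction"), 2L)
  expect_setequal(st$g4_detail$junction, c(1L, 2L))
})

test_that("hybridizing away tract positions never increases the count", {
  des <- cached_design("half_subtractor")
  s <- des$strands
  open_state <- resolve_state(subset_strands(s, "HS-IN 2"), tp)
  covered_state <- resolve_state(s, tp)
  expect_identical(open_state$g4_count, 1L)
  expect_identical(covered_state$g4_count, 0L)
})
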