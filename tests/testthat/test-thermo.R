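test_that("parameter set loads with negative WC stacks and monotone loop table", {
  expect_s3_class(tp, "thermo_params")
  expect_length(tp$nn, 16)
  expect_true(all(tp$nn < 0))
  expect_true(tp$initiation >= 0)
  expect_true(all(diff(tp$loop_penalty) >= 0))
  # self-complementary symmetry of the stack table: dG(XY) == dG(revcomp(XY))
  for (key in names(tp$nn)) {
    expect_equal(tp$nn[[key]], tp$nn[[reverse_complement(key)]])
  }
})

test_that("duplex free energy: single pair, perfect duplex, mismatch additivity", {
  # a single base pair has no stacks: initiation only
  dg1 <- duplex_free_energy(
    "A", "T",
    list(a_start = 1, a_end = 1, b_start = 1, b_end = 1), tp
  )
  expect_equal(dg1, tp$initiation)
  # 8-bp perfect duplex, hand-summed from the parameter file:
  # ACGTCAGG stacks AC,CG,GT,TC,CA,AG,GG = -10.92, + initiation 1.96
  a <- "ACGTCAGG"
  b <- reverse_complement(a)
  win <- list(a_start = 1, a_end = 8, b_start = 1, b_end = 8)
  expect_equal(duplex_free_energy(a, b, win, tp), -8.96)
  expect_equal(duplex_free_energy(a, b, win, tp), oracle_duplex_dg(a, b, win))
  # out-of-range pairing is a contract violation
  expect_error(
    duplex_free_energy(a, b, list(a_start = 1, a_end = 9, b_start = 0, b_end = 8), tp),
    "range"
  )
})

test_that("free energy agrees with the independent oracle on random windows", {
  set.seed(5)
  for (i in 1:25) {
    a <- random_dna(12)
    b <- mutate_base(reverse_complement(a), sample(12, 1))
    win <- list(a_start = 1, a_end = 12, b_start = 1, b_end = 12)
    expect_equal(duplex_free_energy(a, b, win, tp), oracle_duplex_dg(a, b, win))
  }
})

test_that("each added internal mismatch strictly destabilizes a fixed pairing", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(12:24, 1)
    a <- random_dna(n)
    b <- reverse_complement(a)
    win <- list(a_start = 1, a_end = n, b_start = 1, b_end = n)
    dg <- duplex_free_energy(a, b, win, tp)
    # b index paired with a index t is n - t + 1
    internal_a <- sample(2:(n - 1), min(4, n - 2))
    for (pos_a in internal_a) {
      pos_b <- n - pos_a + 1
      cur <- substr(b, pos_b, pos_b)
      wc <- reverse_complement(substr(a, pos_a, pos_a))
      repl <- sample(setdiff(setdiff(c("A", "C", "G", "T"), cur), wc), 1)
      b <- paste0(substr(b, 1, pos_b - 1), repl, substr(b, pos_b + 1, n))
      dg_new <- duplex_free_energy(a, b, win, tp)
      expect_true(dg_new > dg)
      dg <- dg_new
    }
  }
})

test_that("hairpin energy: hand sum, stem monotonicity, loop monotonicity", {
  # 5-bp GC stem with a 20-nt loop: stacks GC,CG,GC,CG = -8.82,
  # + initiation 1.96 + loop_20 5.30
  hp5 <- paste0("GCGCG", strrep("T", 20), "CGCGC")
  expect_equal(hairpin_free_energy(hp5, 5, tp), -8.82 + 1.96 + 5.30)
  # a longer stem of the same composition class is more stable
  hp6 <- paste0("GCGCGC", strrep("T", 20), "GCGCGC")
  expect_lt(hairpin_free_energy(hp6, 6, tp), hairpin_free_energy(hp5, 5, tp))
  # loop penalty is monotone non-decreasing in loop length
  dgs <- vapply(seq(6, 40, by = 2), function(loop) {
    hairpin_free_energy(paste0("GCGCG", strrep("T", loop), "CGCGC"), 5, tp)
  }, numeric(1))
  expect_true(all(diff(dgs) >= 0))
  # overlapping arms are a contract violation
  expect_error(hairpin_free_energy("GCGC", 2, tp), "loop|overlap")
})

test_that("best duplex equals the exhaustive argmin and handles edge cases", {
  a <- "ACGTACGTACGT"
  bd <- best_duplex(a, reverse_complement(a), tp, search_config(6, 0))
  expect_identical(bd$window$length, 12L)
  expect_identical(bd$window$mismatches, 0L)
  # unrelated strands without any qualifying window
  expect_null(best_duplex("AAAAAAAAAA", "CCCCCCCCCC", tp, search_config(6, 0)))
  set.seed(17)
  for (i in 1:50) {
    a <- random_dna(15)
    b <- if (i %% 3 == 0) random_dna(15) else mutate_base(reverse_complement(a), sample(15, 1))
    sc <- search_config(5, 2)
    bd <- best_duplex(a, b, tp, sc)
    wins <- brute_windows(a, b, 5, 2)
    if (is.null(bd)) {
      expect_identical(nrow(wins), 0L)
      next
    }
    dgs <- vapply(seq_len(nrow(wins)), function(r) {
      duplex_free_energy(a, b, wins[r, ], tp)
    }, numeric(1))
    expect_equal(bd$dG, min(dgs))
    # tie-break: earliest start on a, then on b among minimal windows
    near <- which(abs(dgs - min(dgs)) < 1e-12)
    pick <- near[order(wins$a_start[near], wins$b_start[near])][1]
    expect_identical(bd$window$a_start, wins$a_start[pick])
    expect_identical(bd$window$b_start, wins$b_start[pick])
  }
})

test_that("duplex energy is invariant under swapping the strands", {
  set.seed(29)
  for (i in 1:20) {
    a <- random_dna(14)
    b <- mutate_base(reverse_complement(a), sample(14, 1))
    win <- list(a_start = 1, a_end = 14, b_start = 1, b_end = 14)
    mirrored <- list(a_start = 1, a_end = 14, b_start = 1, b_end = 14)
    expect_equal(
      duplex_free_energy(a, b, win, tp),
      duplex_free_energy(b, a, mirrored, tp)
    )
  }
})
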