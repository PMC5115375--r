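test_that("reference truth tables encode the gate logic", {
  ha <- reference_truth_table("half_adder")
  # 1 + 1: SUM 0, CARRY 1, decimal 2
  row11 <- ha[ha$input_1 == 1 & ha$input_2 == 1, ]
  expect_identical(row11$SUM, 0L)
  expect_identical(row11$CARRY, 1L)
  expect_identical(row11$decimal, 2L)
  # adder identity over all rows
  fa <- reference_truth_table("full_adder")
  expect_true(all(
    2L * fa$CARRY_OUT + fa$SUM_OUT == fa$input_1 + fa$input_2 + fa$input_3
  ))
  # half subtractor: 0 - 1 borrows high and prints 1
  hs <- reference_truth_table("half_subtractor")
  row01 <- hs[hs$input_1 == 0 & hs$input_2 == 1, ]
  expect_identical(row01$DIFFERENCE, 1L)
  expect_identical(row01$BORROW, 1L)
  expect_identical(row01$decimal, 1L)
  # full subtractor 1 - 1 - 1: high borrow, difference 1
  fs <- reference_truth_table("full_subtractor")
  row111 <- fs[fs$input_1 == 1 & fs$input_2 == 1 & fs$input_3 == 1, ]
  expect_identical(row111$BORROW_OUT, 1L)
  expect_identical(row111$DIFFERENCE_OUT, 1L)
  # comparator relations
  cmp <- reference_truth_table("comparator")
  expect_identical(cmp$relation, c("equal", "less", "greater", "equal"))
  expect_error(reference_truth_table("nand"), "arg")
})

test_that("arithmetic decoding follows the carry/borrow conventions", {
  # 1 + 1 = 2
  ha <- decode_arithmetic(
    "half_adder",
    tibble::tibble(a = 1L, b = 1L),
    tibble::tibble(SUM = 0L, CARRY = 1L)
  )
  expect_identical(ha$decimal, 2L)
  expect_true(ha$consistent)
  # 1 + 1 + 0 = 2
  fa <- decode_arithmetic(
    "full_adder",
    tibble::tibble(a = 1L, b = 1L, c = 0L),
    tibble::tibble(SUM_OUT = 0L, CARRY_OUT = 1L)
  )
  expect_identical(fa$decimal, 2L)
  expect_true(fa$consistent)
  # 0 - 1 - 1 with high borrow: 2 - 1 - 1 = 0
  fs <- decode_arithmetic(
    "full_subtractor",
    tibble::tibble(a = 0L, b = 1L, c = 1L),
    tibble::tibble(DIFFERENCE_OUT = 0L, BORROW_OUT = 1L)
  )
  expect_identical(fs$decimal, 0L)
  expect_identical(fs$high_borrow, 1L)
  expect_true(fs$consistent)
  # inconsistent digits are reported, not thrown
  bad <- decode_arithmetic(
    "half_adder",
    tibble::tibble(a = 1L, b = 1L),
    tibble::tibble(SUM = 1L, CARRY = 0L)
  )
  expect_false(bad$consistent)
})

test_that("designed circuits simulate their reference truth tables", {
  for (kind in c("half_adder", "half_subtractor", "full_adder",
                 "full_subtractor", "comparator")) {
    des <- cached_design(kind)
    sim <- simulate_truth_table(kind, des$strands, tp)
    ref <- reference_truth_table(kind)
    digit_cols <- unname(circuit_def(kind)$channel_map)
    expect_identical(nrow(sim), nrow(ref))
    for (dc in digit_cols) expect_identical(sim[[dc]], ref[[dc]])
    expect_identical(sim$decimal, ref$decimal)
    expect_true(all(sim$consistent))
    # empty-input row decodes both digits 0 in the positive conventions
    empty <- sim[rowSums(sim[grep("^input_", names(sim))]) == 0, ]
    if (kind != "comparator") {
      expect_identical(unname(unlist(empty[digit_cols])), c(0L, 0L))
    }
  }
})

test_that("simulating with a missing input strand is a configuration error", {
  des <- cached_design("half_adder")
  broken <- des$strands[des$strands$name != "HA-IN 2", ]
  expect_error(simulate_truth_table("half_adder", broken, tp), "missing circuit input")
})

test_that("verification passes designed sets with comfortable margins", {
  v <- verify_circuit("half_adder", cached_design("half_adder")$strands, tp)
  expect_true(v$pass)
  expect_identical(v$n_pass, 4L)
  expect_true(all(v$rows$fam_margin >= 0.3))
  expect_true(all(v$rows$nmm_margin >= 0.3))
  expect_s3_class(tidy(v), "tbl_df")
  g <- glance(v)
  expect_true(g$pass)
  expect_gte(g$min_margin, 0.3)
})

test_that("deleting the split guanine segments breaks exactly the AND rows", {
  des <- cached_design("half_adder")
  s <- des$strands
  # strip the 5' split segment GGGT from input 1 and the 3' split from input 2
  s$sequence[s$name == "HA-IN 1"] <-
    sub("^GGGT", "", s$sequence[s$name == "HA-IN 1"])
  s$sequence[s$name == "HA-IN 2"] <-
    sub("TGGGTGGGTGGG$", "", s$sequence[s$name == "HA-IN 2"])
  v <- verify_circuit("half_adder", s, tp)
  expect_false(v$pass)
  and_row <- v$rows[v$rows$input_1 == 1 & v$rows$input_2 == 1, ]
  expect_false(and_row$pass)
  expect_identical(and_row$CARRY, 0L)
  # the XOR rows are untouched
  expect_true(all(v$rows$pass[!(v$rows$input_1 == 1 & v$rows$input_2 == 1)]))
})

test_that("the comparator is the negative-logic reading of the half subtractor", {
  des <- cached_design("half_subtractor")
  hs <- simulate_truth_table("half_subtractor", des$strands, tp)
  cmp <- simulate_truth_table("comparator", des$strands, tp)
  expect_identical(cmp$EQUAL, 1L - hs$DIFFERENCE)
  expect_identical(cmp$LESS, hs$BORROW)
  expect_identical(cmp$relation, c("equal", "less", "greater", "equal"))
  expect_true(all(cmp$consistent))
})

test_that("simulated rows satisfy the adder and subtractor identities", {
  fa <- simulate_truth_table("full_adder", cached_design("full_adder")$strands, tp)
  expect_true(all(
    2L * fa$CARRY_OUT + fa$SUM_OUT == fa$input_1 + fa$input_2 + fa$input_3
  ))
  fs <- simulate_truth_table(
    "full_subtractor", cached_design("full_subtractor")$strands, tp
  )
  expect_true(all(
    fs$DIFFERENCE_OUT - 2L * fs$BORROW_OUT ==
      fs$input_1 - fs$input_2 - fs$input_3
  ))
})
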