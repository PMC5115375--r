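circuit_kinds <- c(
  "half_adder", "half_subtractor", "full_adder", "full_subtractor",
  "comparator"
)

#' Define a logic circuit on the beacon platform
#'
#' Each circuit shares the single molecular-beacon platform and two
#' fluorescence channels: FAM (beacon opening) and NMM (G-quadruplex
#' assembly). The channel map assigns each channel to an output digit, and a
#' per-channel logic convention says whether a high signal reads as 1
#' (positive) or 0 (negative). The digital comparator is the half-subtractor
#' platform re-read with the FAM channel under the negative convention.
#'
#' @param kind One of `"half_adder"`, `"half_subtractor"`, `"full_adder"`,
#'   `"full_subtractor"`, `"comparator"`.
#' @param input_names Optional custom strand names for the inputs (2 for
#'   half circuits and the comparator, 3 for full circuits).
#' @return A list of class `circuit_def`: `kind`, `input_names`,
#'   `channel_map` (FAM/NMM -> digit role), `conventions` (per channel).
#' @export
circuit_def <- function(kind, input_names = NULL) {
  kind <- match.arg(kind, circuit_kinds)
  defaults <- switch(kind,
    half_adder = list(
      inputs = c("HA-IN 1", "HA-IN 2"),
      map = c(FAM = "SUM", NMM = "CARRY"),
      conv = c(FAM = "positive", NMM = "positive")
    ),
    half_subtractor = list(
      inputs = c("HS-IN 1", "HS-IN 2"),
      map = c(FAM = "DIFFERENCE", NMM = "BORROW"),
      conv = c(FAM = "positive", NMM = "positive")
    ),
    full_adder = list(
      inputs = c("FA-IN 1", "FA-IN 2", "FA-IN 3"),
      map = c(FAM = "SUM_OUT", NMM = "CARRY_OUT"),
      conv = c(FAM = "positive", NMM = "positive")
    ),
    full_subtractor = list(
      inputs = c("FS-IN 1", "FS-IN 2", "FS-IN 3"),
      map = c(FAM = "DIFFERENCE_OUT", NMM = "BORROW_OUT"),
      conv = c(FAM = "positive", NMM = "positive")
    ),
    comparator = list(
      inputs = c("HS-IN 1", "HS-IN 2"),
      map = c(FAM = "EQUAL", NMM = "LESS"),
      conv = c(FAM = "negative", NMM = "positive")
    )
  )
  inputs <- if (is.null(input_names)) defaults$inputs else input_names
  if (length(inputs) != length(defaults$inputs)) {
    stop(kind, " takes ", length(defaults$inputs), " inputs", call. = FALSE)
  }
  structure(
    list(
      kind = kind, input_names = inputs,
      channel_map = defaults$map, conventions = defaults$conv
    ),
    class = "circuit_def"
  )
}

n_inputs <- function(kind) {
  if (kind %in% c("full_adder", "full_subtractor")) 3L else 2L
}

# input bit combinations in binary counting order, input_1 most significant
input_grid <- function(n) {
  rows <- 2L^n
  bits <- matrix(0L, nrow = rows, ncol = n)
  for (i in seq_len(rows)) {
    v <- i - 1L
    for (k in seq(n, 1L)) {
      bits[i, k] <- v %% 2L
      v <- v %/% 2L
    }
  }
  colnames(bits) <- paste0("input_", seq_len(n))
  tibble::as_tibble(bits)
}

circuit_logic <- function(kind, bits) {
  a <- bits[[1]]
  b <- bits[[2]]
  c_in <- if (length(bits) >= 3) bits[[3]] else NULL
  switch(kind,
    half_adder = list(
      SUM = as.integer(xor(a, b)), CARRY = as.integer(a & b)
    ),
    half_subtractor = list(
      DIFFERENCE = as.integer(xor(a, b)), BORROW = as.integer(!a & b)
    ),
    full_adder = list(
      SUM_OUT = (a + b + c_in) %% 2L,
      CARRY_OUT = as.integer(a + b + c_in >= 2L)
    ),
    full_subtractor = list(
      DIFFERENCE_OUT = (a - b - c_in) %% 2L,
      BORROW_OUT = as.integer(a - b - c_in < 0L)
    ),
    comparator = list(
      EQUAL = as.integer(a == b), LESS = as.integer(a < b)
    )
  )
}

#' Reference (electronic-logic) truth table of a circuit
#'
#' Ground truth compiled from the constituent gates: SUM/DIFFERENCE from XOR
#' (three-input parity for the full circuits), CARRY from AND (majority for
#' the full adder), BORROW from INHIBIT, and the comparator from XNOR plus
#' INHIBIT. Arithmetic columns follow the high-borrow convention: a borrow
#' augments the minuend by 2, so `DIFFERENCE - 2 * BORROW` equals the raw
#' signed difference.
#'
#' @param kind A circuit kind (see [circuit_def()]).
#' @return A tibble in binary counting order with input bit columns
#'   (`input_1`, ...), the two output digit columns, `decimal`,
#'   `high_borrow`, and `relation` (comparator only).
#' @examples
#' reference_truth_table("half_adder")
#' @export
reference_truth_table <- function(kind) {
  kind <- match.arg(kind, circuit_kinds)
  bits <- input_grid(n_inputs(kind))
  digits <- circuit_logic(kind, bits)
  out <- dplyr::bind_cols(bits, tibble::as_tibble(digits))
  arith <- decode_arithmetic(kind, bits, tibble::as_tibble(digits))
  out$decimal <- arith$decimal
  out$high_borrow <- arith$high_borrow
  out$relation <- arith$relation
  out
}

#' Arithmetic interpretation of decoded digits
#'
#' Adders: decimal value `2 * CARRY + SUM`, consistent when it equals the
#' sum of the input bits. Subtractors: the printed result is the DIFFERENCE
#' digit, with `high_borrow = BORROW`; the identity
#' `DIFFERENCE - 2 * BORROW = a - b (- b_in)` must hold (a high borrow means
#' the minuend was augmented by 2). Comparator: a categorical relation.
#' Inconsistent digits are reported via `consistent`, not as an error.
#'
#' @param kind Circuit kind.
#' @param input_bits A tibble/data frame of input bit columns (rows align
#'   with `digits`).
#' @param digits A tibble/data frame with the circuit's two digit columns.
#' @return A list with vectors `decimal`, `high_borrow`, `relation`,
#'   `consistent`.
#' @export
decode_arithmetic <- function(kind, input_bits, digits) {
  kind <- match.arg(kind, circuit_kinds)
  a <- input_bits[[1]]
  b <- input_bits[[2]]
  c_in <- if (ncol(input_bits) >= 3) input_bits[[3]] else 0L
  n <- length(a)
  na_int <- rep(NA_integer_, n)
  na_chr <- rep(NA_character_, n)
  if (kind %in% c("half_adder", "full_adder")) {
    s_col <- if (kind == "half_adder") "SUM" else "SUM_OUT"
    c_col <- if (kind == "half_adder") "CARRY" else "CARRY_OUT"
    decimal <- 2L * digits[[c_col]] + digits[[s_col]]
    list(
      decimal = decimal, high_borrow = na_int, relation = na_chr,
      consistent = decimal == a + b + c_in
    )
  } else if (kind %in% c("half_subtractor", "full_subtractor")) {
    d_col <- if (kind == "half_subtractor") "DIFFERENCE" else "DIFFERENCE_OUT"
    b_col <- if (kind == "half_subtractor") "BORROW" else "BORROW_OUT"
    d <- digits[[d_col]]
    brw <- digits[[b_col]]
    list(
      decimal = d, high_borrow = brw, relation = na_chr,
      consistent = (d - 2L * brw) == (a - b - c_in)
    )
  } else {
    eq <- digits[["EQUAL"]]
    less <- digits[["LESS"]]
    relation <- dplyr::case_when(
      eq == 1L ~ "equal",
      less == 1L ~ "less",
      TRUE ~ "greater"
    )
    expected <- dplyr::case_when(a == b ~ "equal", a < b ~ "less", TRUE ~ "greater")
    list(
      decimal = na_int, high_borrow = na_int, relation = relation,
      consistent = relation == expected
    )
  }
}

#' Simulate the truth table of a circuit on a strand set
#'
#' For every input bit combination (binary counting order, empty row
#' included), builds the present-strand subset, resolves the hybridization
#' competition with [resolve_state()], computes noiseless channel
#' intensities, decodes both channels at the threshold under the circuit's
#' per-channel conventions, and attaches the arithmetic interpretation.
#'
#' @param circuit A [circuit_def()] (or a kind string).
#' @param strands A `strand_set` containing the beacon and all named inputs.
#' @param params A `thermo_params` object.
#' @param decode A [decode_config()]; its `convention` field is overridden
#'   per channel by the circuit definition.
#' @param search A [search_config()].
#' @param g4 A [g4_config()].
#' @return A tibble of class `mb_truth_table`: input bits, `fam_norm`,
#'   `nmm_norm`, `beacon_open`, `g4_count`, the two digit columns,
#'   `decimal`, `high_borrow`, `relation`.
#' @export
simulate_truth_table <- function(circuit, strands, params = thermo_params(),
                                 decode = decode_config(),
                                 search = search_config(), g4 = g4_config()) {
  if (is.character(circuit)) circuit <- circuit_def(circuit)
  validate_strand_set(strands)
  missing <- setdiff(circuit$input_names, strands$name)
  if (length(missing) > 0) {
    stop(
      "strand set is missing circuit input(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bits <- input_grid(length(circuit$input_names))
  conv_fam <- decode_config(decode$threshold, decode$strict,
    convention = circuit$conventions[["FAM"]]
  )
  conv_nmm <- decode_config(decode$threshold, decode$strict,
    convention = circuit$conventions[["NMM"]]
  )
  rows <- purrr::map(seq_len(nrow(bits)), function(i) {
    present <- circuit$input_names[unlist(bits[i, ]) == 1L]
    state <- resolve_state(subset_strands(strands, present), params, search, g4)
    intens <- channel_intensities(state)
    tibble::tibble(
      fam_norm = intens$fam_norm,
      nmm_norm = intens$nmm_norm,
      beacon_open = state$beacon_open,
      g4_count = state$g4_count,
      fam_bit = as.integer(decode_bit(intens$fam_norm, conv_fam)),
      nmm_bit = as.integer(decode_bit(intens$nmm_norm, conv_nmm))
    )
  })
  out <- dplyr::bind_cols(bits, dplyr::bind_rows(rows))
  digits <- tibble::tibble(.rows = nrow(out))
  digits[[circuit$channel_map[["FAM"]]]] <- out$fam_bit
  digits[[circuit$channel_map[["NMM"]]]] <- out$nmm_bit
  out <- dplyr::bind_cols(
    dplyr::select(out, -"fam_bit", -"nmm_bit"),
    digits
  )
  arith <- decode_arithmetic(circuit$kind, bits, digits)
  out$decimal <- arith$decimal
  out$high_borrow <- arith$high_borrow
  out$relation <- arith$relation
  out$consistent <- arith$consistent
  attr(out, "circuit") <- circuit
  class(out) <- c("mb_truth_table", class(out))
  out
}

#' Verify a simulated circuit against its reference truth table
#'
#' Row-by-row comparison of the simulated digits with the electronic-logic
#' reference, with per-row threshold margins (distance of each channel
#' intensity from the decoding threshold).
#'
#' @inheritParams simulate_truth_table
#' @return An object of class `mb_verification`: `kind`, `rows` (per-row
#'   expected vs simulated digits, margins, pass), `pass`, `n_pass`.
#' @export
verify_circuit <- function(circuit, strands, params = thermo_params(),
                           decode = decode_config(),
                           search = search_config(), g4 = g4_config()) {
  if (is.character(circuit)) circuit <- circuit_def(circuit)
  sim <- simulate_truth_table(circuit, strands, params, decode, search, g4)
  ref <- reference_truth_table(circuit$kind)
  digit_cols <- unname(circuit$channel_map)
  bit_cols <- paste0("input_", seq_along(circuit$input_names))
  rows <- sim[c(bit_cols, "fam_norm", "nmm_norm", digit_cols)]
  for (dc in digit_cols) {
    rows[[paste0("expected_", dc)]] <- ref[[dc]]
  }
  rows$fam_margin <- abs(sim$fam_norm - decode$threshold)
  rows$nmm_margin <- abs(sim$nmm_norm - decode$threshold)
  rows$pass <- purrr::reduce(
    purrr::map(digit_cols, ~ rows[[.x]] == rows[[paste0("expected_", .x)]]),
    `&`
  )
  structure(
    list(
      kind = circuit$kind,
      circuit = circuit,
      rows = rows,
      truth_table = sim,
      n_pass = sum(rows$pass),
      pass = all(rows$pass)
    ),
    class = "mb_verification"
  )
}

#' @export
print.mb_verification <- function(x, ...) {
  cat(
    "<mb_verification>", x$kind, "-",
    x$n_pass, "/", nrow(x$rows), "rows match;",
    if (x$pass) "PASS" else "FAIL", "\n"
  )
  print(x$rows, ...)
  invisible(x)
}
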