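#' Load thermodynamic parameters
#'
#' Reads the tab-separated parameter file shipped with the package (or a user
#' file in the same format): 16 Watson-Crick nearest-neighbor stack free
#' energies at 37 C, a duplex initiation penalty, flat internal/terminal
#' mismatch penalties, and a hairpin loop penalty table (loop lengths 3-30 nt,
#' constant beyond). Mismatches are scored ordinally - any non-WC pair,
#' including G.T, destabilizes by a flat penalty - because the logic circuits
#' only rely on the stability ordering of duplexes, not on absolute energies.
#'
#' @param path Parameter file; defaults to the packaged unified WC set.
#' @return A list of class `thermo_params`: `nn` (named numeric, kcal/mol),
#'   `initiation`, `mismatch_internal`, `mismatch_terminal`, `loop_penalty`
#'   (numeric vector indexed by loop length 3..30).
#' @export
thermo_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_dg37.tsv", package = "mblogic")
  }
  raw <- utils::read.table(path,
    sep = "\t", comment.char = "#",
    col.names = c("key", "value"), stringsAsFactors = FALSE
  )
  vals <- stats::setNames(as.numeric(raw$value), raw$key)
  stacks <- vals[grepl("^[ACGT]{2}$", names(vals))]
  if (length(stacks) != 16 || any(stacks >= 0)) {
    stop("parameter file must give 16 negative WC stack energies",
      call. = FALSE
    )
  }
  loops <- vals[grepl("^loop_\\d+$", names(vals))]
  loop_len <- as.integer(sub("loop_", "", names(loops)))
  loop_penalty <- stats::setNames(loops[order(loop_len)], sort(loop_len))
  penalties <- vals[c("initiation", "mismatch_internal", "mismatch_terminal")]
  if (any(is.na(penalties)) || any(penalties < 0)) {
    stop("initiation and mismatch penalties must be present and non-negative",
      call. = FALSE
    )
  }
  # integer-indexed stack table: entry (x - 1) * 4 + y for base codes x, y
  nn_idx <- unname(stacks[paste0(
    rep(c("A", "C", "G", "T"), each = 4), rep(c("A", "C", "G", "T"), 4)
  )])
  structure(
    list(
      nn = stacks,
      nn_idx = nn_idx,
      id = local({
        .mb_env$params_counter <- .mb_env$params_counter + 1L
        .mb_env$params_counter
      }),
      initiation = unname(vals[["initiation"]]),
      mismatch_internal = unname(vals[["mismatch_internal"]]),
      mismatch_terminal = unname(vals[["mismatch_terminal"]]),
      loop_penalty = unname(loop_penalty),
      loop_len = sort(loop_len)
    ),
    class = "thermo_params"
  )
}

loop_penalty_at <- function(params, loop_len) {
  stopifnot(loop_len >= min(params$loop_len))
  idx <- findInterval(loop_len, params$loop_len)
  params$loop_penalty[idx]
}

#' Free energy of a gapless duplex window
#'
#' Sums Watson-Crick nearest-neighbor stack energies over consecutive
#' perfectly paired steps, plus the initiation penalty and flat penalties for
#' internal and terminal mismatches. More negative is more stable. Embedding
#' a mismatch in an otherwise complementary duplex therefore always
#' destabilizes it - the energy-control lever the strand designer uses to
#' rank competing hybridizations.
#'
#' @param seq_a,seq_b DNA sequences (5'->3').
#' @param window One row of [duplex_windows()] (or a list with `a_start`,
#'   `a_end`, `b_start`, `b_end`): position `a_start + t` of `seq_a` pairs
#'   with `b_end - t` of `seq_b`.
#' @param params A `thermo_params` object.
#' @return Free energy in kcal/mol.
#' @export
duplex_free_energy <- function(seq_a, seq_b, window, params) {
  a_chars <- strsplit(seq_a, "")[[1]]
  b_chars <- strsplit(seq_b, "")[[1]]
  a_idx <- window$a_start:window$a_end
  b_idx <- window$b_end:window$b_start
  if (window$a_start < 1 || window$a_end > length(a_chars) ||
    window$b_start < 1 || window$b_end > length(b_chars) ||
    length(a_idx) != length(b_idx)) {
    stop("pairing indices out of range or unequal window lengths",
      call. = FALSE
    )
  }
  wc <- is_wc_pair(a_chars[a_idx], b_chars[b_idx])
  L <- length(a_idx)
  stack_sum <- 0
  if (L >= 2) {
    keys <- paste0(a_chars[a_idx[-L]], a_chars[a_idx[-1L]])
    stack_sum <- sum(ifelse(wc[-L] & wc[-1L], params$nn[keys], 0))
  }
  term_mm <- sum(!wc[c(1L, L)])
  int_mm <- sum(!wc) - term_mm
  stack_sum + params$initiation +
    params$mismatch_internal * int_mm + params$mismatch_terminal * term_mm
}

#' Free energy of the beacon hairpin
#'
#' Scores the closed state of a molecular beacon: the intramolecular stem
#' (5' arm paired antiparallel with the 3' arm) plus a loop penalty that
#' grows with loop length, plus initiation. Non-WC stem positions incur the
#' flat mismatch penalties.
#'
#' @param sequence Beacon sequence (5'->3').
#' @param stem_len Number of stem base pairs: position `t` pairs with
#'   position `L - t + 1`.
#' @param params A `thermo_params` object.
#' @return Free energy in kcal/mol.
#' @export
hairpin_free_energy <- function(sequence, stem_len, params) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  loop_len <- L - 2L * stem_len
  if (stem_len < 1 || loop_len < min(params$loop_len)) {
    stop("stem arms overlap or loop shorter than ", min(params$loop_len),
      " nt",
      call. = FALSE
    )
  }
  arm5 <- chars[seq_len(stem_len)]
  arm3 <- chars[seq(L, L - stem_len + 1L)]
  wc <- is_wc_pair(arm5, arm3)
  stack_sum <- 0
  if (stem_len >= 2) {
    keys <- paste0(arm5[-stem_len], arm5[-1L])
    stack_sum <- sum(ifelse(wc[-stem_len] & wc[-1L], params$nn[keys], 0))
  }
  term_mm <- sum(!wc[c(1L, stem_len)])
  int_mm <- sum(!wc) - term_mm
  stack_sum + params$initiation + loop_penalty_at(params, loop_len) +
    params$mismatch_internal * int_mm + params$mismatch_terminal * term_mm
}

#' Duplex search configuration
#'
#' @param min_len Minimum paired window length considered a duplex.
#' @param max_mismatches Maximum non-WC pairs tolerated in a window.
#' @return A list of class `search_config`.
#' @export
search_config <- function(min_len = 6, max_mismatches = 3) {
  stopifnot(min_len >= 4, max_mismatches >= 0)
  structure(
    list(min_len = as.integer(min_len), max_mismatches = as.integer(max_mismatches)),
    class = "search_config"
  )
}

#' Most stable duplex between two strands
#'
#' Minimum-free-energy window among all gapless antiparallel alignments
#' satisfying the search configuration. Ties are broken by earlier start on
#' `seq_a`, then earlier start on `seq_b`.
#'
#' @inheritParams duplex_windows
#' @param params A `thermo_params` object.
#' @param search A [search_config()].
#' @return A list with `window` (one-row tibble) and `dG`, or `NULL` if no
#'   window qualifies.
#' @export
best_duplex <- function(seq_a, seq_b, params, search = search_config()) {
  key <- paste(params$id, search$min_len, search$max_mismatches,
    seq_a, seq_b,
    sep = "\r"
  )
  hit <- .mb_env$bd_cache[[key]]
  if (!is.null(hit)) {
    return(if (identical(hit, "none")) NULL else hit)
  }
  scored <- duplex_windows_scored(
    seq_a, seq_b, search$min_len, search$max_mismatches, params
  )
  res <- if (nrow(scored) == 0) {
    NULL
  } else {
    ord <- order(scored$dG, scored$a_start, scored$b_start)
    best <- scored[ord[1L], , drop = FALSE]
    list(
      window = best[c("a_start", "a_end", "b_start", "b_end", "length", "mismatches")],
      dG = best$dG
    )
  }
  if (length(.mb_env$bd_cache) > 4096) {
    rm(list = ls(.mb_env$bd_cache), envir = .mb_env$bd_cache)
  }
  .mb_env$bd_cache[[key]] <- if (is.null(res)) "none" else res
  res
}

# Best closed-hairpin candidate of a strand: the most stable terminal stem
# with perfectly complementary arms (the beacon model; internal stems and
# bulged stems are out of scope). NULL when no such stem exists.
best_hairpin <- function(sequence, params, min_stem = 3) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  max_stem <- (L - min(params$loop_len)) %/% 2L
  if (max_stem < min_stem) {
    return(NULL)
  }
  best <- NULL
  for (s in seq(min_stem, max_stem)) {
    arm5 <- chars[seq_len(s)]
    arm3 <- chars[seq(L, L - s + 1L)]
    if (!all(is_wc_pair(arm5, arm3))) next
    dg <- hairpin_free_energy(sequence, s, params)
    if (is.null(best) || dg < best$dG) {
      best <- list(stem_len = s, dG = dg)
    }
  }
  best
}
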